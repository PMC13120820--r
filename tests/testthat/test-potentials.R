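test_that("dihedral bias evaluates the printed series and is stationary", {
  k <- 0.5925
  for (te in c(-170, -60, 0, 45, 180)) {
    at_ref <- dihedral_bias(te, theta_expt = te, k = k)
    # sum over even m of 2/m!: 2*(1/2! + 1/4! + 1/6!) = 391/360
    expect_equal(at_ref$energy, k * 391 / 360, tolerance = 1e-12)
    expect_equal(at_ref$gradient, 0, tolerance = 1e-12)
  }
  # stationarity: tiny displacements change the energy only at second order
  d <- dihedral_bias(10 + c(-1e-4, 1e-4), theta_expt = 10)
  expect_equal(d$energy[1], d$energy[2], tolerance = 1e-10)
})

test_that("dihedral bias is 360-degree periodic and linear in k", {
  set.seed(61)
  th <- runif(20, -360, 360)
  for (te in c(-120, 30)) {
    a <- dihedral_bias(th, te)
    b <- dihedral_bias(th + 360, te)
    expect_equal(a$energy, b$energy, tolerance = 1e-9)
    expect_equal(dihedral_bias(th, te, k = 1.2)$energy * 2,
                 dihedral_bias(th, te, k = 2.4)$energy, tolerance = 1e-12)
  }
})

test_that("the printed dihedral sign makes the reference a maximum; the restraining convention inverts it", {
  te <- 40
  printed <- dihedral_bias(c(te, te + 180), te, convention = "printed")
  expect_gt(printed$energy[1], printed$energy[2])
  restr <- dihedral_bias(c(te, te + 180), te, convention = "restraining")
  expect_lt(restr$energy[1], restr$energy[2])
  expect_equal(restr$energy, -printed$energy)
})

test_that("dihedral gradient matches central finite differences", {
  set.seed(62)
  for (th in runif(20, -200, 200)) {
    g <- dihedral_bias(th, theta_expt = -35, k = 0.8)$gradient
    fd <- fd_grad(function(x) dihedral_bias(x, theta_expt = -35,
                                            k = 0.8)$energy, th)
    expect_lt(abs(g - fd), 1e-6)
  }
})

test_that("flat-bottom wall is zero inside and C1-continuous at the boundary", {
  fb <- flat_bottom(c(0, 3, 9.999, 10), d_o = 10, k = 100)
  expect_equal(fb$energy, rep(0, 4))
  expect_equal(fb$gradient, rep(0, 4))
  eps <- 1e-8
  just_out <- flat_bottom(10 + eps, 10, 100)
  expect_lt(just_out$energy, 1e-12)
  expect_lt(just_out$gradient, 1e-5)
  expect_equal(flat_bottom(12, 10, 100)$energy, 200)
  expect_equal(flat_bottom(17, 15, 100)$energy, 200)  # axial variant
  set.seed(63)
  for (d in runif(10, 0, 25)) {
    fd <- fd_grad(function(x) flat_bottom(x, 10, 100)$energy, d)
    expect_equal(flat_bottom(d, 10, 100)$gradient, fd, tolerance = 1e-4)
  }
})

test_that("voltage/field mapping reproduces the unit conversion from constants", {
  expect_equal(signif(kcal_per_mol_e_mV(), 3), 43.4)
  f <- voltage_field(100, 92)
  expect_equal(f$field_mV_per_A, 100 / 92, tolerance = 1e-12)
  expect_equal(f$field_kcal, (100 / 92) / kcal_per_mol_e_mV(),
               tolerance = 1e-12)
  expect_equal(f$field_kcal, 0.02505, tolerance = 1e-3)
  expect_equal(voltage_field(0, 92)$field_kcal, 0)
  # inverse mapping
  expect_equal(field_voltage(f$field_kcal, 92), 100, tolerance = 1e-9)
  expect_error(voltage_field(100, 0), "positive")
})

test_that("knock-on restraint is one-sided and its gradient is analytic", {
  ang <- (0:7) * pi / 4
  targets <- cbind(3 * cos(ang), 3 * sin(ang), 0)
  ctr <- c(0, 0, 0)
  expect_equal(knockon_restraint(ctr, targets)$energy, 0)
  # one target pushed 1 A beyond the coordination distance
  t2 <- targets
  t2[1, ] <- c(4, 0, 0)
  expect_equal(knockon_restraint(ctr, t2)$energy, 0.5 * 3 * 1^2)
  # closer than the target distance incurs no penalty
  t3 <- targets; t3[1, ] <- c(1, 0, 0)
  expect_equal(knockon_restraint(ctr, t3)$energy, 0)
  expect_error(knockon_restraint(ctr, targets[1:7, ]), "8 target")
  set.seed(64)
  for (rep in 1:10) {
    ion <- rnorm(3, sd = 2)
    tg <- matrix(rnorm(24, sd = 4), ncol = 3)
    g <- knockon_restraint(ion, tg)$gradient
    for (dim in 1:3) {
      fd <- fd_grad(function(x) {
        p <- ion; p[dim] <- x
        knockon_restraint(p, tg)$energy
      }, ion[dim])
      expect_equal(g[dim], fd, tolerance = 1e-5)
    }
  }
})
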