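test_that("the chain is reproducible per seed and validates its rates", {
  cfg <- knockon_config(seed = 5, duration_us = 10)
  p1 <- simulate_knockon(cfg)
  p2 <- simulate_knockon(cfg)
  expect_identical(p1$events, p2$events)
  expect_identical(p1$ground_truth, p2$ground_truth)
  p3 <- simulate_knockon(knockon_config(seed = 6, duration_us = 10))
  expect_false(identical(p1$events, p3$events))
  expect_error(simulate_knockon(
    knockon_config(lambda_load = 0, lambda_knock = 0, lambda_return = 0)),
    "absorbing")
  expect_equal(p1$ground_truth$n_cycles,
               length(p1$ground_truth$completion_times_us))
})

test_that("an on-axis blocker (TEA mode) abolishes conduction", {
  for (s in 1:3) {
    p <- simulate_knockon(knockon_config(blocker = "TEA", seed = s))
    expect_equal(p$ground_truth$n_cycles, 0)
    expect_equal(nrow(p$events), 0)
  }
  expect_equal(effective_load_rate(knockon_config(blocker = "TEA")), 0)
  expect_equal(effective_load_rate(knockon_config(blocker = "RY785",
                                                  lambda_load = 8)), 2)
})

test_that("with instant knock-on and no returns the cycle count is Poisson-like", {
  tot <- 0; expected <- 0
  for (s in 1:5) {
    cfg <- knockon_config(lambda_load = 5, lambda_knock = 1000,
                          lambda_return = 0, duration_us = 25, seed = s)
    tot <- tot + simulate_knockon(cfg)$ground_truth$n_cycles
    expected <- expected + 5 * 25
  }
  expect_lt(abs(tot - expected), 3 * sqrt(expected))
})

test_that("noiseless rendering places ions exactly on site centers", {
  cfg <- knockon_config(sigma = 0, duration_us = 5, seed = 9)
  run <- render_traces(simulate_knockon(cfg))
  centers <- c(cfg$map$centers, cfg$map$gate_z - 3, cfg$map$exit_z + 3)
  for (tr in run$traces)
    expect_true(all(vapply(tr$z, function(z)
      any(abs(z - centers) < 1e-9), logical(1))))
})

test_that("rendered traces reproduce the ground-truth cycle count exactly", {
  for (s in c(3, 14, 27)) {
    cfg <- knockon_config(seed = s, duration_us = 10)
    p <- simulate_knockon(cfg)
    run <- render_traces(p)
    ev <- detect_permeation_events(run$traces, cfg$map)
    expect_equal(ev$n_events, p$ground_truth$n_cycles)
  }
})

test_that("coarser frame sampling never creates extra events", {
  cfg1 <- knockon_config(seed = 11, duration_us = 10, frame_interval = 1)
  p <- simulate_knockon(cfg1)
  n1 <- detect_permeation_events(render_traces(p)$traces, cfg1$map)$n_events
  cfg2 <- knockon_config(seed = 11, duration_us = 10, frame_interval = 2)
  n2 <- detect_permeation_events(render_traces(simulate_knockon(cfg2))$traces,
                                 cfg2$map)$n_events
  expect_lte(n2, n1)
})

test_that("pore-site occupancy matches the chain's stationary distribution", {
  cfg <- knockon_config(seed = 13, duration_us = 25)
  p <- simulate_knockon(cfg)
  run <- render_traces(p)
  occ <- do.call(rbind, lapply(run$traces, function(tr)
    assign_sites(tr, cfg$map)))
  occ <- occ[occ$time_ns >= 0, ]
  st <- filter_occupancy_stats(occ)
  p4 <- sum(as.numeric(st$count_distribution[
    as.integer(names(st$count_distribution)) >= 4]))
  pi_B <- cfg$lambda_load /
    (cfg$lambda_load + cfg$lambda_knock + cfg$lambda_return)
  expect_lt(abs(p4 - pi_B), 0.02)
  expect_lt(abs(p4 - p$ground_truth$sojourn_loaded), 0.02)
  # the three-ion configuration dominates the rest of the time
  expect_equal(sum(as.numeric(st$count_distribution[c("3", "4")])), 1,
               tolerance = 0.02)
})

test_that("the detected event rate recovers the effective cycle rate", {
  rates <- vapply(1:20, function(s) {
    p <- simulate_knockon(knockon_config(seed = 100 + s))
    p$ground_truth$n_cycles / p$config$duration_us
  }, numeric(1))
  lam <- effective_cycle_rate(knockon_config())
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - lam), 3 * se + 1e-12)
  expect_equal(lam, 2, tolerance = 0.05)  # regime: ~one event per 0.5 us
})

test_that("induced-vacancy runs realize the blocker dichotomy", {
  m <- default_site_map()
  for (s in 1:3) {
    tea <- make_induced_vacancy_run("TEA", seed = s)
    expect_true(is.na(tea$ground_truth$reload_time_ns))
    expect_true(is.na(detect_s4_reload(tea$traces, m, 100)))
    ry <- make_induced_vacancy_run("RY785", seed = s)
    expect_false(is.na(ry$ground_truth$reload_time_ns))
    det <- detect_s4_reload(ry$traces, m, 100)
    expect_false(is.na(det))
    expect_lt(abs(det - ry$ground_truth$reload_time_ns), 0.1 + 1e-9)
  }
})

test_that("synthetic ligand traces realize the two binding modes", {
  tea <- render_ligand_trace(knockon_config(blocker = "TEA",
                                            duration_us = 2, seed = 3))
  st <- axial_deviation_stats(tea$N$r)
  expect_lt(st$fraction_above, 0.2)  # charged N stays near the axis
  m <- default_site_map()
  expect_equal(mean(tea$N$z), m$centers["Scav"] - 1.5, tolerance = 0.5,
               ignore_attr = TRUE)
  ry <- render_ligand_trace(knockon_config(blocker = "RY785",
                                           duration_us = 2, seed = 3))
  expect_gt(median(ry$N$r), 5)  # wall-bound
  expect_lt(mean(ry$S$z), mean(ry$N$z))  # distal ring toward the cytoplasm
  expect_identical(render_ligand_trace(knockon_config()), list())
})
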