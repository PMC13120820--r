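one_pair <- function(d) {
  list(protein = data.frame(resno = 406, resid = "PRO", chain = "A",
                            elety = "CG", element = "C",
                            x = d, y = 0, z = 0, stringsAsFactors = FALSE),
       ligand = data.frame(element = "C", x = 0, y = 0, z = 0,
                           stringsAsFactors = FALSE))
}

test_that("the cutoff is boundary-inclusive at 4.5 A", {
  sp <- contact_spec()
  expect_equal(count_contacts(one_pair(4.4)$protein, one_pair(4.4)$ligand,
                              sp)$count, 1L)
  expect_equal(count_contacts(one_pair(4.5)$protein, one_pair(4.5)$ligand,
                              sp)$count, 1L)
  expect_equal(count_contacts(one_pair(4.6)$protein, one_pair(4.6)$ligand,
                              sp)$count, 0L)
})

test_that("backbone carbons and non-C/S ligand atoms never count", {
  p <- one_pair(2)$protein
  p$elety <- "CA"
  expect_error(count_contacts(p, one_pair(2)$ligand, contact_spec()),
               "side-chain")
  l <- one_pair(2)$ligand; l$element <- "H"
  expect_error(count_contacts(one_pair(2)$protein, l, contact_spec()),
               "ligand")
})

test_that("contact counts match the all-pairs brute-force oracle", {
  set.seed(41)
  sp <- contact_spec()
  for (rep in 1:20) {
    snap <- random_contact_snapshot()
    cc <- count_contacts(snap$protein, snap$ligand, sp)
    expect_identical(sum(cc$count), brute_contacts(snap$protein, snap$ligand))
    # per-residue totals also equal a restricted brute force
    for (rn in unique(cc$resno)) {
      sub <- snap$protein[snap$protein$resno == rn, , drop = FALSE]
      expect_identical(sum(cc$count[cc$resno == rn]),
                       brute_contacts(sub, snap$ligand, resno = rn))
    }
  }
})

test_that("contact statistics are invariant under joint rigid motion", {
  set.seed(42)
  snap <- random_contact_snapshot()
  sp <- contact_spec()
  base <- count_contacts(snap$protein, snap$ligand, sp)
  R <- random_rotation(); t <- rnorm(3, sd = 20)
  rot <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- m[, 1] + t[1]; df$y <- m[, 2] + t[2]; df$z <- m[, 3] + t[3]
    df
  }
  moved <- count_contacts(rot(snap$protein), rot(snap$ligand), sp)
  expect_equal(moved$count, base$count)
})

test_that("exceedance curves are survival functions of the count series", {
  set.seed(43)
  counts <- rpois(200, 4)
  series <- data.frame(time_ns = seq_along(counts) - 1, resno = 406,
                       resid = "PRO", chain = "A", count = counts)
  exc <- contact_exceedance(series)
  expect_equal(exc$p[exc$n == 0], 1)
  expect_true(all(diff(exc$p) <= 0))
  # sort-based empirical survival oracle
  for (n in 0:max(counts))
    expect_equal(exc$p[exc$n == n], mean(sort(counts) >= n))
  # discrete survival identity: sum over n>=1 equals the mean count
  expect_equal(sum(exc$p[exc$n >= 1]), mean(counts))
  # degenerate series: all snapshots at exactly 5 contacts
  s5 <- transform(series, count = 5L)
  e5 <- contact_exceedance(s5)
  expect_equal(e5$p, ifelse(e5$n <= 5, 1, 0))
})

test_that("constructed fixtures realize their target exceedance exactly", {
  fx <- make_contact_fixture(c("5" = 0.8, "10" = 0.2), n_snapshots = 100,
                             seed = 7)
  series <- contact_series(fx$protein, fx$ligand, fx$times)
  expect_identical(as.integer(tapply(series$count, series$time_ns, sum)
                              [as.character(fx$times)]),
                   fx$counts)
  exc <- contact_exceedance(series)
  expect_equal(exc$p[exc$n == 5], 0.8)
  expect_equal(exc$p[exc$n == 10], 0.2)
  # flat target: at least one contact in every snapshot
  fx1 <- make_contact_fixture(c("1" = 1), n_snapshots = 20, seed = 8)
  expect_true(all(fx1$counts >= 1))
  # empty target: no contacts anywhere
  fx0 <- make_contact_fixture(setNames(numeric(0), character(0)),
                              n_snapshots = 10, seed = 9)
  expect_true(all(fx0$counts == 0))
  expect_error(make_contact_fixture(c("5" = 0.2, "10" = 0.8)), "infeasible")
})

test_that("simultaneous-subunit fractions match direct enumeration", {
  mk <- function(counts_by_chain) {
    do.call(rbind, lapply(seq_along(counts_by_chain), function(t)
      data.frame(time_ns = t, resno = 406, resid = "PRO",
                 chain = c("A", "B", "C", "D"),
                 count = counts_by_chain[[t]])))
  }
  only_one <- mk(replicate(10, c(3, 0, 0, 0), simplify = FALSE))
  expect_equal(simultaneous_subunit_fraction(only_one, 406), 0)
  two <- mk(replicate(10, c(3, 1, 0, 0), simplify = FALSE))
  expect_equal(simultaneous_subunit_fraction(two, 406), 1)
  set.seed(44)
  rnd <- replicate(50, rpois(4, 0.5), simplify = FALSE)
  series <- mk(rnd)
  manual <- mean(vapply(rnd, function(x) sum(x > 0) >= 2, logical(1)))
  expect_equal(simultaneous_subunit_fraction(series, 406), manual)
  expect_error(simultaneous_subunit_fraction(series, 999), "not present")
})
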