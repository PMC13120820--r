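make_trace <- function(z, id = "K1") {
  data.frame(particle_id = rep(id, length(z)), time_ns = seq_along(z),
             z = z, r = rep(0.5, length(z)))
}

test_that("a single bottom-to-top crossing is one event; returns are not", {
  m <- default_site_map()
  cross <- make_trace(seq(-25, 15, by = 0.5))
  ev <- detect_permeation_events(cross, m)
  expect_equal(ev$n_events, 1)
  expect_equal(ev$events$time_ns,
               cross$time_ns[which(cross$z > m$exit_z)[1]])
  # enters the filter, then returns to the cytoplasmic side: no event
  bounce <- make_trace(c(seq(-25, 0, by = 0.5), seq(0, -25, by = -0.5)))
  expect_equal(detect_permeation_events(bounce, m)$n_events, 0)
  # visits the cavity but never a filter site: no event
  shy <- make_trace(c(seq(-25, -8, by = 0.5), seq(-8, -25, by = -0.5)))
  expect_equal(detect_permeation_events(shy, m)$n_events, 0)
  # empty traces yield zero events
  expect_equal(detect_permeation_events(make_trace(numeric(0)), m)$n_events, 0)
})

test_that("re-entry after a return can still complete a later event", {
  m <- default_site_map()
  z <- c(seq(-25, 0, by = 0.5), seq(0, -25, by = -0.5),
         seq(-25, 15, by = 0.5))
  ev <- detect_permeation_events(make_trace(z), m)
  expect_equal(ev$n_events, 1)
})

test_that("conductance reproduces the event-accounting arithmetic", {
  g <- conductance(45, 24.5, 100)
  expect_equal(g$conductance_pS, 45 * 1.602176634e-19 /
                 (24.5e-6 * 0.1) * 1e12, tolerance = 1e-12)
  # linearity in count, inverse in duration and voltage
  expect_equal(conductance(90, 24.5, 100)$conductance_pS,
               2 * g$conductance_pS)
  expect_equal(conductance(45, 49, 100)$conductance_pS,
               g$conductance_pS / 2)
  expect_equal(conductance(45, 24.5, -200)$conductance_pS,
               g$conductance_pS / 2)
  expect_equal(conductance(0, 24.5, 100)$conductance_pS, 0)
  expect_error(conductance(45, 0, 100), "duration")
  expect_error(conductance(45, 24.5, 0), "voltage")
  # mean inter-event time times count recovers the duration
  expect_equal(g$mean_interevent_us * g$n_events, g$duration_us)
})

test_that("density profile localizes mass and respects the cylinder", {
  pos1 <- data.frame(time_ns = 1:100, z = 3.1, r = 1)
  prof <- density_profile(pos1, bin_width = 0.5, z_range = c(0, 6))
  expect_equal(sum(prof$count > 0), 1)
  expect_equal(prof$z[prof$count > 0], 3.25)
  pos2 <- data.frame(time_ns = 1:100, z = runif(100, 0, 6), r = 6.5)
  prof2 <- density_profile(pos2, bin_width = 0.5, z_range = c(0, 6))
  expect_true(all(prof2$relative_density == 0))
  expect_error(density_profile(pos1, n_frames = 0), "frame")
})

test_that("occupancy statistics recover constructed configurations", {
  frames <- 1:10
  occ3 <- do.call(rbind, lapply(frames, function(t)
    data.frame(time_ns = t, particle_id = c("a", "b", "c"),
               label = c("S1", "S3", "S4"))))
  st <- filter_occupancy_stats(occ3)
  expect_equal(as.numeric(st$count_distribution["3"]), 1)
  expect_equal(unname(st$site_occupancy[c("S1", "S3", "S4")]), rep(1, 3))
  expect_equal(unname(st$site_occupancy["S2"]), 0)
  # alternating 3/4-ion frames
  occ4 <- rbind(occ3, data.frame(time_ns = frames[frames %% 2 == 0],
                                 particle_id = "d", label = "Scav"))
  st4 <- filter_occupancy_stats(occ4)
  expect_equal(as.numeric(st4$count_distribution[c("3", "4")]), c(0.5, 0.5))
})

test_that("S4 reload is timed correctly and requires bulk provenance", {
  m <- default_site_map()
  tp <- 100
  dt <- 0.5
  tgrid <- seq(0, 200, by = dt)
  # ion waiting below the gate that reloads S4 at t = 107
  z <- ifelse(tgrid < 107, m$gate_z - 3, m$centers["S4"])
  tr <- data.frame(particle_id = "K1", time_ns = tgrid, z = z)
  expect_equal(detect_s4_reload(tr, m, tp), 107)
  # an ion that was always inside the filter does not count as a reload
  z2 <- ifelse(tgrid < 107, m$centers["S3"], m$centers["S4"])
  tr2 <- data.frame(particle_id = "K2", time_ns = tgrid, z = z2)
  expect_true(is.na(detect_s4_reload(tr2, m, tp)))
  expect_error(detect_s4_reload(tr, m, 500), "range")
})
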