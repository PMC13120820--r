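#' Detect complete permeation events
#'
#' A complete outward permeation event is an ion excursion that starts
#' below the cytoplasmic gate plane, visits at least one filter site
#' (S4...S0) and ends above the filter exit plane without first
#' returning below the gate. Ions that reach the filter but return to
#' the cytoplasmic side are not counted. The completion time is the
#' first frame above the filter exit.
#'
#' @param traces A list of projected traces (columns `time_ns`, `z`), a
#'   single projected trace, or a pooled data.frame with a
#'   `particle_id` column.
#' @param map A [site_map()].
#' @param direction `"outward"` (cytoplasm to extracellular, the
#'   default) or `"inward"`.
#' @return A list with `n_events`, `events` (data.frame `particle_id`,
#'   `time_ns`), and `duration_ns` (span of the pooled time base).
#' @export
detect_permeation_events <- function(traces, map, direction = c("outward", "inward")) {
  direction <- match.arg(direction)
  stopifnot(inherits(map, "site_map"))
  traces <- .as_trace_list(traces)
  ev_id <- character(0); ev_t <- numeric(0)
  tmin <- Inf; tmax <- -Inf
  for (tr in traces) {
    n <- nrow(tr)
    if (n == 0) next
    tmin <- min(tmin, tr$time_ns[1]); tmax <- max(tmax, tr$time_ns[n])
    z <- tr$z
    reg <- ifelse(z < map$gate_z, 0L,
           ifelse(z > map$exit_z, 3L,
           ifelse(z >= map$filter_lo, 2L, 1L)))
    if (direction == "inward") reg <- 3L - reg
    rl <- rle(reg)
    starts <- cumsum(c(1L, rl$lengths[-length(rl$lengths)]))
    armed <- FALSE; visited <- FALSE
    for (k in seq_along(rl$values)) {
      v <- rl$values[k]
      if (v == 0L) { armed <- TRUE; visited <- FALSE }
      else if (v == 2L && armed) visited <- TRUE
      else if (v == 3L && armed && visited) {
        ev_id <- c(ev_id, as.character(tr$particle_id[1]))
        ev_t <- c(ev_t, tr$time_ns[starts[k]])
        armed <- FALSE; visited <- FALSE
      }
    }
  }
  o <- order(ev_t)
  list(n_events = length(ev_t),
       events = data.frame(particle_id = ev_id[o], time_ns = ev_t[o]),
       duration_ns = if (is.finite(tmax)) tmax - tmin else 0)
}

.as_trace_list <- function(traces) {
  if (is.data.frame(traces)) {
    if (!"z" %in% names(traces)) stop("traces must carry a projected 'z' column")
    if ("particle_id" %in% names(traces) &&
        length(unique(traces$particle_id)) > 1)
      return(split(traces, traces$particle_id))
    return(list(traces))
  }
  stopifnot(is.list(traces))
  traces
}

#' Single-channel conductance from an event count
#'
#' Converts a permeation-event count observed over a given analysis
#' window under an applied voltage into a single-channel conductance:
#' `G = n * e / (T * |V|)` with `e` the elementary charge. Also returns
#' the mean inter-event time `T / n` (so that mean inter-event time
#' times event count equals the analysis duration by construction).
#'
#' @param n_events Number of complete permeation events.
#' @param duration_us Analysis duration (microseconds); must be > 0. For
#'   a run in which the field is switched on after an equilibration
#'   preamble, this is the field-on window.
#' @param voltage_mV Applied voltage (mV); must be nonzero.
#' @return List with `conductance_pS`, `mean_interevent_us` (`Inf` when
#'   no events), `n_events`, `duration_us`, `voltage_mV`.
#' @examples
#' conductance(45, 24.5, 100)$conductance_pS  # 2.94 pS, ~3 pS
#' @export
conductance <- function(n_events, duration_us, voltage_mV) {
  stopifnot(n_events >= 0, n_events == round(n_events))
  if (duration_us <= 0) stop("duration must be positive")
  if (voltage_mV == 0) stop("voltage must be nonzero")
  current_A <- n_events * .const$e_C / (duration_us * 1e-6)
  g_pS <- current_A / (abs(voltage_mV) * 1e-3) * 1e12
  list(conductance_pS = g_pS,
       mean_interevent_us = if (n_events > 0) duration_us / n_events else Inf,
       n_events = n_events, duration_us = duration_us,
       voltage_mV = voltage_mV)
}

#' Axial ion density profile relative to bulk
#'
#' Counts ions inside a cylinder coaxial with the pore, bins their axial
#' coordinate, converts counts to a number density and divides by the
#' number-density equivalent of the bulk concentration. An ideal gas at
#' the bulk concentration therefore gives a profile of 1 in every bin.
#'
#' @param positions Projected samples: data.frame with columns `time_ns`,
#'   `z`, `r` (one row per ion per frame).
#' @param n_frames Number of frames sampled; defaults to the number of
#'   distinct `time_ns` values (pass explicitly when some frames contain
#'   no ions).
#' @param cylinder_diameter Cylinder diameter (A, default 12).
#' @param bin_width Axial bin width (A, default 0.5).
#' @param bulk_mM Bulk concentration (mM, default 300).
#' @param z_range Optional c(lo, hi) axial range; default spans the data.
#' @return data.frame `z` (bin centers), `count` (total ions per bin),
#'   `density_A3` (number density per cubic A) and `relative_density`.
#' @export
density_profile <- function(positions, n_frames = NULL,
                            cylinder_diameter = 12, bin_width = 0.5,
                            bulk_mM = 300, z_range = NULL) {
  stopifnot(all(c("time_ns", "z", "r") %in% names(positions)),
            bin_width > 0, cylinder_diameter > 0, bulk_mM > 0)
  if (is.null(n_frames)) n_frames <- length(unique(positions$time_ns))
  if (n_frames <= 0) stop("density profile requires at least one frame")
  R <- cylinder_diameter / 2
  inside <- positions$r <= R
  z <- positions$z[inside]
  if (is.null(z_range)) {
    if (length(z) == 0) stop("no samples inside the cylinder and no z_range given")
    z_range <- range(z)
  }
  breaks <- seq(z_range[1], z_range[2] + bin_width - 1e-12, by = bin_width)
  keep <- z >= breaks[1] & z < breaks[length(breaks)]
  counts <- tabulate(findInterval(z[keep], breaks), nbins = length(breaks) - 1)
  vol <- pi * R^2 * bin_width
  dens <- counts / (vol * n_frames)
  bulk_A3 <- bulk_mM * 1e-3 * .const$N_A / 1e27  # number per cubic A
  data.frame(z = breaks[-length(breaks)] + bin_width / 2,
             count = counts, density_A3 = dens,
             relative_density = dens / bulk_A3)
}

#' Filter occupancy statistics
#'
#' From per-frame site assignments of all tracked ions, tabulates the
#' distribution of the number of ions simultaneously occupying the
#' counted sites (by default S_cav plus the filter sites S4...S0, so the
#' canonical three-ion filter configuration and the metastable four-ion
#' loaded state appear as counts 3 and 4) and the per-site fraction of
#' frames occupied.
#'
#' @param occupancy data.frame with columns `time_ns`, `particle_id`,
#'   `label` (as produced by [assign_sites()] on each trace, row-bound).
#' @param sites Character vector of labels counted as "in the pore
#'   sites"; default `c("Scav","S4","S3","S2","S1","S0")`.
#' @return List with `count_distribution` (named proportions over the
#'   per-frame ion counts) and `site_occupancy` (fraction of frames each
#'   site holds at least one ion).
#' @export
filter_occupancy_stats <- function(occupancy,
                                   sites = .site_names) {
  stopifnot(all(c("time_ns", "label") %in% names(occupancy)))
  frames <- sort(unique(occupancy$time_ns))
  inside <- occupancy[occupancy$label %in% sites, , drop = FALSE]
  per_frame <- table(factor(inside$time_ns, levels = frames))
  count_distribution <- table(as.integer(per_frame)) / length(frames)
  site_occupancy <- vapply(sites, function(s) {
    occ_frames <- unique(inside$time_ns[inside$label == s])
    length(occ_frames) / length(frames)
  }, numeric(1))
  list(count_distribution = count_distribution,
       site_occupancy = site_occupancy)
}

#' Detect reloading of the S4 site after an induced vacancy
#'
#' After a perturbation at `t_perturb` that vacates the S4 site, finds
#' the earliest time at which an ion arriving from below the gate is
#' assigned to S4. Ions that were already inside the filter (sites
#' S4...S0) when the vacancy was created, and ions that never visited
#' the below-gate region before reaching S4, do not qualify: the
#' reported time is a genuine reload from the cytoplasmic side.
#'
#' @param traces List of projected traces (or pooled data.frame with
#'   `particle_id`).
#' @param map A [site_map()].
#' @param t_perturb Perturbation time (ns); must lie inside the traced
#'   time range.
#' @param hysteresis Site-assignment debounce width (A).
#' @return Reload time (ns), or `NA_real_` if S4 is never reloaded.
#' @export
detect_s4_reload <- function(traces, map, t_perturb, hysteresis = 1) {
  traces <- .as_trace_list(traces)
  rng <- range(unlist(lapply(traces, function(tr) range(tr$time_ns))))
  if (t_perturb < rng[1] || t_perturb > rng[2])
    stop("t_perturb outside the traced time range")
  filter_sites <- c("S4", "S3", "S2", "S1", "S0")
  best <- Inf
  for (tr in traces) {
    occ <- assign_sites(tr, map, hysteresis = hysteresis)
    pre <- occ$label[occ$time_ns <= t_perturb]
    if (length(pre) && pre[length(pre)] %in% filter_sites) next
    below_t <- occ$time_ns[occ$label == "below-gate"]
    if (length(below_t) == 0) next
    s4_t <- occ$time_ns[occ$label == "S4" & occ$time_ns > t_perturb]
    s4_t <- s4_t[s4_t > min(below_t)]
    if (length(s4_t)) best <- min(best, s4_t[1])
  }
  if (is.finite(best)) best else NA_real_
}
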