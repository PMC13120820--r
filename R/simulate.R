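#' Configuration for the synthetic knock-on generator
#'
#' Parameters of the stochastic knock-on conduction cycle: the filter
#' holds three K+ ions; loading of the cavity site S_cav from the bulk
#' (rate `lambda_load`) creates a metastable four-ion configuration
#' that either resolves by ejection of the outermost filter ion with a
#' concerted single-file shift (rate `lambda_knock`, one completed
#' cycle) or by return of the cavity ion to the bulk (rate
#' `lambda_return`). An on-axis open-pore blocker ("TEA" mode) abolishes
#' cavity loading entirely; a wall-bound, flow-permissive binder
#' ("RY785" mode) divides the loading rate by `attenuation` (default 4,
#' echoing a four-fold slower permeation rate).
#'
#' The long-run cycle rate of the chain is
#' `lambda_load * lambda_knock / (lambda_load + lambda_knock +
#' lambda_return)` (see [effective_cycle_rate()]). The default rates
#' give ~1.9 cycles per microsecond in open mode — roughly one
#' permeation every 0.5 us — with a short-lived (~10 ns) four-ion
#' loaded state that more often resolves by return of the cavity ion
#' than by ejection.
#'
#' @param map A [site_map()] giving site centers and planes.
#' @param lambda_load,lambda_knock,lambda_return Rates (per us); all
#'   must be nonnegative.
#' @param blocker One of `"none"`, `"TEA"`, `"RY785"`.
#' @param attenuation RY785-mode loading attenuation factor (>= 1).
#' @param sigma Ornstein-Uhlenbeck noise amplitude about site centers
#'   (A).
#' @param tau OU correlation time (ns).
#' @param frame_interval Rendered frame spacing (ns).
#' @param duration_us Simulated duration (us).
#' @param seed RNG seed; all outputs are bitwise-reproducible given
#'   (config, seed).
#' @return Object of class `knockon_config`.
#' @export
knockon_config <- function(map = default_site_map(), lambda_load = 5,
                           lambda_knock = 40, lambda_return = 60,
                           blocker = c("none", "TEA", "RY785"),
                           attenuation = 4, sigma = 0.4, tau = 1,
                           frame_interval = 1, duration_us = 25,
                           seed = 1) {
  blocker <- match.arg(blocker)
  stopifnot(inherits(map, "site_map"),
            lambda_load >= 0, lambda_knock >= 0, lambda_return >= 0,
            attenuation >= 1, sigma >= 0, tau > 0,
            frame_interval > 0, duration_us > 0)
  structure(list(map = map, lambda_load = lambda_load,
                 lambda_knock = lambda_knock, lambda_return = lambda_return,
                 blocker = blocker, attenuation = attenuation,
                 sigma = sigma, tau = tau,
                 frame_interval = frame_interval,
                 duration_us = duration_us, seed = seed),
            class = "knockon_config")
}

#' Effective cavity-loading rate under the configured blocker
#'
#' @param config A [knockon_config()].
#' @return Rate per us: `lambda_load` (none), 0 (TEA) or
#'   `lambda_load / attenuation` (RY785).
#' @export
effective_load_rate <- function(config) {
  switch(config$blocker,
         none = config$lambda_load,
         TEA = 0,
         RY785 = config$lambda_load / config$attenuation)
}

#' Theoretical effective cycle rate of the knock-on chain
#'
#' Exact long-run rate of completed knock-on cycles: one cycle needs on
#' average `1/p_knock` loading attempts (`p_knock = lambda_knock /
#' (lambda_knock + lambda_return)`), each comprising an empty-cavity
#' dwell `1/load` and a loaded-state dwell `1/(lambda_knock +
#' lambda_return)`, which gives
#' `lambda_eff = load * lambda_knock / (load + lambda_knock +
#' lambda_return)` with `load` the blocker-adjusted loading rate. When
#' loading is rate-limiting this reduces to the familiar
#' `load * p_knock`.
#'
#' @param config A [knockon_config()].
#' @return Cycle rate per us.
#' @export
effective_cycle_rate <- function(config) {
  ll <- effective_load_rate(config)
  lk <- config$lambda_knock; lr <- config$lambda_return
  if (ll == 0 || lk == 0) return(0)
  ll * lk / (ll + lk + lr)
}

#' Exact-jump simulation of the knock-on cycle
#'
#' Gillespie simulation of the two-state chain: state A (three filter
#' ions, S_cav empty) loads to state B (S_cav occupied) at the
#' effective loading rate; B resolves back to A either by return of
#' the cavity ion or by a knock-on ejection, which counts as one
#' completed cycle (one elementary charge transported).
#'
#' @param config A [knockon_config()].
#' @return Object of class `knockon_path`: `config`, `events`
#'   (data.frame `time_us`, `type` in load/return/knock) and
#'   `ground_truth` with `n_cycles`, `completion_times_us`,
#'   `sojourn_loaded` (fraction of time in the loaded state) and
#'   `lambda_eff` (theoretical rate).
#' @export
simulate_knockon <- function(config) {
  stopifnot(inherits(config, "knockon_config"))
  ll <- effective_load_rate(config)
  lk <- config$lambda_knock; lr <- config$lambda_return
  if (ll == 0 && lk == 0 && lr == 0 && config$lambda_load == 0)
    stop("all rates are zero: the chain is absorbing")
  set.seed(config$seed)
  T_us <- config$duration_us
  t <- 0; state <- "A"
  tt <- numeric(0); ty <- character(0)
  t_loaded <- 0
  repeat {
    if (state == "A") {
      if (ll == 0) break
      dt <- stats::rexp(1, ll)
      t <- t + dt
      if (t > T_us) break
      state <- "B"; tt <- c(tt, t); ty <- c(ty, "load")
    } else {
      tot <- lk + lr
      if (tot == 0) { t_loaded <- t_loaded + (T_us - t); break }
      dt <- stats::rexp(1, tot)
      if (t + dt > T_us) { t_loaded <- t_loaded + (T_us - t); break }
      t_loaded <- t_loaded + dt
      t <- t + dt
      knock <- stats::runif(1) < lk / tot
      state <- "A"
      tt <- c(tt, t); ty <- c(ty, if (knock) "knock" else "return")
    }
  }
  events <- data.frame(time_us = tt, type = ty, stringsAsFactors = FALSE)
  comp <- tt[ty == "knock"]
  structure(list(config = config, events = events,
                 ground_truth = list(
                   n_cycles = length(comp),
                   completion_times_us = comp,
                   sojourn_loaded = t_loaded / T_us,
                   lambda_eff = effective_cycle_rate(config))),
            class = "knockon_path")
}

#' @export
print.knockon_path <- function(x, ...) {
  cat("knock-on path:", x$config$blocker, "mode,",
      x$config$duration_us, "us,", nrow(x$events), "jumps,",
      x$ground_truth$n_cycles, "completed cycle(s)\n")
  invisible(x)
}

# internal: per-ion site schedule bookkeeping used by the renderer
.schedule_env <- function() {
  e <- new.env()
  e$starts <- list(); e$centers <- list(); e$ends <- numeric(0)
  e$n <- 0L
  e$new_ion <- function(t, center) {
    e$n <- e$n + 1L
    e$starts[[e$n]] <- t; e$centers[[e$n]] <- center
    e$ends[e$n] <- NA_real_
    e$n
  }
  e$add <- function(id, t, center) {
    e$starts[[id]] <- c(e$starts[[id]], t)
    e$centers[[id]] <- c(e$centers[[id]], center)
  }
  e$close <- function(id, t) e$ends[id] <- t
  e
}

# internal: render one ion's OU trace on the frame grid
.render_ion <- function(starts, centers, t_end, grid, dt, sigma, tau) {
  t0 <- starts[1]
  sel <- grid >= t0 & grid < t_end
  tg <- grid[sel]
  n <- length(tg)
  if (n == 0) return(NULL)
  mu <- centers[findInterval(tg, starts)]
  if (sigma > 0) {
    alpha <- exp(-dt / tau)
    innov <- stats::rnorm(n, 0, sigma * sqrt(1 - alpha^2))
    innov[1] <- stats::rnorm(1, 0, sigma)
    dev <- as.numeric(stats::filter(innov, alpha, method = "recursive"))
  } else dev <- numeric(n)
  r <- abs(stats::rnorm(n, 0, 0.6))
  phi <- stats::runif(n, 0, 2 * pi)
  data.frame(time_ns = tg, z = mu + dev, r = r,
             xp = r * cos(phi), yp = r * sin(phi))
}

#' Render ion traces from a simulated knock-on path
#'
#' Turns the jump path into per-ion axial traces: each ion fluctuates
#' (Ornstein-Uhlenbeck noise) about the center of its occupied site and
#' hops instantaneously at jump times. New ions are introduced from
#' below the gate ahead of each loading event, ejected ions continue
#' above the filter exit before their trace ends, and the three ions
#' initially occupying the filter are rendered with a short preamble at
#' negative times showing their entry from the cytoplasmic side (so
#' every ejected ion has a complete gate-to-exit excursion). Radial
#' coordinates are small, as appropriate for pore ions.
#'
#' @param path A `knockon_path` from [simulate_knockon()].
#' @return List with `traces` (list of projected per-ion data.frames
#'   with columns `particle_id`, `time_ns`, `z`, `r`, `xp`, `yp`),
#'   `ground_truth` (copied from the path) and `config`.
#' @export
render_traces <- function(path) {
  stopifnot(inherits(path, "knockon_path"))
  cfg <- path$config
  map <- cfg$map
  set.seed(cfg$seed + 500009L)
  dt <- cfg$frame_interval
  T_ns <- cfg$duration_us * 1000
  below <- map$gate_z - 3
  above <- map$exit_z + 3
  cS <- map$centers
  t_pre <- 20

  sch <- .schedule_env()
  # initial filter occupants (top to bottom: S1, S3, S4), with entry preamble
  id_s1 <- sch$new_ion(-t_pre, below)
  sch$add(id_s1, -8, cS["Scav"]); sch$add(id_s1, -6, cS["S1"])
  id_s3 <- sch$new_ion(-t_pre, below)
  sch$add(id_s3, -14, cS["Scav"]); sch$add(id_s3, -12, cS["S3"])
  id_s4 <- sch$new_ion(-t_pre, below)
  sch$add(id_s4, -18, cS["Scav"]); sch$add(id_s4, -16, cS["S4"])
  id_cav <- NA_integer_

  ev <- path$events
  for (i in seq_len(nrow(ev))) {
    t <- ev$time_us[i] * 1000
    type <- ev$type[i]
    if (type == "load") {
      id_cav <- sch$new_ion(t - 5, below)
      sch$add(id_cav, t, cS["Scav"])
    } else if (type == "return") {
      sch$add(id_cav, t, below)
      sch$close(id_cav, t + 5)
      id_cav <- NA_integer_
    } else {  # knock: concerted single-file shift
      sch$add(id_s1, t, above); sch$close(id_s1, t + 5)
      sch$add(id_s3, t, cS["S1"])
      sch$add(id_s4, t, cS["S3"])
      sch$add(id_cav, t, cS["S4"])
      id_s1 <- id_s3; id_s3 <- id_s4; id_s4 <- id_cav
      id_cav <- NA_integer_
    }
  }
  grid <- seq(-t_pre, T_ns + 6, by = dt)
  sch$ends[is.na(sch$ends)] <- T_ns + dt / 2
  traces <- vector("list", sch$n)
  for (id in seq_len(sch$n)) {
    tr <- .render_ion(sch$starts[[id]], sch$centers[[id]], sch$ends[id],
                      grid, dt, cfg$sigma, cfg$tau)
    if (!is.null(tr)) tr <- cbind(particle_id = sprintf("K%03d", id), tr)
    traces[[id]] <- tr
  }
  traces <- Filter(Negate(is.null), traces)
  names(traces) <- vapply(traces, function(x) as.character(x$particle_id[1]), "")
  list(traces = traces, ground_truth = path$ground_truth, config = cfg)
}

#' Render a synthetic blocker trace
#'
#' Emulates the two binding modes seen for pore blockers: in `"TEA"`
#' mode the reference (charged N) atom sits on the pore axis at a site
#' about 1.5 A below S_cav and rarely deviates more than ~2 A radially;
#' in `"RY785"` mode the reference atoms are wall-bound (r ~ 7 A) in
#' one of four symmetry-equivalent azimuthal poses, between gate and
#' cavity. These are fixtures for the ligand-analysis stage, not
#' physics.
#'
#' @param config A [knockon_config()] (uses map, frame grid, noise and
#'   seed; the mode is taken from `config$blocker`, `"none"` renders
#'   nothing).
#' @return Named list of atom traces (`N`, and `S` for RY785), each a
#'   data.frame `particle_id`, `time_ns`, `z`, `r`, `xp`, `yp`; empty
#'   list for blocker `"none"`.
#' @export
render_ligand_trace <- function(config) {
  stopifnot(inherits(config, "knockon_config"))
  if (config$blocker == "none") return(list())
  set.seed(config$seed + 900001L)
  dt <- config$frame_interval
  tg <- seq(0, config$duration_us * 1000, by = dt)
  n <- length(tg)
  map <- config$map
  alpha <- exp(-dt / config$tau)
  ou <- function(n, sigma) {
    innov <- stats::rnorm(n, 0, sigma * sqrt(1 - alpha^2))
    innov[1] <- stats::rnorm(1, 0, sigma)
    as.numeric(stats::filter(innov, alpha, method = "recursive"))
  }
  if (config$blocker == "TEA") {
    z <- map$centers["Scav"] - 1.5 + ou(n, 0.8)
    xp <- ou(n, 0.7); yp <- ou(n, 0.7)
    list(N = data.frame(particle_id = "TEA:N", time_ns = tg, z = as.numeric(z),
                        r = sqrt(xp^2 + yp^2), xp = xp, yp = yp))
  } else {
    # four symmetry-equivalent wall poses; occasional pose switches
    n_sw <- max(1, stats::rpois(1, config$duration_us / 2))
    sw <- sort(stats::runif(n_sw, 0, max(tg)))
    pose <- cumsum(c(sample(0:3, 1), sample(1:3, length(sw), replace = TRUE)))
    phi0 <- (pose %% 4) * pi / 2 + pi / 4
    phi <- phi0[findInterval(tg, c(-Inf, sw))] + ou(n, 0.12)
    zN <- (map$gate_z + map$centers["Scav"]) / 2 + 2 + ou(n, 1.0)
    rN <- pmax(7 + ou(n, 0.5), 0)
    zS <- zN - 4 + ou(n, 1.0)
    rS <- pmax(7.5 + ou(n, 0.5), 0)
    list(N = data.frame(particle_id = "RY785:N", time_ns = tg,
                        z = as.numeric(zN), r = rN,
                        xp = rN * cos(phi), yp = rN * sin(phi)),
         S = data.frame(particle_id = "RY785:S", time_ns = tg,
                        z = as.numeric(zS), r = rS,
                        xp = rS * cos(phi + 0.2), yp = rS * sin(phi + 0.2)))
  }
}

#' Synthetic induced-vacancy (S4 reload) run
#'
#' Realizes the induced knock-on protocol used to probe blocker
#' occlusion without an applied field: three ions occupy the filter; at
#' `t_perturb` the central ion is driven to S1, the outermost ion is
#' ejected and the innermost shifts up, leaving a vacancy at S4.
#' Whether and when a bulk ion reloads S4 is then drawn from the
#' effective loading rate under the configured blocker mode: never for
#' an on-axis blocker (TEA), within tens of ns for a wall-bound binder
#' (RY785 at the default rates).
#'
#' @param blocker `"TEA"`, `"RY785"` or `"none"`.
#' @param lambda_load Unblocked S4 reload rate (per us, default 400 so
#'   the RY785-mode effective rate of 100/us gives a ~10 ns mean
#'   reload).
#' @param attenuation RY785 attenuation factor (default 4).
#' @param t_perturb Perturbation time (ns, default 100).
#' @param duration_ns Total trace length (ns, default 200).
#' @param frame_interval Frame spacing (ns, default 0.1).
#' @param sigma,tau OU noise parameters.
#' @param map A [site_map()].
#' @param seed RNG seed.
#' @return List with `traces` (per-ion projected traces) and
#'   `ground_truth` (list with `reload_time_ns`, `NA` if S4 is never
#'   reloaded, plus the protocol parameters).
#' @export
make_induced_vacancy_run <- function(blocker = c("TEA", "RY785", "none"),
                                     lambda_load = 400, attenuation = 4,
                                     t_perturb = 100, duration_ns = 200,
                                     frame_interval = 0.1, sigma = 0.4,
                                     tau = 1, map = default_site_map(),
                                     seed = 1) {
  blocker <- match.arg(blocker)
  stopifnot(t_perturb > 0, t_perturb < duration_ns, lambda_load >= 0)
  set.seed(seed)
  rate_ns <- switch(blocker, none = lambda_load, TEA = 0,
                    RY785 = lambda_load / attenuation) / 1000
  cS <- map$centers
  below <- map$gate_z - 3
  above <- map$exit_z + 3
  dt <- frame_interval
  t_pre <- 20

  sch <- .schedule_env()
  # outermost ion: fluctuates S0/S1, here rendered at S1, ejected at t_perturb
  id1 <- sch$new_ion(-t_pre, below)
  sch$add(id1, -8, cS["Scav"]); sch$add(id1, -6, cS["S1"])
  sch$add(id1, t_perturb, above); sch$close(id1, t_perturb + 5)
  # central ion (S2/S3): driven to S1 at the perturbation
  id2 <- sch$new_ion(-t_pre, below)
  sch$add(id2, -14, cS["Scav"]); sch$add(id2, -12, cS["S3"])
  sch$add(id2, t_perturb, cS["S1"])
  # innermost ion (S4): shifts to the center, vacating S4
  id3 <- sch$new_ion(-t_pre, below)
  sch$add(id3, -18, cS["Scav"]); sch$add(id3, -16, cS["S4"])
  sch$add(id3, t_perturb, cS["S3"])

  reload <- NA_real_
  if (rate_ns > 0) {
    cand <- t_perturb + stats::rexp(1, rate_ns)
    if (cand <= duration_ns) {
      # approach from below the gate, clamped after the perturbation
      t0 <- max(cand - 3, t_perturb + dt)
      t1 <- max(cand - 0.5, t0 + dt / 4)
      reload <- max(cand, t1 + dt / 4)
      id4 <- sch$new_ion(t0, below)
      sch$add(id4, t1, cS["Scav"])
      sch$add(id4, reload, cS["S4"])
    }
  }
  grid <- seq(-t_pre, duration_ns, by = dt)
  sch$ends[is.na(sch$ends)] <- duration_ns + dt / 2
  traces <- list()
  for (id in seq_len(sch$n)) {
    tr <- .render_ion(sch$starts[[id]], sch$centers[[id]], sch$ends[id],
                      grid, dt, sigma, tau)
    if (is.null(tr)) next
    tr <- cbind(particle_id = sprintf("K%03d", id), tr)
    traces[[sprintf("K%03d", id)]] <- tr
  }
  list(traces = traces,
       ground_truth = list(reload_time_ns = reload, blocker = blocker,
                           t_perturb = t_perturb,
                           duration_ns = duration_ns))
}

#' Construct a contact fixture realizing a target exceedance curve
#'
#' Builds toy protein/ligand coordinate snapshots whose brute-force
#' contact counts realize a requested exceedance curve exactly: a
#' target `c("5" = 0.8, "10" = 0.2)` over 100 snapshots yields 20
#' snapshots with 10 contacts, 60 with 5 and 20 with none. Contact
#' atoms are placed 3 A from the ligand atom; spectator atoms 20 A
#' away keep the residue present in every snapshot.
#'
#' @param target Named numeric vector: names are contact thresholds
#'   (increasing), values the exceedance probabilities (non-increasing,
#'   in (0, 1]); an increasing curve is infeasible and raises an error.
#'   An empty vector gives zero contacts everywhere.
#' @param n_snapshots Number of snapshots (default 100); each
#'   probability times `n_snapshots` should be an integer for exact
#'   realization.
#' @param resno,resid,chain Residue identity of the contacting side
#'   chain (default P406, subunit A).
#' @param seed RNG seed (snapshot order and atom directions).
#' @return List with `protein` and `ligand` (lists of snapshot atom
#'   tables), `times`, and `counts` (the ground-truth per-snapshot
#'   contact count).
#' @export
make_contact_fixture <- function(target = c("5" = 0.8, "10" = 0.2),
                                 n_snapshots = 100, resno = 406,
                                 resid = "PRO", chain = "A", seed = 1) {
  set.seed(seed)
  if (length(target)) {
    thr <- as.numeric(names(target))
    p <- as.numeric(target)
    if (any(is.na(thr)) || any(diff(thr) <= 0))
      stop("target thresholds must be increasing numbers")
    if (any(p <= 0) || any(p > 1) || any(diff(p) >= 0))
      stop("infeasible exceedance curve: probabilities must be decreasing in n")
    counts <- rep(0L, n_snapshots)
    # snapshots in the top p_k fraction get thr_k contacts, etc.
    n_at <- round(p * n_snapshots) - c(round(p * n_snapshots)[-1], 0)
    lvl <- rep(c(thr, 0), c(n_at, n_snapshots - sum(n_at)))
    counts <- as.integer(sample(lvl))
  } else counts <- rep(0L, n_snapshots)

  sidechain_names <- c("CB", "CG", "CD")
  protein <- vector("list", n_snapshots)
  ligand <- vector("list", n_snapshots)
  for (s in seq_len(n_snapshots)) {
    k <- counts[s]
    dirs <- matrix(stats::rnorm(3 * (k + 4)), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    near <- dirs[seq_len(k), , drop = FALSE] * 3
    far <- dirs[k + 1:4, , drop = FALSE] * 20
    xyz <- rbind(near, far)
    protein[[s]] <- data.frame(
      resno = resno, resid = resid, chain = chain,
      elety = sidechain_names[(seq_len(nrow(xyz)) - 1) %% 3 + 1],
      element = "C", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    ligand[[s]] <- data.frame(element = c("C", "S"),
                              x = c(0, 30), y = c(0, 30), z = c(0, 30),
                              stringsAsFactors = FALSE)
  }
  list(protein = protein, ligand = ligand,
       times = seq_len(n_snapshots) - 1, counts = counts)
}
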