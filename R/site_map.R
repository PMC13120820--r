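.site_names <- c("Scav", "S4", "S3", "S2", "S1", "S0")
.occ_labels <- c("below-gate", "cavity-nonsite", .site_names, "above-filter")

#' Construct a selectivity-filter site map
#'
#' Axial (pore-frame) positions of the K+ binding sites S_cav and
#' S4...S0, the cytoplasmic gate plane and the filter exit plane. Site
#' boundaries are the midpoints between adjacent centers, with a
#' configurable half-width at the two ends.
#'
#' @param centers Named numeric vector of site centers (A) in the order
#'   `Scav, S4, S3, S2, S1, S0`; must be strictly increasing.
#' @param gate_z Gate plane z (A); must lie below the lower boundary of
#'   `Scav`.
#' @param exit_z Filter exit plane z (A); defaults to the upper boundary
#'   of `S0`. Must lie above the `S0` center.
#' @param end_half_width Half-width of the outermost site intervals (A);
#'   defaults to half the mean inter-site spacing.
#' @return Object of class `site_map` with elements `centers`, `gate_z`,
#'   `exit_z`, `boundaries` (the 8 ordered region boundaries) and
#'   `labels` (the 9 occupancy labels).
#' @export
site_map <- function(centers, gate_z, exit_z = NULL, end_half_width = NULL) {
  if (is.null(names(centers))) names(centers) <- .site_names
  stopifnot(identical(names(centers), .site_names))
  centers <- as.numeric(stats::setNames(centers, .site_names))
  names(centers) <- .site_names
  if (any(diff(centers) <= 0))
    stop("site centers must be strictly increasing from Scav to S0")
  gap <- mean(diff(centers))
  if (is.null(end_half_width)) end_half_width <- gap / 2
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  cav_lo <- centers["Scav"] - end_half_width
  s0_hi <- centers["S0"] + end_half_width
  if (is.null(exit_z)) exit_z <- unname(s0_hi)
  if (gate_z >= cav_lo)
    stop("gate plane (", gate_z, ") must lie below the Scav interval")
  if (exit_z <= centers["S0"])
    stop("filter exit plane must lie above the S0 center")
  boundaries <- unname(c(gate_z, cav_lo, mids, s0_hi))
  structure(list(centers = centers, gate_z = gate_z, exit_z = exit_z,
                 boundaries = boundaries, labels = .occ_labels,
                 filter_lo = unname(mids[1])),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat("Site map (z in A):\n")
  cat(sprintf("  gate %.2f | exit %.2f\n", x$gate_z, x$exit_z))
  print(round(x$centers, 2))
  invisible(x)
}

#' Default synthetic site map
#'
#' Site centers used by the synthetic knock-on generator: inter-site
#' spacing of ~3 A in the filter, the cavity site 4.5 A below S4, the
#' gate 18 A below the filter and the exit plane just above S0.
#'
#' @return A [site_map()].
#' @export
default_site_map <- function() {
  site_map(c(Scav = -9, S4 = -3.5, S3 = -0.5, S2 = 2.5, S1 = 5.5, S0 = 8.5),
           gate_z = -18)
}

#' Build a site map from a channel structure
#'
#' Site centers are derived from the time-averaged projected z of the
#' filter oxygen planes: the backbone carbonyl O of Y376, G375, V374 and
#' T373 and the side-chain hydroxyl O (OG1) of T373, averaged over the
#' four subunits (and over frames, when several coordinate sets are
#' given). S1-S3 sit midway between consecutive carbonyl planes, S4
#' between the T373 carbonyl and hydroxyl planes, S0 above the Y376
#' carbonyl plane and S_cav at a configurable offset below the T373
#' hydroxyl plane. The gate plane is the projected z of the gate
#' residue's C-alpha atoms.
#'
#' @param topology A `kv_topology`.
#' @param xyz_frames Optional list of n_atoms x 3 coordinate matrices
#'   (same atom order as `topology$atoms`) over which plane positions
#'   are averaged; default uses the topology coordinates only.
#' @param gate_resno Gate residue (406, the default, or 408).
#' @param cav_offset S_cav center offset below the T373 hydroxyl plane (A).
#' @param s0_offset S0 offset above the Y376 carbonyl plane (A); default
#'   half the mean inter-plane gap.
#' @param exit_offset Filter exit offset above S0 (A); default half the
#'   mean inter-plane gap.
#' @param frame Optional [pore_frame()]; default computed from the
#'   topology via [topology_pore_frame()].
#' @return A [site_map()].
#' @export
build_site_map <- function(topology, xyz_frames = NULL, gate_resno = 406,
                           cav_offset = 4, s0_offset = NULL,
                           exit_offset = NULL, frame = NULL) {
  stopifnot(inherits(topology, "kv_topology"))
  if (!gate_resno %in% c(406, 408))
    stop("gate_resno must be 406 or 408 (C-alpha plane)")
  if (is.null(frame)) frame <- topology_pore_frame(topology)

  plane_sel <- list(p376 = c(376, "O"), p375 = c(375, "O"),
                    p374 = c(374, "O"), p373 = c(373, "O"),
                    pOG = c(373, "OG1"))
  idx <- lapply(plane_sel, function(s) {
    sel <- select_atoms(topology, as.integer(s[1]), s[2])
    match(interaction(sel$resno, sel$elety, sel$chain),
          interaction(topology$atoms$resno, topology$atoms$elety,
                      topology$atoms$chain))
  })
  gate_sel <- select_atoms(topology, gate_resno, "CA")
  gate_idx <- match(interaction(gate_sel$resno, gate_sel$elety, gate_sel$chain),
                    interaction(topology$atoms$resno, topology$atoms$elety,
                                topology$atoms$chain))

  coord_sets <- if (is.null(xyz_frames)) {
    list(as.matrix(topology$atoms[, c("x", "y", "z")]))
  } else lapply(xyz_frames, as.matrix)

  mean_plane <- function(ix) {
    mean(vapply(coord_sets, function(m)
      mean(project_points(m[ix, , drop = FALSE], frame)$z), numeric(1)))
  }
  p <- vapply(idx, mean_plane, numeric(1))
  gate_z <- mean_plane(gate_idx)

  # planes must decrease top-to-bottom: Y376 > G375 > V374 > T373 > T373-OG1
  if (any(diff(p) >= 0))
    stop("filter oxygen planes are not monotonically ordered")
  gap <- mean(abs(diff(p)))
  if (is.null(s0_offset)) s0_offset <- gap / 2
  if (is.null(exit_offset)) exit_offset <- gap / 2

  centers <- c(Scav = unname(p["pOG"] - cav_offset),
               S4 = unname((p["p373"] + p["pOG"]) / 2),
               S3 = unname((p["p374"] + p["p373"]) / 2),
               S2 = unname((p["p375"] + p["p374"]) / 2),
               S1 = unname((p["p376"] + p["p375"]) / 2),
               S0 = unname(p["p376"] + s0_offset))
  site_map(centers, gate_z = gate_z,
           exit_z = unname(centers["S0"] + exit_offset))
}

#' Assign a projected trace to sites with hysteresis
#'
#' Each frame is assigned to the site (or flanking bulk region) whose z
#' interval contains the ion. To debounce boundary noise, the label only
#' changes once z has left the current region's interval by at least
#' `hysteresis`; additive noise of amplitude below the hysteresis width
#' therefore never produces label changes.
#'
#' @param trace Projected trace (columns `time_ns`, `z`).
#' @param map A [site_map()].
#' @param hysteresis Debounce width (A, default 1).
#' @return data.frame `time_ns`, `z`, `label` (factor with levels
#'   `below-gate`, `cavity-nonsite`, `Scav`, `S4`...`S0`, `above-filter`).
#' @export
assign_sites <- function(trace, map, hysteresis = 1) {
  stopifnot(inherits(map, "site_map"), hysteresis >= 0)
  z <- trace$z
  B <- map$boundaries
  idx <- findInterval(z, B) + 1L
  n <- length(z)
  lab <- integer(n)
  if (n > 0) {
    lab[1] <- idx[1]
    for (i in seq_len(n)[-1]) {
      cur <- lab[i - 1L]
      if (idx[i] == cur) { lab[i] <- cur; next }
      hi <- if (cur <= length(B)) B[cur] else Inf
      lo <- if (cur >= 2L) B[cur - 1L] else -Inf
      lab[i] <- if (z[i] >= hi + hysteresis || z[i] <= lo - hysteresis)
        idx[i] else cur
    }
  }
  out <- data.frame(time_ns = trace$time_ns, z = z)
  out$label <- factor(map$labels[lab], levels = map$labels)
  if (!is.null(trace$particle_id)) out$particle_id <- trace$particle_id
  out
}
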