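#' Construct a pore frame
#'
#' A pore frame is the instantaneous coordinate system of the conduction
#' pathway: an origin on the pore axis and a unit axis vector oriented
#' from the cytoplasm toward the extracellular filter exit, so that
#' outward permeation is always +z.
#'
#' @param origin Numeric 3-vector (A).
#' @param axis Numeric 3-vector; normalized internally.
#' @param time Optional frame time (ns).
#' @return An object of class `pore_frame` with unit `axis` (|axis| = 1
#'   to within 1e-9) and an orthonormal in-plane basis `e1`, `e2`.
#' @export
pore_frame <- function(origin, axis, time = NA_real_) {
  origin <- as.numeric(origin); axis <- as.numeric(axis)
  stopifnot(length(origin) == 3, length(axis) == 3)
  n <- sqrt(sum(axis^2))
  if (!is.finite(n) || n < 1e-9) stop("pore axis has (near-)zero length")
  axis <- axis / n
  # deterministic in-plane basis: project lab x (or y) off the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  structure(list(origin = origin, axis = axis, e1 = e1, e2 = e2,
                 time = time),
            class = "pore_frame")
}

#' @export
print.pore_frame <- function(x, ...) {
  cat("Pore frame\n")
  cat("  origin:", sprintf("%.3f", x$origin), "A\n")
  cat("  axis:  ", sprintf("%.6f", x$axis), "\n")
  if (!is.na(x$time)) cat("  time:  ", x$time, "ns\n")
  invisible(x)
}

#' Compute the pore frame from two reference atom selections
#'
#' The axis is defined by two four-atom selections, one per subunit, on
#' either end of the pore (by convention the C-beta atoms of the filter
#' tyrosine, Y376, above and of the S6 valine, V409, below). The origin
#' is the midpoint of the two centroids and the axis points from the
#' lower centroid to the upper one.
#'
#' @param upper_xyz 4x3 matrix of the upper (extracellular-side) atoms.
#' @param lower_xyz 4x3 matrix of the lower (cytoplasmic-side) atoms.
#' @param time Optional frame time (ns).
#' @return A [pore_frame()].
#' @export
compute_pore_frame <- function(upper_xyz, lower_xyz, time = NA_real_) {
  upper_xyz <- as.matrix(upper_xyz); lower_xyz <- as.matrix(lower_xyz)
  stopifnot(ncol(upper_xyz) == 3, ncol(lower_xyz) == 3)
  cu <- colMeans(upper_xyz)
  cl <- colMeans(lower_xyz)
  ax <- cu - cl
  if (sqrt(sum(ax^2)) < 1e-9)
    stop("upper and lower centroids coincide; pore axis undefined")
  pore_frame(origin = (cu + cl) / 2, axis = ax, time = time)
}

#' Project points into a pore frame
#'
#' For each point p: `z = (p - origin) . axis` is the axial coordinate,
#' `r = |p - origin - z*axis|` the radial distance from the axis, and
#' `(xp, yp)` the in-plane components in the frame's fixed basis. The
#' projection is isometric per point: `z^2 + r^2 = |p - origin|^2`.
#'
#' @param xyz n x 3 matrix of coordinates (A).
#' @param frame A [pore_frame()].
#' @return data.frame with columns `z`, `r`, `xp`, `yp`.
#' @export
project_points <- function(xyz, frame) {
  stopifnot(inherits(frame, "pore_frame"))
  xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  rel <- sweep(xyz, 2, frame$origin)
  z  <- as.numeric(rel %*% frame$axis)
  xp <- as.numeric(rel %*% frame$e1)
  yp <- as.numeric(rel %*% frame$e2)
  data.frame(z = z, r = sqrt(xp^2 + yp^2), xp = xp, yp = yp)
}

#' Project a raw trace into pore-frame coordinates
#'
#' @param trace Raw trace data.frame with columns `particle_id`,
#'   `time_ns`, `x`, `y`, `z` (see [read_trace_table()]).
#' @param frame Either a single [pore_frame()] applied to every time
#'   point, or a list of frames whose `time` fields must match the trace
#'   times exactly (per-frame axis for a flexible protein).
#' @return data.frame with columns `particle_id`, `time_ns`, `z`, `r`,
#'   `xp`, `yp`.
#' @export
project_trace <- function(trace, frame) {
  stopifnot(all(c("particle_id", "time_ns", "x", "y", "z") %in% names(trace)))
  xyz <- as.matrix(trace[, c("x", "y", "z")])
  if (inherits(frame, "pore_frame")) {
    pr <- project_points(xyz, frame)
  } else if (is.list(frame)) {
    ft <- vapply(frame, function(f) f$time, numeric(1))
    idx <- match(trace$time_ns, ft)
    if (anyNA(idx))
      stop("no pore frame supplied for time(s): ",
           paste(utils::head(trace$time_ns[is.na(idx)], 5), collapse = ", "))
    pr <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
      project_points(xyz[i, , drop = FALSE], frame[[idx[i]]])))
  } else stop("'frame' must be a pore_frame or a list of pore_frames")
  data.frame(particle_id = trace$particle_id, time_ns = trace$time_ns, pr)
}
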