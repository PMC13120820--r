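#' Planar (membrane-plane) position histogram
#'
#' Normalized 2D probability histogram of ligand or ion positions
#' projected on the plane perpendicular to the pore, with the origin on
#' the pore axis. Useful to distinguish on-axis (open-pore blocking)
#' from off-axis (wall-bound) binding modes.
#'
#' @param xp,yp In-plane coordinates (A) from [project_points()].
#' @param extent Half-extent of the histogram (A, default 15); samples
#'   outside are discarded.
#' @param bin_width Bin width (A, default 0.5).
#' @return List of class `planar_histogram`: `x`, `y` (bin centers),
#'   `counts` (matrix), `p` (matrix, sums to 1), `n` (samples binned).
#' @export
planar_histogram <- function(xp, yp, extent = 15, bin_width = 0.5) {
  stopifnot(length(xp) == length(yp), extent > 0, bin_width > 0)
  breaks <- seq(-extent, extent, by = bin_width)
  keep <- xp >= -extent & xp < breaks[length(breaks)] &
          yp >= -extent & yp < breaks[length(breaks)]
  if (!any(keep)) stop("no samples inside the histogram extent")
  ix <- findInterval(xp[keep], breaks, rightmost.closed = TRUE)
  iy <- findInterval(yp[keep], breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  mids <- breaks[-length(breaks)] + bin_width / 2
  structure(list(x = mids, y = mids, counts = counts,
                 p = counts / sum(counts), n = sum(counts)),
            class = "planar_histogram")
}

#' Axial-deviation statistics of a bound ligand atom
#'
#' Summarizes how far a reference atom strays from the pore axis: the
#' fraction of snapshots beyond a radial threshold (default the 2 A
#' criterion used to call a blocker "on-axis") and quantiles of r.
#'
#' @param r Radial distances from the pore axis (A).
#' @param threshold Radial threshold (A, default 2).
#' @return List with `median_r`, `fraction_above`, `threshold`, and
#'   `quantiles` (25/50/75/90/95%).
#' @export
axial_deviation_stats <- function(r, threshold = 2) {
  stopifnot(is.numeric(r), threshold >= 0)
  list(median_r = stats::median(r),
       fraction_above = mean(r > threshold),
       threshold = threshold,
       quantiles = stats::quantile(r, c(0.25, 0.5, 0.75, 0.9, 0.95)))
}

#' 3D occupancy density map
#'
#' Bins atom positions over all snapshots onto a regular 3D grid and
#' sigma-normalizes the voxel values ((value - mean) / sd over the
#' grid), the convention used for contoured density meshes.
#'
#' @param xyz n x 3 matrix of sample coordinates (A), pooled over atoms
#'   and frames.
#' @param spacing Grid spacing (A, default 1).
#' @param extent Optional 3 x 2 matrix of (lo, hi) per axis; default
#'   spans the samples.
#' @param contour_level Contour level stored with the map (default
#'   0.04, in sigma units).
#' @return List of class `occupancy_map`: `axes` (bin-center vectors),
#'   `origin`, `spacing`, `counts` (3D array), `sigma` (normalized
#'   array), `contour_level`, `n` (samples binned).
#' @export
occupancy_map <- function(xyz, spacing = 1, extent = NULL,
                          contour_level = 0.04) {
  xyz <- matrix(as.numeric(as.matrix(xyz)), ncol = 3)
  stopifnot(spacing > 0, nrow(xyz) > 0)
  if (is.null(extent))
    extent <- t(apply(xyz, 2, range))
  breaks <- lapply(1:3, function(d)
    seq(extent[d, 1], extent[d, 2] + spacing - 1e-12, by = spacing))
  dims <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- vapply(1:3, function(d)
    findInterval(xyz[, d], breaks[[d]]), integer(nrow(xyz)))
  idx <- matrix(idx, ncol = 3)
  keep <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
          idx[, 2] >= 1 & idx[, 2] <= dims[2] &
          idx[, 3] >= 1 & idx[, 3] <= dims[3]
  idx <- idx[keep, , drop = FALSE]
  counts <- array(0, dim = dims)
  flat <- (idx[, 3] - 1) * dims[1] * dims[2] + (idx[, 2] - 1) * dims[1] + idx[, 1]
  tab <- tabulate(flat, nbins = prod(dims))
  counts[] <- tab
  s <- stats::sd(as.numeric(counts))
  if (!is.finite(s) || s == 0)
    stop("degenerate grid: all voxel counts equal; cannot sigma-normalize")
  sigma <- (counts - mean(counts)) / s
  axes <- lapply(breaks, function(b) b[-length(b)] + spacing / 2)
  structure(list(axes = axes,
                 origin = vapply(breaks, `[`, numeric(1), 1),
                 spacing = spacing, counts = counts, sigma = sigma,
                 contour_level = contour_level, n = sum(keep)),
            class = "occupancy_map")
}

#' Write an occupancy map in OpenDX format
#'
#' Exports the sigma-normalized grid as an OpenDX volumetric file (the
#' format molecular viewers read for density meshes), z fastest
#' varying.
#'
#' @param map An [occupancy_map()].
#' @param path Output `.dx` path.
#' @param field `"sigma"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path, field = c("sigma", "counts")) {
  field <- match.arg(field)
  stopifnot(inherits(map, "occupancy_map"))
  a <- map[[field]]
  d <- dim(a)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# kvperm occupancy map (%s), contour level %g", field,
            map$contour_level),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f",
            map$origin[1], map$origin[2], map$origin[3]),
    sprintf("delta %.6f 0 0", map$spacing),
    sprintf("delta 0 %.6f 0", map$spacing),
    sprintf("delta 0 0 %.6f", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX stores grid values with the last index (z) varying fastest
  flat <- numeric(prod(d))
  k <- 1L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    flat[k:(k + d[3] - 1L)] <- a[i, j, ]
    k <- k + d[3]
  }
  n3 <- (length(flat) %/% 3) * 3
  if (n3 > 0)
    writeLines(apply(matrix(sprintf("%.6g", flat[seq_len(n3)]), ncol = 3,
                            byrow = TRUE), 1, paste, collapse = " "), con)
  if (n3 < length(flat))
    writeLines(paste(sprintf("%.6g", flat[(n3 + 1):length(flat)]),
                     collapse = " "), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}
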