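#' Read a plain-text ion/ligand trace table
#'
#' Reads the documented CSV trace format with columns `particle_id`,
#' `time_ns`, `x`, `y`, `z` (coordinates in Angstrom). Rows may appear in
#' any order; the table is sorted by particle and time on input so that a
#' shuffled file yields exactly the same result as a sorted one.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` ordered by `(particle_id, time_ns)` with class
#'   `trace_table`. An empty file (header only) gives a zero-row table.
#' @seealso [write_trace_table()], [split_traces()]
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stop("trace table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_trace_table(df)
}

#' Validate and order a raw trace table
#'
#' @param df A data.frame with columns `particle_id`, `time_ns`, `x`, `y`, `z`.
#' @return The validated table, sorted by `(particle_id, time_ns)`.
#' @export
as_trace_table <- function(df) {
  need <- c("particle_id", "time_ns", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$time_ns)) ||
      any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("trace table contains non-finite values")
  df <- df[order(df$particle_id, df$time_ns), , drop = FALSE]
  dup <- duplicated(df[, c("particle_id", "time_ns")])
  if (any(dup))
    stop("duplicate (particle_id, time_ns) pairs in trace table")
  rownames(df) <- NULL
  class(df) <- c("trace_table", "data.frame")
  df
}

#' Write a trace table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read cycle reproduces the doubles bit-compatibly.
#'
#' @param df A trace table (see [read_trace_table()] for the format).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(df, path) {
  out <- as.data.frame(df)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a trace table into per-particle traces
#'
#' @param df A trace table.
#' @return A named list of data.frames, one per `particle_id`, each sorted
#'   by time with strictly increasing `time_ns`.
#' @export
split_traces <- function(df) {
  df <- as_trace_table(as.data.frame(df))
  if (nrow(df) == 0) return(list())
  out <- split(df, df$particle_id)
  lapply(out, function(tr) {
    rownames(tr) <- NULL
    if (any(diff(tr$time_ns) <= 0))
      stop("non-monotone times for particle ", tr$particle_id[1])
    class(tr) <- "data.frame"
    tr
  })
}

#' Load ion/ligand traces from a file
#'
#' Thin convenience wrapper: reads the documented CSV trace table and
#' returns raw per-particle traces (not yet projected into a pore frame).
#' Standard binary MD trajectories can be brought in through
#' `bio3d::read.dcd()` and converted to this table.
#'
#' @param path CSV trace table path.
#' @return Named list of raw traces (columns `particle_id`, `time_ns`,
#'   `x`, `y`, `z`).
#' @export
load_traces <- function(path) {
  split_traces(read_trace_table(path))
}

#' Unwrap a periodic coordinate series
#'
#' Removes periodic-boundary jumps from a coordinate trace: any step
#' larger than half the box length is shifted by an integer number of box
#' lengths so the trace is continuous.
#'
#' @param z Numeric coordinate series (A).
#' @param box Box length along the coordinate (A).
#' @return Unwrapped series, same length; no consecutive step exceeds
#'   `box/2` in magnitude.
#' @export
unwrap_coord <- function(z, box) {
  stopifnot(is.numeric(z), box > 0)
  if (length(z) < 2) return(z)
  d <- diff(z)
  shift <- -box * round(d / box)
  z + c(0, cumsum(shift))
}
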