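#' Read a flat key-value configuration file
#'
#' Parses a plain-text configuration of `key = value` lines. Blank
#' lines and lines starting with `#` are ignored; values that parse as
#' numbers are returned numeric, everything else as character.
#'
#' @param path Configuration file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param x Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
  }, "")
  writeLines(paste(names(x), "=", vals), path)
  invisible(path)
}

#' Build a knock-on configuration from a config file
#'
#' Recognized keys (all optional): `lambda_load`, `lambda_knock`,
#' `lambda_return`, `blocker`, `attenuation`, `sigma`, `tau`,
#' `frame_interval`, `duration_us`, `seed`, and the site-map keys
#' `z_scav`, `z_s4`, `z_s3`, `z_s2`, `z_s1`, `z_s0`, `gate_z`,
#' `exit_z`.
#'
#' @param path Config file path.
#' @return A [knockon_config()].
#' @export
knockon_config_from_file <- function(path) {
  cf <- read_config(path)
  site_keys <- c("z_scav", "z_s4", "z_s3", "z_s2", "z_s1", "z_s0")
  map <- if (all(site_keys %in% names(cf))) {
    site_map(stats::setNames(as.numeric(cf[site_keys]), .site_names),
             gate_z = if (!is.null(cf$gate_z)) cf$gate_z else
               as.numeric(cf[["z_scav"]]) - 9,
             exit_z = cf$exit_z)
  } else default_site_map()
  args <- cf[intersect(names(cf),
                       c("lambda_load", "lambda_knock", "lambda_return",
                         "blocker", "attenuation", "sigma", "tau",
                         "frame_interval", "duration_us", "seed"))]
  do.call(knockon_config, c(list(map = map), args))
}
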