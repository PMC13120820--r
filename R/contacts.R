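#' Contact counting specification
#'
#' Defines the ligand-protein contact rule: a contact is a pair of one
#' side-chain carbon atom in a listed hydrophobic residue and one
#' ligand carbon/sulfur atom within the cutoff distance (boundary
#' inclusive). Backbone C and CA atoms are excluded; for prolines the
#' ring carbons CB/CG/CD count as side chain.
#'
#' @param resno Residue numbers monitored (default the S6 cluster
#'   V398, I401, I405, P406, V409).
#' @param cutoff Distance cutoff (A, default 4.5); must be positive.
#' @param ligand_elements Ligand elements counted (default C and S).
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(resno = c(398, 401, 405, 406, 409),
                         cutoff = 4.5, ligand_elements = c("C", "S")) {
  stopifnot(length(resno) > 0, cutoff > 0, length(ligand_elements) > 0)
  structure(list(resno = resno, cutoff = cutoff,
                 ligand_elements = ligand_elements),
            class = "contact_spec")
}

.sidechain_carbons <- function(protein, spec) {
  sel <- protein$resno %in% spec$resno &
    protein$element == "C" & !(protein$elety %in% c("C", "CA"))
  protein[sel, , drop = FALSE]
}

#' Count ligand-protein contacts in one snapshot
#'
#' Tallies, per residue and per subunit, the number of (side-chain C,
#' ligand C/S) atom pairs within the cutoff. A snapshot may show
#' multiple contacts with each side chain, sometimes in two different
#' subunits.
#'
#' @param protein Snapshot atom table: columns `resno`, `resid`,
#'   `chain`, `elety`, `element`, `x`, `y`, `z`.
#' @param ligand Ligand atom table: columns `element`, `x`, `y`, `z`.
#' @param spec A [contact_spec()].
#' @return data.frame `resno`, `resid`, `chain`, `count` covering every
#'   (monitored residue, subunit) combination present in the snapshot,
#'   including zero counts.
#' @export
count_contacts <- function(protein, ligand, spec = contact_spec()) {
  stopifnot(inherits(spec, "contact_spec"))
  p <- .sidechain_carbons(protein, spec)
  l <- ligand[ligand$element %in% spec$ligand_elements, , drop = FALSE]
  if (nrow(p) == 0) stop("no side-chain carbon atoms match the contact spec")
  if (nrow(l) == 0) stop("no ligand atoms match the contact spec")
  pm <- as.matrix(p[, c("x", "y", "z")])
  lm <- as.matrix(l[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm)
  hits <- rowSums(d2 <= spec$cutoff^2 + 1e-12)
  key <- interaction(p$resno, p$chain, drop = FALSE)
  grid <- expand.grid(resno = sort(unique(p$resno)),
                      chain = sort(unique(protein$chain)),
                      stringsAsFactors = FALSE)
  grid$resid <- p$resid[match(grid$resno, p$resno)]
  cnt <- tapply(hits, key, sum)
  grid$count <- as.integer(cnt[paste(grid$resno, grid$chain, sep = ".")])
  grid$count[is.na(grid$count)] <- 0L
  grid[, c("resno", "resid", "chain", "count")]
}

#' Build a contact series over trajectory snapshots
#'
#' @param protein_frames List of per-snapshot protein atom tables.
#' @param ligand_frames List of per-snapshot ligand atom tables (same
#'   length).
#' @param times Snapshot times (ns).
#' @param spec A [contact_spec()].
#' @return data.frame `time_ns`, `resno`, `resid`, `chain`, `count`
#'   with class `contact_series`.
#' @export
contact_series <- function(protein_frames, ligand_frames, times = NULL,
                           spec = contact_spec()) {
  stopifnot(length(protein_frames) == length(ligand_frames))
  if (is.null(times)) times <- seq_along(protein_frames) - 1
  out <- do.call(rbind, lapply(seq_along(protein_frames), function(i) {
    cc <- count_contacts(protein_frames[[i]], ligand_frames[[i]], spec)
    cbind(time_ns = times[i], cc)
  }))
  class(out) <- c("contact_series", "data.frame")
  out
}

#' Per-residue contact exceedance curves
#'
#' For each monitored residue, the fraction of snapshots in which at
#' least `n` contacts were observed, as a function of `n` (the
#' empirical survival function of the per-snapshot contact count).
#' Curves start at 1 for n = 0, are non-increasing and sum (over
#' n >= 1) to the mean contact count.
#'
#' @param series A [contact_series()].
#' @param per_subunit If `TRUE`, curves are computed per (residue,
#'   subunit); default sums counts over subunits per snapshot.
#' @return data.frame `resno` (, `chain`), `n`, `p`.
#' @export
contact_exceedance <- function(series, per_subunit = FALSE) {
  stopifnot(nrow(series) > 0)
  grp <- if (per_subunit) interaction(series$resno, series$chain, drop = TRUE)
         else series$resno
  parts <- split(series, grp)
  out <- do.call(rbind, lapply(parts, function(s) {
    tot <- tapply(s$count, s$time_ns, sum)
    nmax <- max(tot)
    n <- 0:nmax
    p <- vapply(n, function(k) mean(tot >= k), numeric(1))
    base <- data.frame(resno = s$resno[1], n = n, p = p)
    if (per_subunit) base$chain <- s$chain[1]
    base
  }))
  rownames(out) <- NULL
  out
}

#' Fraction of snapshots contacting multiple subunits
#'
#' Fraction of snapshots in which a given residue is contacted in at
#' least `min_subunits` different subunits simultaneously.
#'
#' @param series A [contact_series()].
#' @param resno Residue number (must be monitored in the series).
#' @param min_subunits Minimum number of simultaneously contacted
#'   subunits (default 2).
#' @return Fraction in [0, 1].
#' @export
simultaneous_subunit_fraction <- function(series, resno, min_subunits = 2) {
  s <- series[series$resno == resno, , drop = FALSE]
  if (nrow(s) == 0) stop("residue ", resno, " not present in contact series")
  nsub <- tapply(s$count > 0, s$time_ns, sum)
  mean(nsub >= min_subunits)
}
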