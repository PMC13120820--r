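#' Load a channel structure from a PDB file
#'
#' Reads a (tetrameric) channel structure via `bio3d::read.pdb` and
#' returns a light-weight atom table keyed by residue number, atom name
#' and subunit (chain). Residue numbering is taken verbatim from the
#' file.
#'
#' @param path PDB file path.
#' @return Object of class `kv_topology`: a list with element `atoms`, a
#'   data.frame with columns `elety` (atom name), `element`, `resid`,
#'   `resno`, `chain`, `x`, `y`, `z`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  atoms <- data.frame(
    elety = trimws(a$elety), element = trimws(elem),
    resid = trimws(a$resid), resno = a$resno, chain = a$chain,
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, path = path), class = "kv_topology")
}

#' @export
print.kv_topology <- function(x, ...) {
  cat("kv_topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "subunit(s) [",
      paste(sort(unique(x$atoms$chain)), collapse = " "), "]\n")
  invisible(x)
}

#' Select one atom per subunit across the tetramer
#'
#' Channel selections (e.g. the Y376 C-beta atoms used to define the
#' pore axis) must resolve to exactly one atom in each of the four
#' subunits; anything else raises an error naming what is absent.
#'
#' @param topology A `kv_topology`.
#' @param resno Residue number.
#' @param elety Atom name (e.g. `"CB"`, `"O"`, `"OG1"`, `"CA"`).
#' @param n_subunits Expected number of subunits (default 4).
#' @return data.frame of the matched atoms, one row per subunit, ordered
#'   by chain id.
#' @export
select_atoms <- function(topology, resno, elety, n_subunits = 4) {
  stopifnot(inherits(topology, "kv_topology"))
  a <- topology$atoms
  sel <- a[a$resno == resno & a$elety == elety, , drop = FALSE]
  chains <- sort(unique(a$chain))
  if (length(chains) < n_subunits)
    stop("topology has ", length(chains), " subunit(s); ", n_subunits,
         " required")
  chains <- chains[seq_len(n_subunits)]
  hit <- table(factor(sel$chain, levels = chains))
  if (any(hit != 1)) {
    bad <- names(hit)[hit != 1]
    stop("selection resno ", resno, " atom ", elety,
         " does not resolve to one atom per subunit; offending subunit(s): ",
         paste(bad, collapse = ", "))
  }
  sel <- sel[order(sel$chain), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' @rdname select_atoms
#' @param sel A selection returned by `select_atoms`.
#' @export
atom_xyz <- function(sel) as.matrix(sel[, c("x", "y", "z")])

#' Write a synthetic tetrameric channel structure
#'
#' Generates a toy, fourfold-symmetric Kv-like pore structure carrying
#' the residues the analyses rely on (selectivity filter T373-Y376 and
#' the S6 stretch V398-V409) at realistic axial positions, and writes it
#' as a PDB file through `bio3d::write.pdb`. This is a synthetic stand-in
#' for a real channel structure, intended for tests and examples.
#'
#' @param path Output PDB path.
#' @param n_chains Number of subunits to write (default 4; fewer gives a
#'   deliberately defective structure for error-path tests).
#' @param z_shift Rigid shift applied to all z coordinates (A).
#' @return `path`, invisibly.
#' @export
write_toy_channel_pdb <- function(path, n_chains = 4, z_shift = 0) {
  # per-residue atom templates: name, radial offset from axis (A), z (A)
  res <- list(
    list(resno = 373, resid = "THR",
         atoms = list(c("N", 2.6, -3.5), c("CA", 2.2, -3.0),
                      c("C", 1.9, -2.4), c("O", 1.4, -2.0),
                      c("CB", 3.2, -3.8), c("OG1", 1.6, -5.0),
                      c("CG2", 4.0, -4.2))),
    list(resno = 374, resid = "VAL",
         atoms = list(c("N", 2.6, -0.6), c("CA", 2.2, 0.0),
                      c("C", 1.9, 0.6), c("O", 1.4, 1.0),
                      c("CB", 3.4, -0.3))),
    list(resno = 375, resid = "GLY",
         atoms = list(c("N", 2.6, 2.4), c("CA", 2.2, 3.0),
                      c("C", 1.9, 3.6), c("O", 1.4, 4.0))),
    list(resno = 376, resid = "TYR",
         atoms = list(c("N", 2.6, 5.4), c("CA", 2.2, 6.0),
                      c("C", 1.9, 6.6), c("O", 1.4, 7.0),
                      c("CB", 4.2, 6.0))),
    list(resno = 398, resid = "VAL",
         atoms = list(c("N", 7.6, -7.4), c("CA", 7.4, -8.0),
                      c("C", 7.6, -8.6), c("O", 7.8, -8.9),
                      c("CB", 6.6, -8.2), c("CG1", 6.2, -7.6),
                      c("CG2", 6.4, -8.9))),
    list(resno = 401, resid = "ILE",
         atoms = list(c("N", 7.4, -10.4), c("CA", 7.2, -11.0),
                      c("C", 7.4, -11.6), c("O", 7.6, -11.9),
                      c("CB", 6.4, -11.2), c("CG1", 6.0, -10.6),
                      c("CG2", 6.2, -11.9), c("CD1", 5.4, -10.9))),
    list(resno = 405, resid = "ILE",
         atoms = list(c("N", 7.0, -13.4), c("CA", 6.8, -14.0),
                      c("C", 7.0, -14.6), c("O", 7.2, -14.9),
                      c("CB", 6.0, -14.2), c("CG1", 5.6, -13.6),
                      c("CG2", 5.8, -14.9), c("CD1", 5.0, -13.9))),
    list(resno = 406, resid = "PRO",
         atoms = list(c("N", 6.4, -15.6), c("CA", 6.0, -16.0),
                      c("C", 6.2, -16.6), c("O", 6.4, -16.9),
                      c("CB", 5.4, -16.2), c("CG", 5.2, -15.6),
                      c("CD", 5.8, -15.2))),
    list(resno = 408, resid = "PRO",
         atoms = list(c("N", 5.9, -18.6), c("CA", 5.5, -19.0),
                      c("C", 5.7, -19.6), c("O", 5.9, -19.9),
                      c("CB", 4.9, -19.2), c("CG", 4.7, -18.6),
                      c("CD", 5.3, -18.2))),
    list(resno = 409, resid = "VAL",
         atoms = list(c("N", 5.8, -20.4), c("CA", 5.6, -21.0),
                      c("C", 5.8, -21.6), c("O", 6.0, -21.9),
                      c("CB", 5.0, -20.6), c("CG1", 4.6, -20.0),
                      c("CG2", 4.8, -21.3))))
  chains <- LETTERS[seq_len(n_chains)]
  rows <- list()
  for (ci in seq_along(chains)) {
    ang <- (ci - 1) * pi / 2
    for (rr in res) {
      for (at in rr$atoms) {
        rad <- as.numeric(at[2]); z <- as.numeric(at[3]) + z_shift
        # small per-atom azimuthal spread so atoms do not overlap
        phi <- ang + 0.07 * (match(at[1], vapply(rr$atoms, `[`, "", 1)) - 1)
        rows[[length(rows) + 1]] <- data.frame(
          elety = at[1], resid = rr$resid, resno = rr$resno,
          chain = chains[ci],
          x = round(rad * cos(phi), 3), y = round(rad * sin(phi), 3),
          z = round(z, 3), stringsAsFactors = FALSE)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  xyz <- as.numeric(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   resid = atoms$resid, eleno = seq_len(nrow(atoms)),
                   elety = atoms$elety, chain = atoms$chain)
  invisible(path)
}

#' Pore frame of a topology from the standard axis atoms
#'
#' Convenience wrapper: builds the pore frame from the C-beta atoms of
#' the filter tyrosine (default residue 376) and of the S6 valine
#' (default residue 409) in the four subunits, and checks the
#' orientation convention (the filter-side centroid projects above the
#' gate-side centroid, so +z points extracellularly).
#'
#' @param topology A `kv_topology`.
#' @param upper_resno,lower_resno Residue numbers of the axis atoms.
#' @param elety Atom name used on both ends (default `"CB"`).
#' @return A [pore_frame()].
#' @export
topology_pore_frame <- function(topology, upper_resno = 376,
                                lower_resno = 409, elety = "CB") {
  up <- atom_xyz(select_atoms(topology, upper_resno, elety))
  lo <- atom_xyz(select_atoms(topology, lower_resno, elety))
  fr <- compute_pore_frame(upper_xyz = up, lower_xyz = lo)
  zu <- mean(project_points(up, fr)$z)
  zl <- mean(project_points(lo, fr)$z)
  if (zu <= zl) stop("pore frame orientation check failed")
  fr
}
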