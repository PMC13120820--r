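# shared fixtures built in code

toy_pdb_path <- local({
  path <- NULL
  function() {
    if (is.null(path)) {
      path <<- file.path(tempdir(), "toy_channel.pdb")
      write_toy_channel_pdb(path)
    }
    path
  }
})

# rotation matrix about a random axis (Rodrigues)
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# central finite-difference derivative
fd_grad <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# symmetric 8-atom axis fixture: 4 upper at z = +5, 4 lower at z = -5
axis_atoms <- function() {
  ang <- (0:3) * pi / 2
  upper <- cbind(3 * cos(ang), 3 * sin(ang), 5)
  lower <- cbind(4 * cos(ang + pi / 4), 4 * sin(ang + pi / 4), -5)
  list(upper = upper, lower = lower)
}

# brute-force all-pairs contact oracle (independent of count_contacts)
brute_contacts <- function(protein, ligand, cutoff = 4.5,
                           ligand_elements = c("C", "S"),
                           resno = c(398, 401, 405, 406, 409)) {
  total <- 0L
  for (i in seq_len(nrow(protein))) {
    pa <- protein[i, ]
    if (!(pa$resno %in% resno) || pa$element != "C" ||
        pa$elety %in% c("C", "CA")) next
    for (j in seq_len(nrow(ligand))) {
      la <- ligand[j, ]
      if (!(la$element %in% ligand_elements)) next
      d <- sqrt((pa$x - la$x)^2 + (pa$y - la$y)^2 + (pa$z - la$z)^2)
      if (d <= cutoff) total <- total + 1L
    }
  }
  total
}

# random contact-fixture snapshot over several residues/subunits
random_contact_snapshot <- function(n_protein = 50, n_ligand = 20) {
  resnos <- c(398, 401, 405, 406, 409, 400)  # 400 is a decoy, not monitored
  elety <- c("CB", "CG", "CD", "C", "CA")
  protein <- data.frame(
    resno = sample(resnos, n_protein, replace = TRUE),
    resid = "XXX",
    chain = sample(LETTERS[1:4], n_protein, replace = TRUE),
    elety = sample(elety, n_protein, replace = TRUE),
    element = sample(c("C", "N", "O"), n_protein, replace = TRUE,
                     prob = c(0.8, 0.1, 0.1)),
    x = runif(n_protein, -8, 8), y = runif(n_protein, -8, 8),
    z = runif(n_protein, -8, 8), stringsAsFactors = FALSE)
  ligand <- data.frame(
    element = sample(c("C", "S", "H", "N"), n_ligand, replace = TRUE,
                     prob = c(0.6, 0.2, 0.1, 0.1)),
    x = runif(n_ligand, -8, 8), y = runif(n_ligand, -8, 8),
    z = runif(n_ligand, -8, 8), stringsAsFactors = FALSE)
  list(protein = protein, ligand = ligand)
}
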