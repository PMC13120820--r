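#' Dihedral biasing potential
#'
#' Evaluates the weak structure-preserving dihedral bias used to keep
#' long trajectories near an experimental geometry:
#' \deqn{U(\theta) = k \sum_{m=1}^{6} (-1)^m
#'   [1 + \cos(m\theta - m(\theta_{expt} - 180))]/m!}
#' with angles in degrees and `k` defaulting to 1 kB*T at 298 K. The
#' potential is 360-degree periodic and stationary at `theta_expt` for
#' every `theta_expt` and `k`.
#'
#' Note on sign: evaluated exactly as printed (`convention =
#' "printed"`), the stationary point at `theta_expt` is an energy
#' maximum (`U(theta_expt) > U(theta_expt + 180)` for `k > 0`), so the
#' form that actually restrains toward `theta_expt` is the sign-flipped
#' one (`convention = "restraining"`). Both are exposed; the
#' discrepancy is deliberate and documented rather than silently fixed.
#'
#' @param theta Dihedral angle(s), degrees.
#' @param theta_expt Reference (experimental) angle, degrees, in
#'   (-180, 180].
#' @param k Force constant (kcal/mol); default 1 kB*T at 298 K
#'   (~0.592 kcal/mol).
#' @param convention `"printed"` (default) or `"restraining"`.
#' @return List with `energy` (kcal/mol) and `gradient`
#'   (kcal/mol/degree), both vectorized over `theta`.
#' @export
dihedral_bias <- function(theta, theta_expt, k = .kBT_298,
                          convention = c("printed", "restraining")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(k), all(is.finite(theta)),
            theta_expt > -180, theta_expt <= 180)
  s <- if (convention == "printed") 1 else -1
  drad <- (theta - (theta_expt - 180)) * pi / 180
  e <- numeric(length(theta)); g <- numeric(length(theta))
  for (m in 1:6) {
    e <- e + (-1)^m * (1 + cos(m * drad)) / factorial(m)
    g <- g + (-1)^m * (-m * sin(m * drad)) / factorial(m)
  }
  list(energy = s * k * e,
       gradient = s * k * g * pi / 180)
}

#' Flat-bottom confinement potential
#'
#' Half-harmonic wall: zero for `d <= d_o`, `0.5 k (d - d_o)^2` beyond.
#' Used to confine a ligand inside a cylindrical volume coaxial with
#' the pore (radial variant, `d_o = 10` A by default) or to keep it on
#' the cytoplasmic side (axial-projection variant, `d_o = 15` A). The
#' potential is continuous with continuous first derivative at `d_o`.
#'
#' @param d Distance coordinate(s) (A); radial distance to the axis or
#'   axial projection, depending on the variant.
#' @param d_o Flat-bottom radius (A, default 10).
#' @param k Force constant (kcal/mol/A^2, default 100).
#' @return List with `energy` (kcal/mol) and `gradient` (kcal/mol/A).
#' @examples
#' flat_bottom(12, d_o = 10, k = 100)$energy  # 200 kcal/mol
#' @export
flat_bottom <- function(d, d_o = 10, k = 100) {
  stopifnot(d_o >= 0, k >= 0)
  over <- pmax(d - d_o, 0)
  list(energy = 0.5 * k * over^2, gradient = k * over)
}

#' Constant-field representation of a transmembrane voltage
#'
#' Maps an applied voltage across a periodic box of height `L_z` to the
#' uniform electric field used in constant-field MD: `E = V / L_z`,
#' expressed both in mV/A and in the molecular-mechanics unit
#' kcal mol^-1 A^-1 e^-1 via the conversion
#' 1 kcal mol^-1 A^-1 e^-1 = [kcal_per_mol_e_mV()] mV/A (~43.4).
#'
#' @param voltage_mV Transmembrane voltage (mV).
#' @param L_z Box height along the membrane normal (A); must be > 0.
#' @return Object of class `field_spec` with `voltage_mV`, `L_z`,
#'   `field_mV_per_A` and `field_kcal` (kcal mol^-1 A^-1 e^-1).
#' @examples
#' voltage_field(100, 92)$field_kcal  # ~0.025 kcal/mol/A/e
#' @export
voltage_field <- function(voltage_mV, L_z) {
  if (!is.finite(L_z) || L_z <= 0) stop("box height L_z must be positive")
  f_mV <- voltage_mV / L_z
  structure(list(voltage_mV = voltage_mV, L_z = L_z,
                 field_mV_per_A = f_mV,
                 field_kcal = f_mV / kcal_per_mol_e_mV()),
            class = "field_spec")
}

#' Voltage corresponding to a constant field (inverse mapping)
#'
#' @param field_kcal Field in kcal mol^-1 A^-1 e^-1.
#' @param L_z Box height (A).
#' @return Voltage in mV.
#' @export
field_voltage <- function(field_kcal, L_z) {
  if (!is.finite(L_z) || L_z <= 0) stop("box height L_z must be positive")
  field_kcal * kcal_per_mol_e_mV() * L_z
}

#' Knock-on induction restraint energy
#'
#' Half-harmonic restraints that pull an ion within coordination
#' distance of the eight carbonyl oxygen atoms of the filter tyrosine
#' and glycine (Y376 and G375, all four subunits): for each target atom
#' at distance `d`, the energy is `0.5 k (d - d_target)^2` when
#' `d > d_target` and zero otherwise (no penalty for being closer).
#'
#' @param ion 3-vector, ion position (A).
#' @param targets 8 x 3 matrix of target carbonyl O positions (two per
#'   subunit); any other row count raises an error.
#' @param d_target Target coordination distance (A, default 3).
#' @param k Force constant (kcal/mol/A^2, default 3).
#' @return List with `energy` (kcal/mol) and `gradient` (3-vector,
#'   kcal/mol/A, with respect to the ion position).
#' @export
knockon_restraint <- function(ion, targets, d_target = 3, k = 3) {
  ion <- as.numeric(ion)
  targets <- as.matrix(targets)
  stopifnot(length(ion) == 3, d_target > 0, k >= 0)
  if (nrow(targets) != 8 || ncol(targets) != 3)
    stop("knock-on restraint requires exactly 8 target atoms (2 per subunit)")
  rel <- sweep(targets, 2, ion, "-")
  d <- sqrt(rowSums(rel^2))
  over <- pmax(d - d_target, 0)
  grad <- colSums((k * over / pmax(d, 1e-12)) * (-rel))
  list(energy = sum(0.5 * k * over^2), gradient = grad)
}
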