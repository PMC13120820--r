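---
title: "Methods: permeation, block and synthetic knock-on trajectories in kvperm"
author: "kvperm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permeation, block and synthetic knock-on trajectories in kvperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvperm)
```

`kvperm` analyzes ion permeation and small-molecule block in simulations
of voltage-gated K⁺ channels. This vignette documents the models and
procedures it implements, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the
synthetic-trajectory generator does and does not emulate.

## Pore frame and projection

All analyses work in cylindrical coordinates attached to the pore. The
axis is defined by two four-atom selections, one per subunit: the Cβ
atoms of the selectivity-filter tyrosine (residue 376) above and of the
S6 valine (residue 409) below. The origin is the midpoint of the two
centroids; the axis is the unit vector from the lower centroid to the
upper one, so +z always points extracellularly and outward permeation
is +z by construction (`topology_pore_frame()` enforces this
orientation and fails loudly if the convention is violated). Points
project as `z = (p − o)·a`, `r = |p − o − z a|`; the projection is
isometric per point (`z² + r² = |p − o|²`), which the test suite checks
on random clouds, together with equivariance of the frame under rigid
motions.

Two choices were open:

- **Per-frame vs. average axis.** `project_trace()` accepts either a
  single frame (applied to all times) or a per-snapshot list matched by
  time. A flexible protein drifts, so the per-frame route is the safer
  default in real trajectories; the synthetic generator, which has no
  protein, uses a fixed frame.
- **Periodic wrapping.** Raw MD coordinates wrap at the box boundary;
  `unwrap_coord()` removes any step larger than half the box length
  before projection. The analyses themselves assume continuous traces.

Units are Å, ns and kcal/mol throughout; residue numbering is taken
verbatim from the PDB file.

## Site map

Site centers derive from the time-averaged projected z of the filter
oxygen planes (backbone carbonyl O of residues 376, 375, 374, 373 and
the side-chain hydroxyl O of 373, averaged over the four subunits):
S1–S3 sit midway between consecutive carbonyl planes, S4 between the
threonine carbonyl and hydroxyl planes, S0 half an inter-plane gap
above the top plane, and S_cav at a configurable offset below the
hydroxyl plane. The offset defaults to 4 Å: the literature gives no
number for this transient cavity site, and 4 Å places it clearly below
the filter yet well above the gate; the qualitative observation that an
on-axis quaternary-ammonium blocker sits ~1.5 Å from S_cav is used only
as a sanity check, never as a calibration. Site boundaries are
midpoints between adjacent centers with half-a-gap end widths.

The cytoplasmic gate plane is the Cα plane of residue 406 by default;
408 is accepted via `gate_resno` because both prolines are used as gate
markers in practice, and nothing downstream depends on the distinction
beyond a ~3 Å shift of the gate plane.

Site assignment (`assign_sites()`) debounces boundary noise with a
hysteresis width of 1 Å by default: a label changes only when the ion
has left its current interval by at least that much. 1 Å is small
against the ~3 Å inter-site spacing but larger than typical frame-to-
frame jitter; additive noise below the hysteresis width provably causes
no label changes, which is tested with constructed square-wave signals.

## Permeation events and conductance

No formal definition of a "complete permeation event" exists in the
field's figure captions, so the package fixes one that is unambiguous
and single-pass computable: an excursion that starts below the gate
plane, visits at least one filter site (S4–S0), and ends above the
filter exit plane without first returning below the gate. Ions that
reach the filter but come back to the cytoplasmic side are not events.
The completion time is the first frame above the exit plane.

Conductance converts an event count n over a window T at voltage V to
`G = n·e/(T·|V|)`. With the canonical accounting of 45 events over the
24.5 µs field-on window (25 µs minus a 0.5 µs zero-field preamble) at
100 mV this gives 2.94 pS, i.e. 3 pS at integer rounding, and a mean
inter-event time of 0.54 µs (~one ion per 0.5 µs). Whether the window
is taken as 24.5 or 25 µs does not change either rounded figure.

The axial density profile counts ions inside a coaxial cylinder
(diameter 12 Å), bins z (0.5 Å default), converts to number density and
divides by the density equivalent of the bulk concentration (300 mM
default, i.e. 1.807×10⁻⁴ ions/Å³); an ideal gas at bulk concentration
gives 1.0 in every bin, with per-bin fluctuations shrinking as the
square root of the expected per-bin count.

## Ligand contact statistics

A contact is a pair (side-chain carbon of a monitored residue, ligand
C/S atom) within 4.5 Å, boundary inclusive ("within 4.5 Å" is read as
≤). Backbone C and CA are excluded for all residues — the standard
reading of "side-chain carbons" — so for proline the ring carbons
CB/CG/CD count. The monitored set defaults to the S6 hydrophobic
cluster 398, 401, 405, 406, 409. Counts are tallied per residue per
subunit; exceedance curves report the fraction of snapshots with at
least n contacts (the empirical survival function, which starts at 1,
is non-increasing and sums over n ≥ 1 to the mean count — identities
the tests assert), and `simultaneous_subunit_fraction()` reports how
often a residue is engaged in two or more subunits at once. Contact
counting is verified exactly against an all-pairs brute-force oracle on
random fixtures.

Planar histograms use a ±15 Å extent and 0.5 Å bins by default (the
published axes are unspecified; this covers the whole cavity cross-
section). Occupancy maps are 3D histograms on a 1 Å grid,
sigma-normalized over the grid, exported in OpenDX with a stored
contour level (0.04 by default, matching the convention of contoured
density meshes).

## Restraint and bias potentials

Three energy functions are evaluated with analytic gradients (all
verified against central finite differences to 1e-6):

- **Dihedral bias** `U(θ) = k Σₘ₌₁⁶ (−1)ᵐ[1+cos(mθ − m(θ_expt −
  180))]/m!`, k defaulting to 1 kBT at 298 K (0.5922 kcal/mol computed
  from constants). At θ = θ_expt the odd terms vanish and the even
  terms give `U = k·2(1/2! + 1/4! + 1/6!) = 1.0861 k` with zero
  gradient. Evaluated exactly as printed, that stationary point is an
  energy *maximum*: `U(θ_expt) > U(θ_expt + 180)` for k > 0. A
  restraint toward the reference geometry requires the opposite sign,
  so both conventions are exposed (`convention = "printed"` /
  `"restraining"`); the discrepancy is surfaced deliberately instead of
  silently "fixing" the printed form.
- **Flat-bottom confinement** `U(d) = ½k(d − d₀)²` for d > d₀, zero
  inside; C¹ at the boundary. The radial variant (d = distance to the
  axis) uses d₀ = 10 Å, k = 100 kcal/mol/Å²; the axial variant
  (d = projection on the axis relative to the V409 Cβ center) uses
  d₀ = 15 Å. At d = d₀ + 2 the radial form gives exactly 200 kcal/mol.
- **Knock-on induction restraint**: one half-harmonic per target atom
  (the eight carbonyl O of residues 376/375 across subunits), target
  distance 3 Å, k = 3 kcal/mol/Å², one-sided (no penalty for being
  closer — the restraint only *brings the ion within* coordination
  distance).

The constant-field mapping converts voltage to field as `E = V/L_z`,
with the unit identity 1 kcal mol⁻¹ Å⁻¹ e⁻¹ = 43.4 mV/Å derived from
physical constants (4184 J per kcal over the Faraday constant =
43.364 mV). For a 92 Å box, 100 mV gives 0.0251 kcal mol⁻¹ Å⁻¹ e⁻¹;
the package implements the formula, not any rounded printed value, and
the reported ~92 Å box height is approximate anyway.

## The synthetic knock-on generator

No trajectory data are deposited for desk-scale validation of analyses
like these, so the package ships a generator whose outputs have the
statistical structure the analyses assume, with exact ground truth.

The conduction cycle is a two-state continuous-time Markov chain
simulated with the Gillespie algorithm: state A (three filter ions,
cavity empty) loads at rate λ_load to state B (four-ion configuration);
B resolves at rate λ_return (cavity ion returns to bulk) or λ_knock
(outermost ion ejected, concerted single-file shift — one completed
cycle). Blocker modes rescale loading only: an on-axis blocker ("TEA")
sets it to zero; a wall-bound binder ("RY785") divides it by an
attenuation factor, 4 by default, mirroring a four-fold slower
permeation rate. The exact long-run cycle rate is

λ_eff = λ_load·λ_knock / (λ_load + λ_knock + λ_return),

which reduces to λ_load·λ_knock/(λ_knock+λ_return) when loading is
rate-limiting. The defaults (λ_load = 5, λ_knock = 40, λ_return =
60 µs⁻¹) were chosen once, on three grounds: the four-ion state is
short-lived (10 ns mean dwell, consistent with its description as
metastable), returns outnumber ejections (the incoming ion more often
falls back than triggers a knock-on), and the open-mode rate is
1.90 µs⁻¹ — approximately one permeation per 0.5 µs, the regime of the
full-scale simulations. No published dwell or return rates exist; these
defaults are regime-matching only and are not estimates of real Kv2.1
kinetics.

Rendering turns the jump path into per-ion traces: ions fluctuate about
their site centers with exact-discretization Ornstein–Uhlenbeck noise
(σ = 0.4 Å, τ = 1 ns, 1 ns frames by default; σ is kept below the
assignment hysteresis so noise cannot flip labels), hop instantaneously
at jump times, enter from a point 3 Å below the gate and leave via a
point 3 Å above the filter exit. The three ions that occupy the filter
at t = 0 are given a short preamble at negative times showing their
entry from the cytoplasmic side, so *every* ejected ion has a complete
gate-to-exit excursion and the detected event count equals the chain's
completed-cycle count exactly, for every seed — the round-trip property
the acceptance tests verify. The internal shuffling of the three filter
ions among sub-states is deliberately not modeled (OU noise about
representative centers instead): only cavity loading and ejection
govern the counted events.

The induced-vacancy protocol mirrors the zero-field corroboration
experiment: at t = 100 ns the central filter ion is driven to S1, the
outermost ion is ejected, the innermost shifts up and S4 is vacated;
whether a bulk ion reloads S4 is then drawn from the blocker-adjusted
loading rate. For this protocol the unblocked rate defaults to
400 µs⁻¹, so the wall-bound mode (400/4 = 100 µs⁻¹) reloads with a
10 ns mean — matching reloading "within ~10 ns" — while the on-axis
mode never reloads in the 100 ns window. `detect_s4_reload()` reports
the first S4 assignment of an ion that was not already in the filter
when the vacancy was created and that arrived from below the gate; the
in-filter exclusion is needed because hysteresis lets the shifted ion
keep its S4 label for a few frames after the perturbation.

**What the generator does not emulate:** water, the protein, realistic
dwell-time distributions (all exponential here), correlated multi-ion
motion beyond the concerted shift, voltage dependence (voltage enters
only through the user-set rates), and ligand kinetics (ligand traces
are geometric fixtures — on-axis near S_cav for TEA-like, wall-bound at
r ≈ 7 Å in four symmetry-equivalent poses for RY785-like binding).
Passing tests on synthetic data therefore validate the *analysis
machinery* — detection, assignment, counting, statistics — not any
claim about real channel kinetics.

## Problem sizes and tolerances

The test suite runs the generator at 25 µs-equivalent duration across
20 seeds for the round-trip and attenuation-ratio checks, 100 random
fixtures for the brute-force contact oracle, and 25 000 frames of an
ideal-gas fixture for the density profile; these sizes keep every
stochastic check several standard errors wide of its threshold while
the whole suite completes in well under a minute. Rate-recovery checks
use a 3-standard-error band; count round trips and contact counts are
exact; gradients match finite differences to 1e-6.

## Known limitations

- Event detection assumes single-file, effectively one-dimensional
  transport; it would under-count in a pore wide enough for ions to
  pass one another (not the case in a K⁺ filter).
- Site boundaries are midpoint-based; published site labels have no
  quantitative z-boundaries, so comparisons at that level are
  qualitative.
- The trace-table reader holds everything in memory; multi-microsecond
  trajectories at fine output intervals should be down-sampled first.
- `load_topology()` trusts the PDB's chain labels for subunit identity;
  structures with hetero-atoms sharing author chain ids may need
  pre-filtering.
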