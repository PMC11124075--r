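---
title: "Geometry descriptors and energy bookkeeping for cyclodextrin inclusion complexes"
author: "cdbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry descriptors and energy bookkeeping for cyclodextrin inclusion complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbind)
```

# The system and the problem

Cyclodextrins (CDs) are cyclic oligosaccharides of 6 (α), 7 (β) or 8 (γ)
glucopyranose units that form a truncated-cone cavity: a narrow *primary
rim* carrying the O6 hydroxyls and a wide *secondary rim* carrying the
O2/O3 hydroxyls, with the glycosidic (bridging O4) oxygens forming a ring
between them. A hydrophobic guest — here a rigid three-ring
organophosphorus flame retardant (DOPO, with rings labelled A, B, C) — can
insert into the cavity and form a non-covalent host:guest inclusion
complex. Two inclusion poses matter: **BS**, with the guest's B ring
towards the secondary rim, and **BP**, with the B ring towards the primary
rim; a guest outside the cavity is **unbound**.

`cdbind` implements the complete desk-side analysis machinery for such
studies: per-frame geometric descriptors of guest binding, their
trajectory statistics, and three flavours of energy bookkeeping (pairwise
force-field decomposition, ω-weighted DFT-component recombination, and
the MM–PBSA ledger). It deliberately does *not* run docking, molecular
dynamics, Poisson–Boltzmann solvers or quantum chemistry — those engines
produce the structures, charges and component energies that this package
consumes and analyses.

# The host frame and the geometric descriptors

All descriptors derive from one host-fixed frame (`build_frame_basis()`):

* **origin** — unweighted centroid of the glycosidic oxygens. This is a
  geometric plane anchor, so no mass weighting is applied; the guest COM,
  in contrast, is always mass-weighted.
* **z axis** — normal of the least-squares plane through the glycosidic
  oxygens, sign-oriented from the secondary towards the primary rim
  (checked against the rim-oxygen centroids).
* **x axis** — towards the first unit's glycosidic oxygen, projected into
  the plane; y completes a right-handed triad.

An alternative convention uses the whole-host mass-weighted COM as the
reference point (as docking setups often do); the difference for a CD is
sub-Ångström, and `signed_com_distance(use_host_com = TRUE)` switches to
it.

**Signed COM distance** (`signed_com_distance()`): magnitude is the
distance from the guest's mass-weighted COM to the origin; the sign is
negative when the guest COM is farther from the primary-rim oxygen
centroid than from the secondary-rim centroid, i.e. negative = guest on
the secondary-rim side. The exact tie breaks positive (it only occurs at
distance 0, where the sign is meaningless).

**Guest orientation θ** (`guest_orientation()`): the angle between a
user-designated tail→head guest vector (tail in ring B, head in ring A)
and +z, in [0°, 180°]. Which two guest atoms define that vector is a
modelling decision the user must make explicitly — the package never
guesses it from the guest topology.

**Glucose tilt τ** (`tilt_angles()`): per unit, a least-squares plane is
fitted to the six pyran-ring atoms (O5, C1–C5; heavy atoms only) and the
angle between its normal and +z reported. A plain plane–plane angle would
fold at 90° and could not distinguish a unit leaning inwards from one
leaning outwards, so the ring normal is first oriented to have a positive
component along the unit's outward radial direction; τ then lives on
(0°, 180°), with 90° meaning a ring parallel to the cavity axis and
values below 90° a more open secondary rim. Typical crystal and
force-field values sit in the high 70s to high 80s.

**Circularity** (`circularity()`): the glycosidic oxygens are projected
onto the base plane and the square root of the eigenvalue ratio of their
2×2 covariance returned — the axis ratio of the best-fit ellipse, 1 for a
perfect circle. Several distortion measures exist in the literature under
this name; the axis-ratio form was chosen because it is exactly 1 for a
circle, affine-sensible, and frame-independent. Agreement with published
values computed under an unknown variant is therefore expected only to
about ±0.02.

**Hydrogen bonds** (`count_hbonds()`): donors are O/N with a covalent H
(within 1.2 Å), acceptors are O/N; a host↔guest donor–acceptor pair
counts when the D–A distance is ≤ 3.5 Å and the H–D–A angle ≤ 30° — the
defaults applied by the standard MD analysis tools. Both cutoffs are
parameters (`hbond_criteria()`). Explicit hydrogens are required;
heavy-atom structures get `NA` from `describe_frame()` rather than a
silent zero.

**Binding-mode classification** (`classify_mode()`): unbound when
|d| > 6.5 Å — the cutoff separating the inclusion-complex peak from
dissociated-guest peaks in COM-distance distributions — otherwise BS for
θ < 90° and BP for θ ≥ 90°. The measure-zero tie θ = 90° deterministically
maps to BP.

# Trajectory statistics

`descriptor_histogram()` normalises so that density × bin width sums to
one; default widths are 0.25 Å for distances and 5° for angles (narrow
enough to resolve the bimodal BS/BP structure, wide enough to stay smooth
at 10³–10⁴ frames). `bound_fraction()` and `mode_occupancy()` summarise
dwell behaviour; occupancies are permutation-invariant while transition
counts are ordering-sensitive, which the tests assert.

`block_average()` estimates uncertainties of correlated series as the SD
of the means of `n_blocks` equal contiguous blocks, dropping remainder
frames from the end. The default of 5 blocks is a conventional choice for
~10 ns analysis windows (the block count is rarely stated in papers);
it is a parameter everywhere it is used. `subsample_frames()` provides
the customary end-state cadence (10 ps steps, giving 1001 frames over
10 ns) as a default, not a hard-coded rule.

`group_contiguous_modes()` merges maximal runs of identical mode labels
along an ordered coordinate into intervals — the standard way of
summarising a docking scan over the cavity axis — keeping singleton runs
as one-point intervals, which do occur in real scans.

# Force-field energy decomposition (EDA-FF)

`pairwise_eda()` sums Coulomb and Lennard-Jones 12-6 terms over all
inter-fragment atom pairs, with no cutoff and no exclusions (the
fragments are distinct molecules):

$$\Delta E_{FF} = \sum_{i\in A}\sum_{j\in B}\Big[k_C\frac{Q_iQ_j}{r_{ij}}
 + \varepsilon_{ij}\Big(\tfrac{R_{min,ij}}{r_{ij}}\Big)^{12}
 - 2\,\varepsilon_{ij}\Big(\tfrac{R_{min,ij}}{r_{ij}}\Big)^{6}\Big]$$

Two numerical decisions deserve a note:

* The attractive term carries the factor 2: with ε/Rmin parameters the
  12-6 pair potential must reach its minimum of −ε exactly at Rmin (that
  is what Rmin *means*), which forces the Amber form
  ε[(Rmin/r)¹² − 2(Rmin/r)⁶]. The bare C12/C6 grouping without the
  factor — which would put the pair-potential zero at Rmin instead — is
  available behind `form = "plain"` for sensitivity checks.
* The Coulomb prefactor is 332.0522 kcal·Å·mol⁻¹·e⁻² (Amber's 18.2223²),
  matching the Amber-family parameters these analyses use. Other codes
  use 332.0637; the difference is below 0.1 kcal/mol for host–guest
  systems and the constant is an argument.

Mixed parameters follow Lorentz–Berthelot/Amber combination
(`combine_lj()`): geometric mean of ε, sum of Rmin/2. RESP2-style charge
sets are produced by `blend_charges()`, the per-atom mix
δ·q_water + (1−δ)·q_gas with the conventional δ = 0.5. Charges and LJ
parameters are inputs (`ff_fragment()`, `read_ff_params()`); ESP fitting
itself is out of scope.

Correctness is established by equivalence with an independent brute-force
double loop on random toy systems (≤ 10⁻¹⁰ kcal/mol), plus the algebraic
invariants: symmetry in the fragments, linearity of the electrostatics in
either charge set, and charge-independence of the LJ terms.

# sobEDAw recombination

DFT-based energy decomposition delivers electrostatic (els), exchange
(x), Pauli repulsion (rep), orbital (orb), DFT-correlation (dftc) and
dispersion-correction (dc) components. To compare with SAPT, a fraction ω
of the correlation energy is folded into dispersion and the remainder
into exchange–repulsion:

$$\omega = e^{-r\,(\Delta E_{dc}/\Delta E_{els} - a)}\,(1-c) + c,\qquad
\Delta E_{xrep} = (\Delta E_x + \Delta E_{rep}) + (1-\omega)\,\Delta E_{DFTc},\qquad
\Delta E_{disp} = \Delta E_{dc} + \omega\,\Delta E_{DFTc}$$

The (r, a, c) weights are calibrated per level of theory; the only
built-in preset is the B3LYP-D3(BJ)/6-31+G(d,p) calibration
(r = 2.571, a = 0.071, c = 0.575) — other levels must supply their own
triple (`sobedaw_params()`). Two identities hold for *any* ω and are
asserted across random parameter sweeps: xrep + disp equals
(x + rep) + dftc + dc, and the interaction energy
eint = els + x + rep + orb + dftc + dc equals els + xrep + orb + disp.

The binding-free-energy ledger (`binding_free_energy()`) operates at the
level of its four stated terms: gbind = eint + (def_h + def_g) +
(polar + nonpolar) + gcorr, with aggregate overrides accepted. When
validating published tables whose entries are rounded to one decimal,
this matters: sums of rounded leaves can drift 0.1 kcal/mol from a
printed aggregate that was formed from unrounded values.
`sobedaw_consistency()` therefore classifies each deviation — "ok" within
0.05 kcal/mol (exact at the printed precision), "rounding" within 0.15,
"fail" beyond — rather than silently loosening one global tolerance. On
the bundled reference table all 84 checks are ok or rounding-flagged;
none fail.

# The MM–PBSA ledger

`mmpbsa_ledger()` book-keeps E_bind = E_MM + G_sol with
E_MM = (bonded_h + bonded_g) + (vdW + elec) and
G_sol = polar + nonpolar. Each aggregate is taken verbatim when supplied
and otherwise summed from its immediate parts, so the ledger runs on
summary tables and on per-frame series alike; series get block-averaged
uncertainties. The polar and nonpolar solvation terms are upstream-solver
outputs consumed as numbers.

The entropy contribution is represented as an explicit, optional
`minus_tds` field. When absent — as in end-state analyses that skip the
expensive and method-sensitive entropy estimate — the result is labelled
`e_bind`, a binding *energy*; only when −TΔS is supplied does a `g_bind`
row appear. The two are never conflated.

`mmpbsa_check_table()` applies the same ok/rounding/fail classification
to a published decomposition table; on the bundled reference table all
30 checks pass at 0.15 kcal/mol with the expected handful of 0.1
rounding flags. (The analogous additivity check on the bundled
force-field EDA table, `edaff_check_table()`, honestly reports that one
host/phase block of that reference table is internally inconsistent as
tabulated by 0.9–1.8 kcal/mol; every other block is additive to
one-decimal rounding.)

# The synthetic generator: what it does and does not emulate

Because docking, MD and QM engines are out of scope, every analysis
stage is validated against synthetic ground truth:

* `build_cd()` places the glycosidic oxygens on an ellipse (axis ratio =
  requested ellipticity, hence circularity is recovered exactly) and
  builds one planar pyran hexagon per unit whose plane makes exactly the
  requested tilt with the base plane *under the package's own
  convention*, with primary-rim oxygens above and secondary-rim oxygens
  below the plane. Atom names and residue layout follow glucopyranose
  conventions so that topology detection runs on the output.
* `build_guest()` is a rigid, planar three-ring scaffold with labelled
  tail/head vector atoms and a P/O-bearing bridge ring — fixture
  geometry mimicking the guest's shape, not its chemistry.
* `place_guest()` realises an exact (d, θ, azimuth) pose, so
  generator→descriptor inversion is tested to 10⁻⁶.
* `simulate_descriptor_trajectory()` evolves a hidden three-state Markov
  chain (BS ↔ BP jumps with unbound excursions, the qualitative dynamics
  seen in such simulations) and emits Gaussian-noised (d, θ) per frame,
  optionally with full structures. Default state centres are typical
  inclusion poses (BS −1.0 Å/20°, BP 1.2 Å/152°, unbound 9 Å), with
  0.5 Å/8° noise — well-separated from the classification boundaries so
  hidden-state dwell fractions are recoverable. The state log is returned
  as ground truth.
* `toy_charge_system()` draws non-overlapping random fragments with
  charges in [−1, 1] e, ε in [0, 0.3] kcal/mol, Rmin/2 in [1.2, 2.2] Å.

All generators are pure functions of their seed. What the synthetic data
does **not** contain: thermal host flexibility (rings are rigid planes),
solvent, chemically valid bond lengths, force-field energetics of the
emitted structures, or correlated noise. Passing tests therefore
demonstrate the correctness of the descriptor and bookkeeping machinery,
not the realism of any simulation protocol.

# Numerical choices and degenerate inputs

* Plane fits use the eigendecomposition of the point covariance; a
  collinear oxygen set (two near-zero eigenvalues) is an error, as are
  degenerate ring geometries and ring centroids on the cavity axis.
* COM computations refuse unknown element symbols — no silent unit-mass
  fallback.
* PDB I/O is delegated to `bio3d` with a light validation pass that
  reports malformed coordinate fields with their line number and rejects
  multi-model files whose MODELs disagree in atom count or ordering.
  Coordinates round-trip at the 10⁻³ Å precision of the format.
* Problem sizes in the test-suite: statistical recoveries use 10⁴-frame
  descriptor logs (structures not emitted); structure-emitting tests use
  5–50 frames; oracle equivalence uses 7–100-atom fragments. The full
  suite runs in well under a minute.

# Known limitations

* Topology detection is name-based (O4/C1 bridging within 1.8 Å) and
  assumes standard glucopyranose atom names; anything else needs explicit
  hints, which always win.
* Circularity reproduces other published values only up to the ±0.02
  convention ambiguity noted above.
* The tilt convention is self-consistent and matches the common
  crystal-structure values in magnitude, but published tilt angles
  computed under an unstated convention (e.g. with hydrogens included in
  the plane fit) may differ by a degree or two.
* Histogram binning and block counts of published figures are rarely
  stated; distributions are reproduced in shape, not bit-exactly.
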