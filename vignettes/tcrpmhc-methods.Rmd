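---
title: "Methods: descriptors and group statistics for TCRpMHC ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptors and group statistics for TCRpMHC ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tcrpmhc)
```

# Scope and model

`tcrpmhc` analyses ensembles of Cartesian coordinate frames of a
TCR/peptide/MHC complex — one ensemble per simulation — and asks whether a
set of structural descriptors differs systematically between two groups of
simulations (typically complexes of more vs. less immunogenic peptide
variants).  The package does not run molecular dynamics, build topologies
or model side-chain mutations; it starts from coordinates (multi-model
PDB) plus a region annotation and an immunogenicity table.

The statistical unit throughout is the *simulation*, not the frame.
Frames within one trajectory are autocorrelated and share a
simulation-specific mean (slow conformational modes), so all resampling
reassigns whole simulations.

# Trajectory handling

* **Units.**  Internal lengths are nm; PDB Ångström values are converted
  on read/write.  Residue numbering is per-chain as in the input files;
  all region configs are inclusive `(chain, first, last)` intervals.
* **Equilibration.**  `discard_equilibration()` drops frames with
  time ≤ cutoff; the default cutoff of 10 ns treats the first tenth of a
  100 ns run as relaxation, so analyses are based on the last 90 ns.
* **Superposition.**  `superpose()` removes global motion with an
  SVD-based least-squares rigid fit of a selection.  Without an explicit
  reference a two-pass procedure is used: align to frame 1, rebuild the
  arithmetic mean structure, align to that mean.  Fewer than three
  non-collinear fit atoms is a degenerate-fit error.
* **Frame stride** is a config parameter (default 1, i.e. every retained
  frame); the source analyses used "equally distributed frames" without
  stating a count, so the choice is left to the user and the
  normalisations always use the frames actually analysed.

# Descriptors

## Hydrogen-bond footprints

A bond is counted between donor D (N/O with an attached H) and acceptor A
(N/O) when d(D,A) ≤ 0.35 nm and the H–D–A angle is ≤ 30° — the default
geometric criterion of the common MD analysis tools.  Because the PDB
dialect carries no bond topology, hydrogens are attached to donors by
proximity (≤ 0.12 nm).  The angle convention of the original tooling is
not documented; we fix H–D–A and expose D–H–A linearity
(`angle_convention = "dha"`) as an alternative.  The footprint score of a
residue is the total bond count across all frames of all pooled
simulations divided by the total frame count; it is zero iff the residue
never bonds, one for a single persistent bond, and exceeds one when a
residue mediates several simultaneous bonds.  Both bond partners
(donor-side and acceptor-side residue) are credited.

## SASA

A deterministic point-sphere (Shrake–Rupley-style) algorithm: each
selected atom is inflated by the probe radius (default 0.14 nm, water)
and sampled with a fixed 960-point golden-spiral set; the accessible
fraction is the share of points outside every neighbouring inflated
sphere.  The production tooling used a double-cubic-lattice variant;
the point-sphere method is numerically equivalent at the ≤ 1 % level on
test bodies and is much easier to verify against an independent
random-direction oracle, which is why it was chosen.  Radii come from a
configurable per-element table (C 0.170, N 0.155, O 0.152, S 0.180,
P 0.180, H 0.120 nm); unknown elements are an error rather than a guess.
Hydrogens are excluded by default (united-atom convention).

## RMSF

Per atom, RMSF = √⟨‖x − x̄‖²⟩ over frames after superposition; per
residue, the unweighted mean over the residue's backbone atoms
(N, CA, C, O).  The source analyses state "backbone atoms only" but not
the aggregation; the unweighted mean is our documented choice.  A
single-frame ensemble has no defined fluctuation and errors.

## Interface distances

Sixteen named distances (kink-to-CDR ×6, groove width ×3,
peptide-to-CDR3 ×7).  The underlying analyses name residues and regions
but not reference points, so the package fixes: single residues → Cα;
regions (CDRs, whole peptide, joint CDR3 pair) → unweighted centroid of
non-hydrogen atoms.  The "middle" residue of a length-L peptide is
⌊(L+1)/2⌋ (residue 5 of a 9-mer).  Groove begin/middle/end are
helix1–helix2 Cα–Cα distances at the first, kink and last annotated
helix residues.  Kink residues are annotation inputs, never computed —
automatic kink detection is out of scope.

## Inter-domain orientation

For each variable domain the first and second principal components of
its conserved-core Cα set are computed per frame (A1/A2 for Vα, B1/B2
for Vβ); the anchor is the core centroid, the simplest consistent
interface point (the adapted construction used by the source analyses is
not printed).  With C the unit vector from Vα anchor to Vβ anchor:
BA = signed torsion of A1 vs B1 about C (right-hand rule, (−180, 180]),
AC1 = ∠(A1, C), BC1 = ∠(B1, −C), AC2 = ∠(A2, C), BC2 = ∠(B2, −C),
DC = anchor separation.

Principal axes have a sign ambiguity.  A naive fix against static
reference axes flips once a domain rotates beyond 90°, so the stored
reference keeps the reference core *coordinates*: for every frame the
reference core is rigidly fitted onto the frame's core and the reference
axes are transported by that rotation before the sign fix.  This keeps
signs stable along arbitrarily long smooth trajectories (property-tested
with a 120° sweep) while remaining exactly equivariant under rigid-body
motion.  For group comparisons all simulations share one reference
(default: first frame of the first ensemble).

# Group statistics

## tvd and d/r

Pooled per-frame values of the two groups are binned on shared
equal-width edges spanning the pooled (untrimmed) range;
tvd = ½ Σ |pᵢ − qᵢ| ∈ [0, 1].  The original analyses never state their
binning; we default to the Freedman–Diaconis count on the pooled sample
with a floor of 10 bins (and a cap of 1000), exposed in the API.
d/r = |mean₁ − mean₂| divided by the pooled range after discarding the
lowest and highest 2.5 % (type-7 quantiles).  A zero trimmed range with
a genuine mean difference is a degenerate-denominator error; when both
are zero (constant data) d/r is 0.

## Permutation test

Observed tvd and d/r are compared against `n_perm` (default 2000) random
reassignments of whole simulations to two groups of the original sizes.
Bin edges and the d/r denominator are computed once from the pooled data
(both are permutation-invariant), so each permutation only re-sums
per-simulation histograms and means.  Percentiles use the
strictly-smaller convention — ties count against significance — because
the original description does not specify the inequality and strict is
the conservative choice.  Given the seed the test is bit-reproducible;
the caller's RNG state is never touched.

## Categories and their calibration

Each statistic is categorised by its own percentile: ≥ 0.90 of
permutations smaller → "slight", ≥ 0.95 → "difference", ≥ 0.99 →
"strong", else "none".  An earlier design aggregated the two percentiles
with a maximum before categorising.  That convention is structurally
miscalibrated: under the null the two percentiles are each uniform but
only imperfectly correlated (≈ 0.8 at the generator's default
simulation-to-frame variance ratio), so P(max ≥ 0.90) ≈ 0.14 rather than
the 0.10 the thresholds imply — the suite's calibration test detects
exactly this.  The package therefore reports `category_tvd` and
`category_dr` separately and uses the tvd (overlap) category as the
headline `category`; the d/r percentile is always reported alongside, as
the original analyses do.

## Group split

Immunogenicity is tabulated as −log₁₀ of the molar concentration for
50 % lysis, or "never".  groupL = all "never" entries; groupM = entries
with concentration ≤ 10⁻⁶·⁹⁴ M (tabulated value ≥ 6.94); the remainder
is excluded.  A `top_n` policy is available for size-based splits.  No
multiple-testing correction is applied across descriptors, matching the
original analysis.

# The synthetic generator

`build_toy_complex()` constructs a deliberately non-physical minimal
geometry: a 9-residue peptide strand flanked by two 12-residue helix
rods (±0.7 nm), and two 8-residue anisotropic box cores (Vα, Vβ) 1.6 nm
apart above the peptide, each with three 3-residue CDR stand-ins.  Every
residue carries N, H, CA, C, O so all descriptor code paths run.  One
switchable hydrogen bond (peptide residue 2 N–H → helix-1 residue 4
carbonyl, d(D,A) = 0.29 nm, collinear) is formed in a
Bernoulli(`hbond_occupancy`) subset of frames.

`generate_ensemble()` adds iid Gaussian jitter per region (default
σ = 0.05 nm per coordinate — a typical backbone-level fluctuation scale)
and two kinds of structure:

* *planted group effects*: a rigid translation of Vβ along the
  inter-domain axis (`dc_shift_nm`) and a rigid rotation about it
  (`ba_offset_deg`), which change DC and BA by exactly the planted
  amount on noiseless frames (the spec-level description of a DC shift
  "via sub-rotation" is internally inconsistent — a rotation about the
  inter-domain axis leaves DC unchanged — so the generator uses the
  physically consistent translation/rotation pair);
* *simulation-level random effects*: per-simulation constant offsets of
  DC (σ = 0.03 nm) and of the Vβ rotation (σ = 1.5°), giving each
  trajectory its own mean.  These are what make the trajectory-level
  permutation test necessary, and their ratio to the frame-level noise
  (≈ 1.2 : 1 for DC) is the world used by the calibration tests.

Defaults are 100 frames at 1 ns spacing so the 10 ns equilibration cut
retains 90 frames.  In the planted-effect recovery test, "null spread"
is read as the standard deviation of the pooled per-frame DC
distribution absent any effect, √(0.03² + 0.025²) nm, where
0.025 = σ/2 is the analytic DC noise from jittering two 8-point core
centroids; reading it instead as the spread of the permutation null of
the mean difference would make a "3×" effect a z ≈ 3 observation whose
99th-percentile recovery rate is ≈ 75 % by construction, inconsistent
with the ≥ 95 % recovery the acceptance property demands.

What the toy world does **not** emulate: real protein stereochemistry,
side chains, solvent, force-field energetics, anharmonic or multi-state
dynamics, and realistic H-bond networks.  A green pipeline test
establishes that the machinery measures what was planted with the right
false-positive rate — not that any biological conclusion transfers.

# Numerical choices and degenerate inputs

* Superposition/PCA degeneracy thresholds: < 3 fit atoms or second
  singular value < 10⁻⁸ of the first → error (collinear cores cannot
  define axes).
* Torsions are undefined when an axis-parallel principal axis makes the
  in-plane projection vanish (< 10⁻¹⁰ nm); coincident anchors
  (DC < 10⁻⁹ nm) are errors.
* Histogram values on the shared right edge fall in the last bin;
  all-equal pooled samples get a unit-width bin around the value.
* Seeds are mandatory for every stochastic operation; derived
  per-descriptor seeds stay below 2³¹.

# Limitations

* Only PDB-dialect input is supported (multi-model PDB for
  trajectories); binary trajectory formats would need an external
  converter.
* The interface reference points (Cα / heavy-atom centroid) and the
  anchor-point construction are package conventions where the original
  method descriptions are silent; absolute angle/distance values are
  therefore comparable within this package, not across tools.
* SASA is O(selection² ) per frame with dense neighbour checks —
  adequate for interface-sized selections, not for whole large systems
  at every frame.
* The category thresholds are used without multiple-testing correction
  across the 22 default descriptors; with ~22 descriptors roughly two
  "slight" calls are expected under the null, and users should read the
  report accordingly.
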