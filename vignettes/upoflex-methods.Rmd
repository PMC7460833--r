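---
title: "Methods: windowed RMSF, channel volumetrics and kinetics in upoflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed RMSF, channel volumetrics and kinetics in upoflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upoflex)
```

## Scope

`upoflex` post-processes molecular-dynamics trajectories of unspecific
peroxygenase (UPO) variants to quantify how substitutions in the heme access
channel — the PaDa-I panel F76A, F76L, F191A, F76A/F191A, F76L/F191A —
change per-residue flexibility and channel topography, and it fits the
accompanying kinetic measurements (Michaelis–Menten, H2O2 inactivation,
total turnover number). Producing the trajectories themselves (force-field
setup, solvation, integrators) is outside the package: the input is a
finished trajectory as a multi-model PDB or multi-frame XYZ file, with
frame times in picoseconds. Because real 50-ns explicit-solvent
trajectories of a ~330-residue protein are far too expensive to regenerate
at test time, the package ships a synthetic-data module whose outputs have
known ground truth; every statistic is validated against that, not against
archived MD.

## Superposition and RMSD

Rigid-body least-squares superposition uses the Kabsch (SVD) solution with
the reflection branch corrected through the sign of the determinant, so
only proper rotations are returned. Weights default to uniform: all
flexibility analyses here run on C-alpha atoms of a single chemical type,
and mass weighting would change nothing. By default the same atom
selection is used for fitting and for measuring deviations; a caller can
separate the two, but the simplest convention is also the easiest to
reason about. Configurations with fewer than three points, or collinear
ones, are rejected because the rotation is not identifiable. `rmsd()`
itself performs no alignment — alignment is always an explicit, visible
step.

## Windowed per-residue RMSF

The mobility statistic is the root-mean-square fluctuation of each
C-alpha, computed in fixed-duration windows rather than over the whole
production run. The analyzed span is the last 40 ns of the trajectory,
subdivided into consecutive 100-ps packages (half-open intervals by frame
time; a trailing partial package is dropped; a package with fewer than two
frames is an error because a fluctuation about a window mean is then
undefined). Within each window:

1. an average structure is computed by aligning all window frames to the
   first frame on the C-alpha selection, averaging, then re-aligning the
   original frames to that mean and averaging once more (a second pass is
   within ~1e-3 A of the fully iterated fixed point on equilibrated
   windows, which the tests verify against a 10-iteration oracle);
2. every frame is Kabsch-aligned to that window average on the same
   selection;
3. per residue, RMSF_w,i = sqrt(mean_t |r_i(t) − <r_i>_w|^2) over the
   aligned frames.

The reported profile is the unweighted mean of RMSF_w,i over windows (the
windows contain equal frame counts by construction). Superposition before
measuring fluctuations is essential — without it rigid-body diffusion
dominates the statistic — and windowing deliberately suppresses motion on
timescales longer than the window, which is the point of the package
design: the statistic captures local wiggling, not slow collective drift.
The test suite asserts this directly on a two-timescale generator where
the windowed profile falls well below the full-span profile.

For isotropic Gaussian displacements of amplitude sigma and n frames per
window, the expectation is `sigma * sqrt(3) * sqrt((n-1)/n)` (the (n−1)/n
factor is the loss from subtracting the window mean). Superposing onto the
window average absorbs a further six rigid degrees of freedom out of 3N,
biasing the estimate low by roughly `6/(2*3N)`; at N = 100 residues this
is about 1%, which is why the validation band for per-residue recovery is
5% rather than the pure sampling noise (~0.7% at 400 windows).

## Differential mobility calls

For a variant profile v and reference profile r, per-residue differences
`delta_i = v_i − r_i` are summarized by their mean and population standard
deviation over all residues (population rather than sample: at ~300
residues the distinction is immaterial, but fixing it makes results
byte-reproducible). A residue is called

* `increased` when `delta_i > mean(delta) + k * sd(delta)`,
* `decreased` when `delta_i < mean(delta) − k * sd(delta)`,
* `unchanged` otherwise,

with k = 1 by default. The one-standard-deviation phrasing admits a
one-sided reading; the two-sided form is used because the analysis needs
both directions of change (variants show both rigidified and mobilized
segments), and the sign of the excursion supplies the direction naturally.
Under a pure-noise null with i.i.d. Gaussian deltas this rule flags
2*(1−pnorm(1)) ≈ 31.7% of residues — that calibration is asserted by
simulation in the acceptance suite, and it is worth keeping in mind when
reading call lists: the rule is a ranking device, not a significance test.
All residues present in both profiles enter the mean/SD; no termini or
cofactor exclusions are applied. If sd(delta) = 0 (identical profiles)
every residue is `unchanged`.

## Channel volume inside inclusion spheres

Channel volume follows the POVME recipe. Two spheres of radius 4 A anchor
the measurement: one at the centroid of the CZ atoms of Phe69, Phe121 and
Phe199 (the aromatic triad near the heme), one at the centroid of the
side-chain reference atoms of residues 76 and 191 at the channel mouth.
Because variants replace those phenylalanines, the mouth anchor atom
follows the residue actually present — CB for Ala, CD1 for Leu, CZ for Phe
(`mouth_reference_atom()`); asking for an atom the variant does not have
is an error that states this convention. The named anchors are all
carbons, so the unweighted centroid equals the center of mass exactly.

Per analyzed frame the spheres are re-resolved (they ride on the protein),
a regular grid is laid over their bounding box, and a grid point counts
toward the volume when it lies inside the union of the spheres and outside
every heavy atom's van der Waals radius plus a probe pad. Volume is
`count * spacing^3`. Numerical choices:

* Grid points sit at voxel centers (offset by spacing/2), the natural
  voxelization; on an analytic 4-A sphere this measures 268.08 A^3 within
  2% at 0.5 A spacing and converges within 1% on halving the spacing.
* Default spacing is 1.0 A (the common POVME operating point); validation
  and figure-quality runs use 0.5 A.
* The probe pad defaults to 0 (bare vdW clash). Nothing in the measurement
  definition fixes a probe; the default is the minimal one and is
  configurable.
* Contiguity (keeping only grid points 26-connected to the component
  containing a sphere center) is off by default — the minimal published
  recipe is spheres plus clash removal — but available for irregular-shape
  analyses. If every sphere center is itself buried, the contiguous volume
  is zero with a warning rather than an error.
* Hydrogens never clash (crystal-structure-derived systems typically lack
  them); heme atoms do clash, as they form the pocket floor. Waters and
  buffer ions are dropped at file-reading time by default.
* vdW radii come from a bundled Bondi-style element table; unknown
  elements fall back to 1.7 A with a warning.

## Distance distributions

Residue-pair C-alpha distances (76–191, 76–274 are the pairs of interest)
are measured per frame with no superposition — distances are invariant
under rigid motion. Frequency distributions use half-open bins of 0.25 A
by default (the final bin is closed so the maximum is counted); bin counts
sum to the number of frames, and merging adjacent bins sums their counts.

## Kinetics

Initial rates at varied substrate concentration are fitted to
`v = Vmax * S / (Km + S)` by nonlinear least squares (Levenberg–Marquardt
via minpack.lm), not by a linearizing transform; `kcat = Vmax/[E]`, and
standard errors come from the fit covariance. Initialization is
`Vmax0 = max(v)`, `Km0 = S` at half-maximal observed rate, which is
reliable for any monotone saturating dataset. A fit is rejected with fewer
than four distinct concentrations; a Km estimate far outside the sampled
range triggers a warning that the design does not constrain it (flat,
saturated datasets are the classic case). Catalytic efficiency is
`kcat / (Km * 1e-6)` in 1/(M s).

H2O2 inactivation time courses are fitted to `A(t) = A0 * exp(-k t)` in
linear space with A0 free — pinning A0 to 1 makes the fit hostage to
normalization error in the t = 0 point. The log-linear regression slope
initializes the fit, and an increasing activity trend is a model-violation
error, not a fit result. `t_half = ln(2)/k`. TTN is the mole ratio of
converted substrate to enzyme; enzyme-unit conversion from absorbance
slopes uses the assay's molar extinction coefficient (built-in
definitions: ABTS 418 nm / 36,000; NBD-derived 4-nitrocatechol 425 nm /
9,700; 1-naphthol 303 nm / 2,010; H2O2 240 nm / 43.6 1/(M cm)). The
Reinheitszahl A420/A280 is included because ~2.0 is the purity criterion
used for these preparations.

`reference_kinetics()` and `reference_inactivation()` expose the reported
parameter panel (18 variant-substrate kinetic rows; 6 inactivation rows)
that drives report layouts, synthetic-data truths, and the consistency
checks of the derived columns. One reported efficiency cell
(F76L/naphthalene) differs in the third significant figure from the
quotient of its reported kcat and Km — an artifact of the inputs being
rounded to three significant figures — so derived-cell checks use a 1%
relative band, which is what 3-significant-figure input rounding can
propagate into a quotient.

## The synthetic-data generators

The generator suite is first-class, tested code; its defaults define the
conditions under which the statistics are validated.

* `synth_reference()` builds an ideal-helix C-alpha trace (rise 1.5 A,
  100 degrees per residue, radius chosen so consecutive C-alpha spacing is
  exactly 3.8 A) with optional CB/CD1/CZ pseudo-atoms so sphere recipes
  resolve on designated residues.
* `synth_trajectory()` adds i.i.d. isotropic Gaussian displacements of
  per-residue amplitude sigma, optionally composed with a rigid-body
  random walk (which superposition must remove — asserted) and/or a slow
  coherent drift mode (per-residue fixed random directions with a common
  sinusoidal time factor, which windowing must suppress — asserted).
  Isotropic Gaussian fluctuations were chosen over elastic-network models
  precisely because every downstream statistic then has a closed form or
  a cheap Monte-Carlo oracle. The internal-motion noise is drawn before
  the rigid-body path, so for a fixed seed the internal dynamics are
  identical with and without rigid motion, letting tests compare the two
  runs directly.
* `synth_cavity_phantom()` surrounds an empty void with a Fibonacci-
  lattice shell of carbons (500 atoms by default — dense enough that no
  grid point inside the void escapes between shell atoms at these radii);
  the constructor rejects shells closer than `void_radius + vdw`.
  Breathing modulates the shell radius sinusoidally, with the expected
  clipped-void volume available analytically
  (`phantom_expected_volume()`).
* `synth_mm_data()` / `synth_inactivation_data()` produce exact model
  curves with optional multiplicative Gaussian noise. Simulation studies
  use 8 concentrations measured in triplicate, mirroring the assay
  protocol (all reported measurements were triplicate); at 5% relative
  noise this design recovers kcat with ~2.5–3% median error over 200
  replicates.

What the generators do **not** emulate: anharmonic and correlated
residue motions, solvent and force-field physics, conformational
substates, or sequence-dependent packing. Passing the validation suite
therefore demonstrates that the estimators measure what they claim on
data with known truth — not that any particular biological conclusion
about a real variant is reproduced. Typical validation scale, chosen so
the full synthetic pipeline runs in well under ten minutes on one CPU:
100 residues, 4000 frames at 10 ps (400 windows of 10 frames), phantom
shells of 500 atoms, 200-replicate kinetic simulations.

## Orchestration

`run_flex_report()` executes reading, RMSD, windowed RMSF, differential
mobility against the designated reference, cavity volumes over the
trailing frames, and distance histograms from a single config (YAML via
`read_config()` or a plain list), writing one TSV per stage and a
`summary.json`; any stage failure aborts with a stage-labeled message and
partial outputs are retained. `run_kinetics_report()` fits all configured
rate and decay tables (a failing dataset is warned about and skipped, the
run continues) and writes table-shaped TSV/JSON reports. Re-running with
the same config and seed reproduces outputs exactly. The package is
function-first: these two entry points plus the exported primitives are
the interface, and `scripts/acceptance.R` re-derives the headline numbers
from an installed copy.

## Known limitations

* The windowed RMSF carries a small (~1% at 100 residues) downward bias
  from superposition absorbing rigid degrees of freedom; it is common to
  variant and reference and cancels in differences.
* The 1-SD mobility rule has a ~32% null flag rate by construction; treat
  calls as a ranking, corroborated across windows/replicas, not as
  hypothesis tests.
* Cavity volumes depend on the unreported probe/contiguity conventions;
  defaults are the minimal recipe and both knobs are exposed.
* The XYZ reader accepts only well-formed fixed blocks; binary trajectory
  formats (DCD/XTC) are out of scope.
* Km estimates from designs that do not bracket Km (e.g. saturating-only
  concentrations) are flagged but still returned; interpret the SE.
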