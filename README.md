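# upoflex

Trajectory post-processing and kinetic characterization for unspecific
peroxygenase (UPO) heme-channel variants.

UPOs oxidize a remarkably broad range of substrates with H2O2 as the
oxidant, but every peroxygenase reaction starts with the substrate
traversing a narrow channel from bulk solvent to the distal heme face. In
the laboratory-evolved variant PaDa-I, two phenylalanines at the channel
mouth (Phe76, Phe191) gate that traffic; replacing them with smaller
residues (Ala, Leu) changes both the flexibility of the surrounding loop
and helix and the shape and volume of the channel, with measurable
consequences for catalysis. `upoflex` implements the complete analysis
layer used to quantify those effects:

* **Windowed per-residue RMSF** — for each residue *i*, with the analyzed
  span split into 100-ps windows *w*,

      RMSF_i = mean_w sqrt( mean_t | r_i(t) - <r_i>_w |^2 )

  where frames are Kabsch-superposed (C-alpha) onto each window's own
  average structure. Windowing isolates local flexibility from slow
  collective drift.
* **Differential mobility calls** — per-residue differences
  `delta_i = RMSF_i(variant) - RMSF_i(reference)` are labeled
  increased/decreased when they deviate from the panel mean by more than
  one standard deviation of the differences.
* **Channel volume** — POVME-style grid volumetrics inside two 4-A
  inclusion spheres anchored to side-chain atoms of the channel triad
  (Phe69/Phe121/Phe199, CZ) and the channel mouth (positions 76/191; CB,
  CD1 or CZ depending on the residue present), with vdW clash removal and
  optional contiguity filtering.
* **Distance distributions** — C-alpha pair distances (76–191, 76–274)
  per frame and their frequency histograms.
* **Kinetics** — nonlinear Michaelis–Menten fits
  (`v = Vmax S / (Km + S)`, kcat = Vmax/[E]), first-order H2O2
  inactivation (`A = A0 exp(-k t)`, t1/2 = ln2/k), total turnover numbers,
  enzyme-unit conversion from absorbance slopes, and the Reinheitszahl
  purity ratio. The reported parameter panel for PaDa-I and its five
  channel variants ships as `reference_kinetics()` /
  `reference_inactivation()`.
* **Synthetic data with known ground truth** — helix references, Gaussian
  fluctuation trajectories (optionally with rigid-body motion and slow
  drift), cavity phantoms of analytically known volume, and noisy kinetic
  datasets. Every estimator in the package is validated against these
  generators.

Structures and trajectories are read from multi-model PDB (via bio3d) or
plain multi-frame XYZ; reports are TSV + JSON.

## Worked example

Plant a known mobility change and recover it:

```r
library(upoflex)

ref <- synth_reference(100, seed = 1)
sig <- rep(0.4, 100); sig[50:55] <- 0.8          # doubled amplitude, residues 50-55
wt  <- synth_trajectory(ref, 0.4, n_frames = 2000, frame_interval_ps = 10, seed = 101)
mut <- synth_trajectory(ref, sig, n_frames = 2000, frame_interval_ps = 10, seed = 102)

prof_wt  <- windowed_rmsf(wt,  window_ps = 100)
prof_mut <- windowed_rmsf(mut, window_ps = 100)
prof_wt
#> rmsf_profile: 100 residues, 200 windows of 100 ps over [0, 20000) ps
#>   RMSF (A): min 0.627 / median 0.645 / max 0.656

differential_mobility(prof_mut, prof_wt)
#> mobility_calls: 100 residues; threshold |delta - 0.0399| > 1 x 0.1525 A
#>   increased: 50, 51, 52, 53, 54, 55
#>   decreased: none
```

The wild-type profile sits at the closed-form expectation for sigma =
0.4 A fluctuations sampled 10 frames per window
(`0.4 * sqrt(3) * sqrt(9/10) = 0.66 A`), and the one-standard-deviation
rule flags exactly the six planted residues.

Kinetics, from a noisy synthetic assay (8 concentrations in triplicate,
5% noise) and a noiseless decay:

```r
fit_mm(synth_mm_data(286, 736, 30,
                     rep(seq(100, 2000, length.out = 8), each = 3),
                     rel_noise = 0.05, seed = 7))
#> Michaelis-Menten fit ([E] = 30 nM, n = 24):
#>   kcat     = 293.2 +/- 12 1/s
#>   Km       = 731.4 +/- 76 uM
#>   kcat/Km  = 4.01e+05 1/(M s)

fit_inactivation(synth_inactivation_data(0.181, seq(0, 15, 1.5)))
#> first-order inactivation fit (n = 11):
#>   k_inact = 0.181 +/- 0 1/min
#>   t_1/2   = 3.83 min
```

Full panel runs go through `run_flex_report()` / `run_kinetics_report()`
with a YAML or list config; see the methods vignette
(`vignettes/upoflex-methods.Rmd`) for the model details, defaults and
design choices.

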