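Package: upoflex
Title: Heme-Channel Flexibility, Cavity Volumetrics and Kinetics for
    Unspecific Peroxygenase Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories and
    kinetic characterization of unspecific peroxygenase (UPO) heme-channel
    variants. Implements windowed per-residue C-alpha RMSF with differential
    mobility calling between a variant and a reference enzyme, grid-based
    binding-pocket volumes inside atom-anchored inclusion spheres, residue
    pair distance distributions, Kabsch rigid-body superposition, and
    Michaelis-Menten, first-order inactivation and total-turnover-number
    kinetics. A synthetic-data module generates trajectories with known
    per-residue fluctuation amplitudes, cavity phantoms of analytically known
    volume, and noisy kinetic datasets, so every statistic can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
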