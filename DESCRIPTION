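Package: hgtclock
Title: Horizontal-Gene-Transfer-Constrained Molecular Clock Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for Bayesian divergence-time analyses of
    microbial lineages with reticulate gene histories. Parses posterior traces
    of dated phylogenies (one newick chronogram per line, the 'datedist'
    dialect of common dating software), applies burn-in, enforces horizontal
    gene transfer (HGT) relative time constraints -- age(donor node) >
    age(recipient node) -- by conditional post-sampling of the posterior, and
    summarizes node ages as medians with highest-posterior-density intervals.
    Includes hard fossil/geochemical calibration bounds with root priors, a
    calibrated-prior Gibbs sampler and pseudo-posterior simulators for
    validation, transfer-feasibility probabilities P(age A > age B), bundled
    model presets for phototroph dating analyses, and cross-model comparison
    of interval precision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
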