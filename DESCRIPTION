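Package: unwindFRET
Title: Single-Molecule FRET Analysis of Cas9-Induced DNA Unwinding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET (smFRET) experiments that
    probe CRISPR-Cas9 induced DNA unwinding. Provides a ground-truth-labelled synthetic
    data generator (two-state rewound/unwound kinetics, dual-channel TIRF movie
    rendering), spot detection and aperture photometry for dual-channel EMCCD movies,
    FRET-efficiency histograms with donor-only/low/high threshold classification, a
    bootstrap estimator of the unwound fraction exposed as a classed model fit, and the
    derived unwinding promiscuity and specificity statistics used to compare Cas9
    variants and guide-RNA designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
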