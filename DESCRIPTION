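Package: NanoSiMPull
Title: Single-Molecule Pulldown Analysis for Lipid Nanodisc Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for lipid Nanodisc single-molecule pulldown
    (SiMPull) experiments imaged by two-channel TIRF microscopy. Provides a
    forward simulator for sparse diffraction-limited spot movies with EMCCD
    noise and full ground truth; point-spread-function based spot detection
    and per-field counting with background subtraction; per-spot intensity
    trace extraction and two-state binarization; photobleaching step
    classification (one to four steps) by exact penalized change-point
    fitting; dwell-time kinetics with uncensored exponential maximum
    likelihood estimation of dissociation rates, likelihood-ratio rate
    comparison and rebinding quantification; mean + 2 SD binding-threshold
    derivation with one-tailed binding calls; and Nanodisc/vesicle lipid
    stoichiometry arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
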