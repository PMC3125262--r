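Package: xspecnorm
Title: Normalization and Centering of Cross-Species Array Hybridization Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Normalizes and centers probe intensities from heterologous
    (cross-species) genomic DNA hybridizations onto short-oligonucleotide
    tiling arrays. Log intensities of universally diverged control probes are
    regressed on nearest-neighbor duplex free energy (dG37) per species, and
    all probes are adjusted for the fitted thermodynamic effect and phase
    shifted so the median control probe is zero, yielding adjusted intensities
    on which zero means the non-specific baseline. Also provides the
    conventional aCGH comparison pipeline (quantile normalization, per-array
    scaling to a common mean, positional smoothing), evaluation procedures
    (conserved-gene testing with Bonferroni control, deletion ratio-track
    scans, probe-identity specificity curves, genome k-mer frequency), and a
    seeded synthetic hybridization generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
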