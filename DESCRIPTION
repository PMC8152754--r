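Package: vigildecode
Title: Temporal-Generalization EEG Decoding Across Vigilance States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate decoding of epoched EEG across vigilance states
    (wake, NREM sleep stages N1-N3, REM). Provides a seeded generator for
    multi-subject epoched EEG with state-specific background activity and
    planted binary-condition effects; trial conditioning (zero-phase FIR
    band-pass, cropping, decimation, per-trial standardization, balanced
    subsampling); per-timepoint L2-regularized logistic decoding with
    temporal generalization within and across states; conversion of
    classifier weights to forward-model activation patterns in microvolts
    via the data-covariance (Haufe) transform; and group-level
    mass-univariate Mann-Whitney testing with Benjamini-Hochberg false
    discovery rate control.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    data.table,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
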