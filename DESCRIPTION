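Package: periotherm
Title: Periorbital Skin-Temperature Analysis for Thermal-Video Startle Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting and analysing periorbital (inner-canthus)
    skin temperature from radiometric thermal video around an auditory
    startle stimulus. Provides a synthetic thermal-video phantom generator
    with ground-truth motion, drift and injected temperature effects;
    cross-search block-matching region tracking with a mean-squared-error
    criterion and an exhaustive-search oracle; robust upper-half trimmed-mean
    temperature time-series extraction with second-order Butterworth
    low-pass filtering; pre/post-stimulus window statistics (moments,
    histogram Shannon entropy, chi-squared normality, Wald-Wolfowitz runs
    test); a three-way repeated-measures mixed ANOVA (window x side x
    participant); automated detection of visible startle movement; and a
    study-level pipeline with trial accounting and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
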