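Package: mrfecg
Title: Multireceptive-Field Convolutional Networks for Multilabel 12-Lead ECG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates a lightweight multireceptive-field
    one-dimensional convolutional network (MRF-CNN) for multilabel
    classification of 12-lead electrocardiograms. Convolutional blocks combine
    parallel kernels of size 7, 5 and 1 at dilation rates 1 and 2 so that one
    layer sees receptive fields of 1 to 13 samples, matching the range of
    P-QRS-T feature durations. Includes a parameter-budget solver that fixes
    the per-block filter widths against published parameter totals, a
    sliding-window inference scheme with element-wise-maximum aggregation, the
    full label-based and example-based multilabel evaluation suite (macro and
    micro averaging, ROC AUC, F_max), a synthetic multilabel 12-lead ECG
    generator for dependency-free testing, and readers for WFDB-format ECG
    databases such as PTB-XL.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
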