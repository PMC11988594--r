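Package: kelptrace
Title: Geographical-Origin Traceability of Kelp from GC-IMS Volatile Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for authenticating the geographical origin
    of kelp (Laminaria japonica) from gas chromatography-ion mobility
    spectrometry (GC-IMS) volatile organic compound (VOC) intensity tables.
    Ships a curated reference table of 115 VOC features with per-origin
    signal-intensity distributions for three Chinese coastal cities
    (Rongcheng, Dalian, Xiapu), a synthetic cohort generator parameterized by
    those distributions, per-feature one-way ANOVA screening with Duncan's
    multiple range letter grouping, a compact one-dimensional convolutional
    neural network classifier trained by Adam on categorical cross-entropy,
    leakage-free standardization with stratified splitting, confusion-matrix
    and one-vs-rest ROC/AUC evaluation, and Shapley-value attribution (exact
    enumeration and antithetic permutation sampling over a masking value
    function) at global and local levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
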