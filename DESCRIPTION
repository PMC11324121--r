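Package: ecgmae
Title: Masked-Autoencoder Pretraining for 12-Lead Electrocardiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pretraining of Vision Transformer encoders on
    12-lead electrocardiograms (ECGs) with a masked autoencoder (MAE), and the
    downstream protocol for detecting left-ventricular systolic dysfunction
    (LVSD) from ECGs. Records are 10-second, 500 Hz, 12-lead voltage matrices
    split into a 12 x 20 grid of half-second patches; a large fraction of
    patches is masked, only visible patches are encoded, and a light decoder
    reconstructs the masked voltage. Includes lead-aware patchification with
    random, grid and per-lead masking strategies, a compiled transformer
    core with manual backpropagation, plateau learning-rate scheduling with
    early stopping, cohort construction from paired ECG-echocardiography
    tables, a synthetic multi-ECG-per-patient cohort generator with an
    ejection-fraction-linked morphology signal, PTB-XL-style multi-label
    task loading, and rank-based AUROC with DeLong confidence intervals and
    paired comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
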