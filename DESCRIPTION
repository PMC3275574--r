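Package: tfanca
Title: Transcription Factor Activity Inference by Network Component Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deduces transcription factor activities (TFAs) from target-gene
    expression under a fixed TF-to-gene connectivity pattern using network
    component analysis (NCA), a constrained bilinear decomposition E = A * P
    in which the zero pattern of the control-strength matrix A is dictated by
    known regulatory interactions.  Includes structural identifiability
    checks, an alternating-least-squares solver, null calibration of TFA
    significance against random-gene networks with robust modified z-scores,
    connectivity trimming of spurious edges, and downstream TFA-signature
    analytics: uncentered-correlation hierarchical clustering of samples,
    chi-squared association of cluster groups with a binary functional
    status, per-TF differential tests, signature derivation, and TFA
    co-activity structure.  A synthetic-data generator with planted ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    broom,
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
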