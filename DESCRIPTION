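Package: fltrt
Title: Early FLT-PET Response to Radiotherapy in NSCLC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and statistical analysis of early changes in
    3'-deoxy-3'-[18F]fluorothymidine (FLT) PET uptake in non-small cell lung
    cancer under radiotherapy. Converts activity-concentration images to
    standardized uptake value (SUV) maps, extracts per-lesion volume, SUV_mean
    and SUV_max with bone-marrow overlap quality control, computes test-retest
    repeatability coefficients and percentage radiotherapy response,
    biologically effective dose, and fits a log10-scale offset ANCOVA with a
    cross-patient random intercept by profile maximum likelihood, giving
    lesion-type-specific back-transformed effect sizes with confidence
    intervals and variance partitions. Includes rank-based statistics with
    exact small-sample options, Kaplan-Meier and univariate Cox outcome
    analysis, and a synthetic cohort and phantom generator that reproduces the
    statistical structure the models assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    survival,
    withr
Config/testthat/edition: 3
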