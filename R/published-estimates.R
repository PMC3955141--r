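#' Published offset-ANCOVA estimates for the FLT-PET radiotherapy study
#'
#' Reference fixed effects and variance components reported for the
#' duplicate-baseline (model A) and response (model B) fits of the
#' clinical FLT-PET cohort, per lesion parameter on the log10 scale.
#' These are inputs for desk-scale recalculations (back-transformed effect
#' sizes, variance partitions), not outputs of this package's fits.
#'
#' @return Data frame with columns `model` (A/B), `parameter`, `beta0`,
#'   `beta0_se`, `beta0_p`, `beta1`, `beta1_se`, `beta1_p`, `sigma_b2`,
#'   `sigma2`, `aic`.
#' @seealso [back_transform_effect()], [variance_partition()]
#' @export
published_model_fits <- function() {
  data.frame(
    model = rep(c("A", "B"), each = 3),
    parameter = rep(c("suv_mean", "suv_max", "volume_cm3"), 2),
    beta0 = c(-0.014, 0.024, 0.041, -0.127, -0.119, 0.018),
    beta0_se = c(0.025, 0.026, 0.031, 0.025, 0.029, 0.073),
    beta0_p = c(0.60, 0.37, 0.11, 0.0001, 0.0007, 0.81),
    beta1 = c(0.015, -0.025, -0.025, -0.095, -0.147, -0.177),
    beta1_se = c(0.032, 0.027, 0.031, 0.029, 0.035, 0.089),
    beta1_p = c(0.65, 0.38, 0.43, 0.004, 0.0006, 0.06),
    sigma_b2 = c(0.00000, 0.00188, 0.00300, 0.00224, 0.00154, 0.00858),
    sigma2 = c(0.00448, 0.00291, 0.00374, 0.00556, 0.00839, 0.05579),
    aic = c(-28.78, -30.20, -25.42, -45.24, -37.02, 15.46))
}

#' Published test-retest reproducibility summaries
#'
#' Reference mean and SD of the duplicate-baseline percentage differences
#' (with the mean absolute difference) per parameter and lesion group, as
#' reported for the clinical reproducibility cohort (7 primaries,
#' 11 nodes). The repeatability coefficient follows as `1.96 * SD`.
#'
#' @return Data frame with columns `parameter`, `lesion_group`, `n`,
#'   `mean_diff_pct`, `sd_diff_pct`, `abs_repro_pct`.
#' @export
published_reproducibility <- function() {
  data.frame(
    parameter = rep(c("volume_cm3", "suv_mean", "suv_max"), each = 3),
    lesion_group = rep(c("primary", "node", "all"), 3),
    n = rep(c(7L, 11L, 18L), 3),
    mean_diff_pct = c(9.5, 8.4, 8.8, -2.9, 0.6, -0.8, 5.7, 3.1, 4.1),
    sd_diff_pct = c(12.8, 22.5, 18.9, 8.9, 18.0, 14.9, 12.6, 17.2, 15.3),
    abs_repro_pct = c(9.8, 19.3, 15.6, 6.8, 11.9, 9.9, 9.5, 14.0, 12.3))
}
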