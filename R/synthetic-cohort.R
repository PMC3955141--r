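#' Configuration for the synthetic FLT-PET cohort generator
#'
#' Defines the statistical structure of a simulated cohort: each patient
#' carries one primary tumour and a uniform random number of nodal lesions;
#' every lesion receives duplicate baseline scans (S1, S2) differing only
#' by test-retest measurement noise, and an on-treatment scan (S3) whose
#' log10 value follows the offset random-intercept model
#' `log10(S3) = log10(latest baseline) + beta0 + b_i + beta1 * node + eps`.
#' All three lesion parameters (volume, SUV_mean, SUV_max) are generated.
#'
#' Baseline values are lognormal; `baseline_log10_mean_*` and
#' `baseline_log10_sd` are the log10-scale mean and SD per parameter.
#' Model coefficients and variances may be scalars (recycled) or named
#' length-3 vectors over `volume_cm3`, `suv_mean`, `suv_max`.
#'
#' @param n_patients Positive integer.
#' @param nodes_per_patient_range Integer interval `c(lo, hi)`, `lo >= 0`.
#' @param baseline_log10_mean_primary,baseline_log10_mean_node Named
#'   length-3 numeric vectors (log10 scale).
#' @param baseline_log10_sd Positive, per parameter (log10 scale).
#' @param beta0 Treatment effect for primaries (log10 scale).
#' @param beta1 Node-primary contrast (log10 scale).
#' @param sigma_b2 Cross-patient random-intercept variance (>= 0).
#' @param sigma2 Residual lesion-level variance (> 0).
#' @param retest_sd_log10 SD of pure test-retest noise (log10 scale, > 0).
#' @param share_random_intercept If `TRUE` one patient effect `b_i` is
#'   shared by all three parameters; default `FALSE` (independent draws,
#'   as each parameter is modelled separately).
#' @param seed Integer seed driving a single random stream.
#' @return Object of class `flt_cohort_config`.
#' @seealso [cohort_config_response()], [cohort_config_reproducibility()]
#' @export
cohort_config <- function(n_patients,
                          nodes_per_patient_range = c(1, 2),
                          baseline_log10_mean_primary,
                          baseline_log10_mean_node,
                          baseline_log10_sd,
                          beta0 = 0, beta1 = 0,
                          sigma_b2 = 0, sigma2 = 1e-4,
                          retest_sd_log10 = 0.05,
                          share_random_intercept = FALSE,
                          seed = 1L) {
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  expand <- function(x, name) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 3), pars)
    if (is.null(names(x))) names(x) <- pars
    if (!all(pars %in% names(x)))
      stop(name, " must be a scalar or named over ", paste(pars, collapse = ", "))
    x[pars]
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    nodes_per_patient_range = as.integer(nodes_per_patient_range),
    baseline_log10_mean_primary = expand(baseline_log10_mean_primary,
                                         "baseline_log10_mean_primary"),
    baseline_log10_mean_node = expand(baseline_log10_mean_node,
                                      "baseline_log10_mean_node"),
    baseline_log10_sd = expand(baseline_log10_sd, "baseline_log10_sd"),
    beta0 = expand(beta0, "beta0"), beta1 = expand(beta1, "beta1"),
    sigma_b2 = expand(sigma_b2, "sigma_b2"),
    sigma2 = expand(sigma2, "sigma2"),
    retest_sd_log10 = expand(retest_sd_log10, "retest_sd_log10"),
    share_random_intercept = isTRUE(share_random_intercept),
    seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("empty cohort: n_patients must be >= 1")
  if (length(cfg$nodes_per_patient_range) != 2L ||
      cfg$nodes_per_patient_range[1] < 0L ||
      diff(cfg$nodes_per_patient_range) < 0L)
    stop("nodes_per_patient_range must be a nondecreasing interval with lower bound >= 0")
  if (any(cfg$sigma2 <= 0)) stop("sigma2 must be strictly positive")
  if (any(cfg$sigma_b2 < 0)) stop("sigma_b2 must be nonnegative")
  if (any(cfg$baseline_log10_sd < 0)) stop("baseline_log10_sd must be nonnegative")
  if (any(cfg$retest_sd_log10 < 0)) stop("retest_sd_log10 must be nonnegative")
  structure(cfg, class = "flt_cohort_config")
}

#' Log10-scale lognormal moments matched to natural-scale mean and SD
#'
#' Moment matching for a lognormal variable: given the natural-scale mean
#' `m` and SD `s`, returns the log10-scale mean and SD of the matching
#' lognormal distribution.
#'
#' @param mean_natural,sd_natural Positive natural-scale moments.
#' @return List with `mean_log10` and `sd_log10`.
#' @export
lognormal_log10_moments <- function(mean_natural, sd_natural) {
  if (any(mean_natural <= 0)) stop("mean must be positive")
  v_ln <- log1p((sd_natural / mean_natural)^2)
  mu_ln <- log(mean_natural) - v_ln / 2
  list(mean_log10 = mu_ln / log(10), sd_log10 = sqrt(v_ln) / log(10))
}

# Published cohort-level summary moments used by the presets: natural-scale
# baseline mean/SD per lesion type and parameter, and log10-scale
# test-retest noise SDs implied by the duplicate-baseline variance
# components (sd = sqrt((sigma_b2 + sigma2)/2) of the reproducibility fit).
preset_moments <- function(which = c("response", "reproducibility")) {
  which <- match.arg(which)
  if (which == "response") {
    base <- list(primary = list(mean = c(volume_cm3 = 78, suv_mean = 2.2, suv_max = 5.3),
                                sd = c(volume_cm3 = 56, suv_mean = 0.7, suv_max = 2.0)),
                 node = list(mean = c(volume_cm3 = 7.4, suv_mean = 1.7, suv_max = 3.2),
                             sd = c(volume_cm3 = 5.3, suv_mean = 0.4, suv_max = 0.9)))
  } else {
    base <- list(primary = list(mean = c(volume_cm3 = 38, suv_mean = 1.6, suv_max = 3.5),
                                sd = c(volume_cm3 = 31, suv_mean = 0.7, suv_max = 1.7)),
                 node = list(mean = c(volume_cm3 = 7.5, suv_mean = 2.1, suv_max = 4.0),
                             sd = c(volume_cm3 = 4.0, suv_mean = 0.5, suv_max = 1.3)))
  }
  retest_var <- c(volume_cm3 = 0.00300 + 0.00374,
                  suv_mean = 0.00000 + 0.00448,
                  suv_max = 0.00188 + 0.00291)
  list(baseline = base, retest_sd_log10 = sqrt(retest_var / 2))
}

#' Preset: response-cohort study conditions
#'
#' A 12-patient cohort (12 primaries, 1-2 nodes each, 18 nodes expected),
#' baseline lognormal moments matched to the published response-cohort
#' summaries, treatment effects and variance components set to the
#' published response-model (model B) estimates per parameter, and
#' test-retest noise implied by the duplicate-baseline variance components.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size (default 12, the study's response cohort).
#' @return `flt_cohort_config`.
#' @export
cohort_config_response <- function(seed = 1L, n_patients = 12L) {
  m <- preset_moments("response")
  bp <- lognormal_log10_moments(m$baseline$primary$mean, m$baseline$primary$sd)
  bn <- lognormal_log10_moments(m$baseline$node$mean, m$baseline$node$sd)
  cohort_config(
    n_patients = n_patients,
    nodes_per_patient_range = c(1, 2),
    baseline_log10_mean_primary = bp$mean_log10,
    baseline_log10_mean_node = bn$mean_log10,
    baseline_log10_sd = (bp$sd_log10 + bn$sd_log10) / 2,
    beta0 = c(volume_cm3 = 0.018, suv_mean = -0.127, suv_max = -0.119),
    beta1 = c(volume_cm3 = -0.177, suv_mean = -0.095, suv_max = -0.147),
    sigma_b2 = c(volume_cm3 = 0.00858, suv_mean = 0.00224, suv_max = 0.00154),
    sigma2 = c(volume_cm3 = 0.05579, suv_mean = 0.00556, suv_max = 0.00839),
    retest_sd_log10 = m$retest_sd_log10,
    seed = seed)
}

#' Preset: reproducibility-cohort study conditions
#'
#' A 7-patient cohort (7 primaries, 1-2 nodes each) with baseline moments
#' matched to the published duplicate-baseline summaries; treatment effects
#' null (the duplicate-baseline model found no systematic drift), retest
#' noise from the duplicate-baseline variance components.
#'
#' @param seed Integer seed.
#' @param n_patients Cohort size (default 7).
#' @return `flt_cohort_config`.
#' @export
cohort_config_reproducibility <- function(seed = 1L, n_patients = 7L) {
  m <- preset_moments("reproducibility")
  bp <- lognormal_log10_moments(m$baseline$primary$mean, m$baseline$primary$sd)
  bn <- lognormal_log10_moments(m$baseline$node$mean, m$baseline$node$sd)
  cohort_config(
    n_patients = n_patients,
    nodes_per_patient_range = c(1, 2),
    baseline_log10_mean_primary = bp$mean_log10,
    baseline_log10_mean_node = bn$mean_log10,
    baseline_log10_sd = (bp$sd_log10 + bn$sd_log10) / 2,
    beta0 = 0, beta1 = 0,
    sigma_b2 = c(volume_cm3 = 0.00300, suv_mean = 0, suv_max = 0.00188),
    sigma2 = c(volume_cm3 = 0.00374, suv_mean = 0.00448, suv_max = 0.00291),
    retest_sd_log10 = m$retest_sd_log10,
    seed = seed)
}

#' Generate a synthetic lesion-level cohort table
#'
#' Simulates the tidy cohort table the downstream analyses consume. Draw
#' order (one stream seeded from `config$seed`): per patient, the nodal
#' lesion count, then the patient random intercept(s) `b_i`; per lesion and
#' parameter, the true baseline log10 value, two independent test-retest
#' noise draws (S1, S2), and the residual `eps` for the on-treatment scan.
#' The on-treatment log10 value is the measured latest baseline (S2) plus
#' `beta0 + b_i + beta1 * node + eps`. All values are returned on the
#' natural scale (strictly positive).
#'
#' @param config An `flt_cohort_config` (see [cohort_config()]).
#' @return Tidy data frame: `patient_id`, `lesion_id`, `lesion_type`
#'   (`primary`/`node`), `scan_label` (`S1`/`S2`/`S3`), `volume_cm3`,
#'   `suv_mean`, `suv_max`. Bit-identical across runs for a fixed seed.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "flt_cohort_config"))
    stop("config must be built with cohort_config()")
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  set.seed(config$seed)
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", i)
    rng <- config$nodes_per_patient_range
    n_nodes <- if (rng[1] == rng[2]) rng[1]
               else sample(seq(rng[1], rng[2]), 1L)
    if (config$share_random_intercept) {
      b1 <- stats::rnorm(1)
      bi <- b1 * sqrt(config$sigma_b2)
    } else {
      bi <- stats::rnorm(3) * sqrt(config$sigma_b2)
    }
    names(bi) <- pars
    types <- c("primary", rep("node", n_nodes))
    for (j in seq_along(types)) {
      type <- types[j]
      lid <- sprintf("%s_L%d", pid, j)
      is_node <- as.numeric(type == "node")
      mu <- if (type == "node") config$baseline_log10_mean_node
            else config$baseline_log10_mean_primary
      vals <- matrix(NA_real_, nrow = 3, ncol = 3,
                     dimnames = list(c("S1", "S2", "S3"), pars))
      for (p in pars) {
        base <- stats::rnorm(1, mu[p], config$baseline_log10_sd[p])
        s1 <- base + stats::rnorm(1, 0, config$retest_sd_log10[p])
        s2 <- base + stats::rnorm(1, 0, config$retest_sd_log10[p])
        eps <- stats::rnorm(1, 0, sqrt(config$sigma2[p]))
        s3 <- s2 + config$beta0[p] + bi[p] + config$beta1[p] * is_node + eps
        vals[, p] <- 10^c(s1, s2, s3)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, lesion_id = lid, lesion_type = type,
        scan_label = rownames(vals), vals, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic survival records linked to on-treatment uptake
#'
#' Draws exponential event times whose log hazard is linear in each
#' patient's on-treatment (S3) primary-tumour SUV_max, with independent
#' exponential censoring. Used to exercise the outcome analyses with a
#' known true hazard ratio `exp(link)` per covariate unit.
#'
#' @param cohort Tidy cohort table with S3 scans (see [generate_cohort()]).
#' @param link Log hazard ratio per covariate unit (0 = null).
#' @param baseline_hazard Positive baseline hazard (events per month).
#' @param censor_rate Target censoring fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame: `patient_id`, `time_months`, `event` (logical),
#'   `covariate` (on-treatment primary SUV_max).
#' @export
generate_survival <- function(cohort, link = 0, baseline_hazard = 0.05,
                              censor_rate = 0.3, seed = 1L) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censor_rate < 0 || censor_rate > 1) stop("censor_rate must be in [0, 1]")
  prim <- cohort[cohort$lesion_type == "primary" & cohort$scan_label == "S3", ]
  prim <- prim[!duplicated(prim$patient_id), ]
  if (nrow(prim) == 0L) stop("each patient needs an on-treatment (S3) primary SUV_max")
  set.seed(seed)
  x <- prim$suv_max
  rate <- baseline_hazard * exp(link * x)
  t_event <- stats::rexp(nrow(prim), rate)
  if (censor_rate >= 1) {
    time <- stats::rexp(nrow(prim), baseline_hazard)
    event <- rep(FALSE, nrow(prim))
  } else if (censor_rate == 0) {
    time <- t_event
    event <- rep(TRUE, nrow(prim))
  } else {
    c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
    t_cens <- stats::rexp(nrow(prim), c_rate)
    time <- pmin(t_event, t_cens)
    event <- t_event <= t_cens
  }
  data.frame(patient_id = prim$patient_id, time_months = time,
             event = event, covariate = x)
}

#' @export
print.flt_cohort_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d patients, %d-%d nodes each, seed %d\n",
    x$n_patients, x$nodes_per_patient_range[1], x$nodes_per_patient_range[2],
    x$seed))
  invisible(x)
}

#' Write / read a tidy cohort table as CSV
#'
#' @param cohort Tidy cohort data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
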