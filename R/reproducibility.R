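#' Test-retest percentage difference
#'
#' Percentage difference of duplicate baseline measurements relative to
#' their mean: `(scan2 - scan1) / (scan1 + scan2) * 200`. Antisymmetric
#' under swapping the scans and bounded in (-200, 200) for positive inputs.
#'
#' @param scan1,scan2 Positive numeric vectors (recycled).
#' @return Numeric vector of percentage differences.
#' @examples
#' test_retest_difference(2.0, 2.5)  # +22.22
#' @export
test_retest_difference <- function(scan1, scan2) {
  if (any(scan1 <= 0) || any(scan2 <= 0))
    stop("scan values must be strictly positive")
  (scan2 - scan1) / (scan1 + scan2) * 200
}

#' Reproducibility summary of test-retest differences
#'
#' Summarizes test-retest percentage differences per lesion group and
#' parameter: mean, sample SD (the reproducibility), mean absolute
#' difference (absolute reproducibility) and the repeatability coefficient
#' `RC = 1.96 * SD` -- the change a response must exceed to be
#' distinguishable from measurement noise.
#'
#' Averaging is across lesions by default, matching summaries in which all
#' lesions of a group are pooled. With `averaging = "patient"` each
#' patient's lesion differences are first averaged so the SD is taken
#' across patient means.
#'
#' @param records Data frame with columns `patient_id`, `lesion_type`,
#'   `parameter`, `diff_pct` (one row per lesion x parameter). See
#'   [test_retest_records()].
#' @param by Grouping: `"lesion_type"` (primaries and nodes separately,
#'   plus a pooled `"all"` row per parameter) or `"all"` only.
#' @param averaging `"lesion"` or `"patient"`.
#' @return Data frame with columns `parameter`, `lesion_group`, `n`,
#'   `mean_diff_pct`, `sd_diff_pct`, `abs_repro_pct`, `rc_pct`.
#' @export
summarize_reproducibility <- function(records,
                                      by = c("lesion_type", "all"),
                                      averaging = c("lesion", "patient")) {
  by <- match.arg(by)
  averaging <- match.arg(averaging)
  stopifnot(all(c("patient_id", "lesion_type", "parameter", "diff_pct") %in%
                names(records)))
  one <- function(df, group_label) {
    d <- df$diff_pct
    if (averaging == "patient")
      d <- tapply(df$diff_pct, df$patient_id, mean)
    n <- length(d)
    if (n < 2L) stop("need at least 2 observations for an SD")
    s <- stats::sd(d)
    data.frame(parameter = df$parameter[1], lesion_group = group_label,
               n = n, mean_diff_pct = mean(d), sd_diff_pct = s,
               abs_repro_pct = mean(abs(d)), rc_pct = 1.96 * s)
  }
  out <- lapply(split(records, records$parameter), function(df) {
    rows <- list(one(df, "all"))
    if (by == "lesion_type") {
      grp <- lapply(split(df, df$lesion_type), function(g)
        one(g, as.character(g$lesion_type[1])))
      rows <- c(grp, rows)
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build test-retest records from a tidy cohort table
#'
#' Pairs the two baseline scans (S1, S2) of every lesion and computes the
#' test-retest difference for each parameter. Lesions lacking either
#' baseline scan are dropped.
#'
#' @param cohort Tidy cohort data frame (see [generate_cohort()]).
#' @return Long data frame: `patient_id`, `lesion_id`, `lesion_type`,
#'   `parameter`, `scan1_value`, `scan2_value`, `diff_pct`, `mean_value`.
#' @export
test_retest_records <- function(cohort) {
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  s1 <- cohort[cohort$scan_label == "S1", ]
  s2 <- cohort[cohort$scan_label == "S2", ]
  m <- merge(s1, s2, by = c("patient_id", "lesion_id", "lesion_type"),
             suffixes = c("_s1", "_s2"))
  if (nrow(m) == 0L) stop("no lesions with duplicate baseline scans")
  out <- lapply(pars, function(p) {
    data.frame(patient_id = m$patient_id, lesion_id = m$lesion_id,
               lesion_type = m$lesion_type, parameter = p,
               scan1_value = m[[paste0(p, "_s1")]],
               scan2_value = m[[paste0(p, "_s2")]],
               diff_pct = test_retest_difference(m[[paste0(p, "_s1")]],
                                                 m[[paste0(p, "_s2")]]),
               mean_value = (m[[paste0(p, "_s1")]] + m[[paste0(p, "_s2")]]) / 2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Size dependence of test-retest variability
#'
#' Spearman correlation between absolute test-retest differences and the
#' mean of the two baseline values, the diagnostic used to decide whether a
#' single repeatability coefficient is appropriate across lesion sizes.
#'
#' @param records Test-retest records for one parameter
#'   (see [test_retest_records()]).
#' @return `flt_cor` result (rho, two-sided p).
#' @export
size_dependence <- function(records) {
  if (length(unique(records$parameter)) != 1L)
    stop("records must hold a single parameter")
  spearman_cor(abs(records$diff_pct), records$mean_value)
}

#' Classify a response against the repeatability interval
#'
#' Compares a percentage response to `mean_bias_pct +/- rc_pct`. A change is
#' called only when it falls strictly outside the closed interval, i.e.
#' values on the boundary are classified `within` (conservative calling).
#'
#' @param response_pct Numeric vector of percentage responses.
#' @param rc_pct Repeatability coefficient(s) (positive, percent; recycled).
#' @param mean_bias_pct Mean test-retest difference (percent), default 0.
#' @return Factor with levels `exceeds_decrease`, `within`,
#'   `exceeds_increase`.
#' @export
classify_change <- function(response_pct, rc_pct, mean_bias_pct = 0) {
  if (any(rc_pct <= 0)) stop("rc_pct must be positive")
  lo <- mean_bias_pct - rc_pct
  hi <- mean_bias_pct + rc_pct
  factor(ifelse(response_pct < lo, "exceeds_decrease",
         ifelse(response_pct > hi, "exceeds_increase", "within")),
         levels = c("exceeds_decrease", "within", "exceeds_increase"))
}
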