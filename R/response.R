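#' Percentage response relative to baseline
#'
#' Standard relative change: `(scan3 - baseline) / baseline * 100`.
#'
#' @param baseline Positive numeric vector (latest/single baseline value).
#' @param scan3 Numeric vector, the on-treatment value.
#' @return Percentage change.
#' @examples
#' percent_response(2.0, 1.5)  # -25
#' @export
percent_response <- function(baseline, scan3) {
  if (any(baseline <= 0)) stop("baseline must be strictly positive")
  (scan3 - baseline) / baseline * 100
}

#' Select the baseline scan for response calculation
#'
#' The latest available baseline is used: Scan2 when the lesion has
#' duplicate baselines, otherwise Scan1.
#'
#' @param scans Data frame of one lesion's scans with columns `scan_label`
#'   and the value columns.
#' @return List with `scan_label` (`"S1"` or `"S2"`) and `row` (the chosen
#'   row of `scans`).
#' @export
select_baseline <- function(scans) {
  lab <- if ("S2" %in% scans$scan_label) "S2"
         else if ("S1" %in% scans$scan_label) "S1"
         else stop("lesion has no baseline scan (S1 or S2)")
  list(scan_label = lab, row = scans[scans$scan_label == lab, , drop = FALSE])
}

#' Biologically effective dose
#'
#' Linear-quadratic BED for a fractionation schedule:
#' `BED = n * D * (1 + D / (alpha/beta))`, with `n` fractions of `D` Gy
#' each. The conventional tumour `alpha/beta` of 10 Gy is the default. When
#' evaluated at an on-treatment scan, `n_fractions` is the number of
#' fractions delivered before that scan.
#'
#' @param n_fractions Positive integer, fractions delivered.
#' @param dose_per_fraction_Gy Positive dose per fraction (Gy).
#' @param alpha_beta_Gy Tissue alpha/beta ratio (Gy), default 10.
#' @return BED in Gy.
#' @examples
#' bed(20, 2.75)  # 70.125 Gy for a 55 Gy / 20 fraction schedule
#' @export
bed <- function(n_fractions, dose_per_fraction_Gy, alpha_beta_Gy = 10) {
  if (any(n_fractions <= 0) || any(dose_per_fraction_Gy <= 0))
    stop("fractions and dose per fraction must be positive")
  if (any(alpha_beta_Gy <= 0)) stop("alpha/beta must be positive")
  n_fractions * dose_per_fraction_Gy *
    (1 + dose_per_fraction_Gy / alpha_beta_Gy)
}

#' Build per-lesion response records from a tidy cohort table
#'
#' Pairs each lesion's latest baseline (S2 if present, else S1) with its
#' on-treatment scan (S3) and computes the percentage response per
#' parameter. Lesions without an S3 scan are dropped with a warning.
#'
#' @param cohort Tidy cohort data frame (see [generate_cohort()]).
#' @param schedules Optional data frame with `patient_id`,
#'   `n_fractions_at_scan3`, `dose_per_fraction_Gy` and optionally
#'   `alpha_beta_Gy`; when given, a `bed_Gy` column is added.
#' @return Long data frame: `patient_id`, `lesion_id`, `lesion_type`,
#'   `parameter`, `baseline_value`, `baseline_scan`, `scan3_value`,
#'   `response_pct` (+ `bed_Gy`).
#' @export
response_records <- function(cohort, schedules = NULL) {
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  key <- c("patient_id", "lesion_id", "lesion_type")
  les <- unique(cohort[key])
  rows <- lapply(seq_len(nrow(les)), function(i) {
    scans <- merge(les[i, , drop = FALSE], cohort, by = key)
    if (!"S3" %in% scans$scan_label) return(NULL)
    base <- select_baseline(scans[scans$scan_label != "S3", , drop = FALSE])
    s3 <- scans[scans$scan_label == "S3", , drop = FALSE]
    do.call(rbind, lapply(pars, function(p) {
      data.frame(les[i, , drop = FALSE], parameter = p,
                 baseline_value = base$row[[p]],
                 baseline_scan = base$scan_label,
                 scan3_value = s3[[p]][1],
                 response_pct = percent_response(base$row[[p]], s3[[p]][1]))
    }))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L)
    warning(sprintf("%d lesion(s) without an on-treatment scan dropped", dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no lesion has an on-treatment (S3) scan")
  rownames(out) <- NULL
  if (!is.null(schedules)) {
    ab <- if ("alpha_beta_Gy" %in% names(schedules)) schedules$alpha_beta_Gy else 10
    schedules$bed_Gy <- bed(schedules$n_fractions_at_scan3,
                            schedules$dose_per_fraction_Gy, ab)
    out <- merge(out, schedules[c("patient_id", "bed_Gy")], by = "patient_id")
    if (anyNA(out$bed_Gy)) stop("missing RT schedule for some patients")
  }
  out
}

#' Summary of percentage responses
#'
#' Arithmetic mean and sample SD of `response_pct` per parameter, for
#' primaries, nodes and all lesions pooled. A group of size one reports an
#' `NA` SD.
#'
#' @param records Response records (see [response_records()]).
#' @param exclude_lesions Optional character vector of `lesion_id`s to drop
#'   (default none: outliers are retained).
#' @return Data frame: `parameter`, `lesion_group`, `n`, `mean_response_pct`,
#'   `sd_response_pct`.
#' @export
summarize_response <- function(records, exclude_lesions = character()) {
  records <- records[!records$lesion_id %in% exclude_lesions, ]
  if (nrow(records) == 0L) stop("no response records to summarize")
  one <- function(df, label) {
    data.frame(parameter = df$parameter[1], lesion_group = label,
               n = nrow(df), mean_response_pct = mean(df$response_pct),
               sd_response_pct = if (nrow(df) > 1) stats::sd(df$response_pct)
                                 else NA_real_)
  }
  out <- lapply(split(records, records$parameter), function(df) {
    grp <- lapply(split(df, df$lesion_type), function(g)
      one(g, as.character(g$lesion_type[1])))
    do.call(rbind, c(grp, list(one(df, "all"))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
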