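#' Run the reproducibility analysis on a cohort table
#'
#' End-to-end duplicate-baseline analysis: test-retest differences per
#' lesion and parameter, grouped reproducibility summaries with
#' repeatability coefficients, the duplicate-baseline offset ANCOVA
#' (model A: y0 = Scan1, y1 = Scan2) for all three parameters, and the
#' size-dependence diagnostic. Deterministic given the input table.
#'
#' @param cohort Tidy cohort table with S1 and S2 scans.
#' @param averaging Passed to [summarize_reproducibility()].
#' @param ... Further arguments to [fit_ancova()].
#' @return List of class `flt_repro_report`: `records`, `summary`,
#'   `model_a` (named list of `flt_ancova` per parameter),
#'   `size_dependence` (named list of `flt_cor`), `n_patients`,
#'   `n_lesions`.
#' @export
run_reproducibility <- function(cohort, averaging = c("lesion", "patient"),
                                ...) {
  averaging <- match.arg(averaging)
  records <- test_retest_records(cohort)
  summary <- summarize_reproducibility(records, averaging = averaging)
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  model_a <- lapply(stats::setNames(pars, pars), function(p)
    fit_ancova(model_input_from_cohort(cohort, "A", p), ...))
  sizedep <- lapply(stats::setNames(pars, pars), function(p)
    size_dependence(records[records$parameter == p, ]))
  structure(list(records = records, summary = summary, model_a = model_a,
                 size_dependence = sizedep,
                 n_patients = length(unique(records$patient_id)),
                 n_lesions = length(unique(records$lesion_id))),
            class = "flt_repro_report")
}

#' Run the response analysis on a cohort table
#'
#' End-to-end radiotherapy-response analysis: per-lesion percentage
#' responses against the latest baseline, group summaries, classification
#' of each response against the repeatability interval, and the response
#' offset ANCOVA (model B: y0 = latest baseline, y1 = Scan3) for all three
#' parameters -- with the BED-covariate extension when schedules are given.
#'
#' Classification follows the reproducibility structure of the analysis:
#' SUV responses are compared against the pooled (all-lesion) repeatability
#' coefficient, volume responses against the lesion-type-specific one,
#' because volume test-retest variability is size-dependent.
#'
#' @param cohort Tidy cohort table with baseline and S3 scans.
#' @param rc_summary Reproducibility summary (from
#'   [summarize_reproducibility()] or [run_reproducibility()]`$summary`);
#'   optional -- without it no classification is produced.
#' @param schedules Optional RT schedule table (see [response_records()]);
#'   enables BED and the covariate model.
#' @param ... Further arguments to [fit_ancova()].
#' @return List of class `flt_response_report`: `records`, `summary`,
#'   `classification`, `model_b` (named list of `flt_ancova`),
#'   `model_b_bed` (named list from [fit_ancova_with_covariate()], or
#'   `NULL`), `effects` (back-transformed effects table), `n_patients`,
#'   `n_lesions`.
#' @export
run_response <- function(cohort, rc_summary = NULL, schedules = NULL, ...) {
  records <- response_records(cohort, schedules = schedules)
  summary <- summarize_response(records)
  classification <- NULL
  if (!is.null(rc_summary))
    classification <- classify_responses(records, rc_summary)
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  model_b <- lapply(stats::setNames(pars, pars), function(p)
    fit_ancova(model_input_from_cohort(cohort, "B", p), ...))
  model_b_bed <- NULL
  if (!is.null(schedules)) {
    model_b_bed <- lapply(stats::setNames(pars, pars), function(p)
      fit_ancova_with_covariate(
        model_input_from_cohort(cohort, "B", p, schedules = schedules),
        covariate = "bed", ...))
  }
  effects <- do.call(rbind, lapply(pars, function(p) {
    f <- model_b[[p]]
    rbind(
      data.frame(parameter = p, lesion_group = "primary",
                 effect_pct = f$effect_primary_pct$point,
                 ci_lower_pct = f$effect_primary_pct$lower,
                 ci_upper_pct = f$effect_primary_pct$upper),
      if (!is.null(f$effect_node_pct))
        data.frame(parameter = p, lesion_group = "node",
                   effect_pct = f$effect_node_pct$point,
                   ci_lower_pct = f$effect_node_pct$lower,
                   ci_upper_pct = f$effect_node_pct$upper))
  }))
  structure(list(records = records, summary = summary,
                 classification = classification, model_b = model_b,
                 model_b_bed = model_b_bed, effects = effects,
                 n_patients = length(unique(records$patient_id)),
                 n_lesions = length(unique(records$lesion_id))),
            class = "flt_response_report")
}

#' Classify per-lesion responses against repeatability coefficients
#'
#' @param records Response records (see [response_records()]).
#' @param rc_summary Reproducibility summary with `parameter`,
#'   `lesion_group`, `mean_diff_pct`, `rc_pct` columns.
#' @return `records` with `rc_pct`, `mean_bias_pct` and `classification`
#'   columns appended.
#' @export
classify_responses <- function(records, rc_summary) {
  pick <- function(parameter, lesion_type) {
    grp <- if (parameter == "volume_cm3") lesion_type else "all"
    row <- rc_summary[rc_summary$parameter == parameter &
                        rc_summary$lesion_group == grp, ]
    if (nrow(row) == 0L)  # fall back to pooled when the type row is absent
      row <- rc_summary[rc_summary$parameter == parameter &
                          rc_summary$lesion_group == "all", ]
    row[1, c("rc_pct", "mean_diff_pct")]
  }
  sel <- mapply(function(p, lt) pick(p, lt), records$parameter,
                records$lesion_type, SIMPLIFY = FALSE)
  sel <- do.call(rbind, sel)
  records$rc_pct <- sel$rc_pct
  records$mean_bias_pct <- sel$mean_diff_pct
  records$classification <- classify_change(records$response_pct,
                                            records$rc_pct,
                                            records$mean_bias_pct)
  records
}

#' @export
print.flt_repro_report <- function(x, ...) {
  cat(sprintf("Reproducibility analysis: %d lesions in %d patients\n",
              x$n_lesions, x$n_patients))
  print(transform(x$summary,
                  mean_diff_pct = round(mean_diff_pct, 1),
                  sd_diff_pct = round(sd_diff_pct, 1),
                  abs_repro_pct = round(abs_repro_pct, 1),
                  rc_pct = round(rc_pct, 1)))
  invisible(x)
}

#' @export
print.flt_response_report <- function(x, ...) {
  cat(sprintf("Response analysis: %d lesions in %d patients\n",
              x$n_lesions, x$n_patients))
  print(transform(x$summary,
                  mean_response_pct = round(mean_response_pct, 1),
                  sd_response_pct = round(sd_response_pct, 1)))
  cat("Model-based effects (back-transformed):\n")
  print(transform(x$effects, effect_pct = round(effect_pct, 1),
                  ci_lower_pct = round(ci_lower_pct, 1),
                  ci_upper_pct = round(ci_upper_pct, 1)))
  invisible(x)
}
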