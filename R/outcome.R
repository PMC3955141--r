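#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve with Greenwood standard errors and
#' pointwise confidence limits on the log(-log) scale. The median is the
#' earliest time at which the estimated survival drops to 0.5 or below;
#' its confidence interval is the set of times whose pointwise confidence
#' band contains 0.5 (endpoints `NA` when not reached).
#'
#' @param time Positive event/censoring times.
#' @param event Logical (or 0/1): `TRUE` when the event was observed.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `flt_km`: `curve` (data frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `se`, `lower`, `upper`),
#'   `median`, `median_ci`, `n`, `n_events`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (any(time <= 0)) stop("times must be strictly positive")
  event <- as.logical(event)
  if (length(time) != length(event)) stop("length mismatch")
  n <- length(time)
  ut <- sort(unique(time))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- se <- lower <- upper <- numeric(length(ut))
  s <- 1
  gw <- 0  # running Greenwood sum
  for (k in seq_along(ut)) {
    t0 <- ut[k]
    n_risk[k] <- sum(time >= t0)
    n_event[k] <- sum(time == t0 & event)
    n_censor[k] <- sum(time == t0 & !event)
    if (n_event[k] > 0) {
      s <- s * (1 - n_event[k] / n_risk[k])
      if (n_risk[k] > n_event[k])
        gw <- gw + n_event[k] / (n_risk[k] * (n_risk[k] - n_event[k]))
      else
        gw <- Inf
    }
    surv[k] <- s
    se[k] <- s * sqrt(gw)
    if (s > 0 && s < 1 && is.finite(gw)) {
      # log(-log) transform: se of cloglog is sqrt(gw)/|log s|
      hw <- z * sqrt(gw) / abs(log(s))
      lower[k] <- s^exp(hw)
      upper[k] <- s^exp(-hw)
    } else {
      lower[k] <- if (s == 1) 1 else if (s == 0) 0 else NA_real_
      upper[k] <- if (s == 1) 1 else if (s == 0) 0 else NA_real_
    }
  }
  curve <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                      n_censor = n_censor, surv = surv, se = se,
                      lower = lower, upper = upper)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
  # median CI = {t : lower(t) <= 0.5 <= upper(t)}; the lower band crosses
  # 0.5 first, giving the earlier endpoint
  med_lo <- if (any(!is.na(lower) & lower <= 0.5))
    ut[which(!is.na(lower) & lower <= 0.5)[1]] else NA_real_
  med_hi <- if (any(!is.na(upper) & upper <= 0.5))
    ut[which(!is.na(upper) & upper <= 0.5)[1]] else NA_real_
  # upper(t) >= surv(t) >= lower(t) pointwise, so med_lo <= med <= med_hi
  structure(list(curve = curve, median = med,
                 median_ci = c(lower = med_lo, upper = med_hi),
                 conf_level = conf_level,
                 n = n, n_events = sum(event)),
            class = "flt_km")
}

#' @export
print.flt_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d subjects, %d events\n",
              x$n, x$n_events))
  if (is.na(x$median)) {
    cat("  median not reached\n")
  } else {
    cat(sprintf("  median %.2f (%.0f%% CI %s to %s)\n", x$median,
                100 * x$conf_level,
                ifelse(is.na(x$median_ci[1]), "NA",
                       sprintf("%.2f", x$median_ci[1])),
                ifelse(is.na(x$median_ci[2]), "NA",
                       sprintf("%.2f", x$median_ci[2]))))
  }
  invisible(x)
}

#' Univariate Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the Cox partial likelihood for a single
#' continuous covariate, with Efron's (default) or Breslow's handling of
#' tied event times. The hazard ratio is per one covariate unit; the Wald
#' standard error comes from the observed information at the optimum.
#'
#' Monotone partial likelihood (perfect separation of events by the
#' covariate) is flagged via `converged = FALSE` when the estimate runs
#' away beyond `|beta| > 15`.
#'
#' @param time Positive times.
#' @param event Logical event indicators; at least 2 events required.
#' @param covariate Numeric covariate, non-constant.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf_level Confidence level for the hazard-ratio CI.
#' @return Object of class `flt_cox`: `log_hr`, `se`, `hr`, `ci95`, `p`,
#'   `loglik`, `n`, `n_events`, `ties_method`, `converged`, `iterations`.
#' @export
cox_univariate <- function(time, event, covariate,
                           ties = c("efron", "breslow"),
                           conf_level = 0.95) {
  ties <- match.arg(ties)
  event <- as.logical(event)
  if (length(unique(c(length(time), length(event), length(covariate)))) != 1L)
    stop("length mismatch")
  if (any(time <= 0)) stop("times must be strictly positive")
  if (sum(event) < 2L) stop("need at least 2 observed events")
  if (stats::var(covariate) == 0) stop("covariate is constant")

  beta <- 0
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- cox_partial(beta, time, event, covariate, ties)
    if (d$info <= 0) break
    step <- d$score / d$info
    beta <- beta + step
    if (abs(beta) > 15) break           # monotone likelihood
    if (abs(step) < 1e-10 || abs(d$score) < 1e-10) { converged <- TRUE; break }
    if (iter >= 50L) break
  }
  d <- cox_partial(beta, time, event, covariate, ties)
  se <- if (d$info > 0) 1 / sqrt(d$info) else NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(log_hr = beta, se = se, hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * z * se),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 loglik = d$loglik, n = length(time), n_events = sum(event),
                 ties_method = ties, converged = converged,
                 iterations = iter),
            class = "flt_cox")
}

# partial log-likelihood, score and information for scalar beta
cox_partial <- function(beta, time, event, x, ties) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  w <- exp(beta * x)
  ll <- 0; score <- 0; info <- 0
  for (t0 in unique(time[event])) {
    risk <- time >= t0
    dead <- time == t0 & event
    dd <- sum(dead)
    s0r <- sum(w[risk]);  s1r <- sum(w[risk] * x[risk])
    s2r <- sum(w[risk] * x[risk]^2)
    s0d <- sum(w[dead]);  s1d <- sum(w[dead] * x[dead])
    s2d <- sum(w[dead] * x[dead]^2)
    ll <- ll + beta * sum(x[dead])
    if (ties == "breslow") {
      ll <- ll - dd * log(s0r)
      score <- score + sum(x[dead]) - dd * s1r / s0r
      info <- info + dd * (s2r / s0r - (s1r / s0r)^2)
    } else {
      for (l in seq_len(dd) - 1L) {
        f0 <- s0r - (l / dd) * s0d
        f1 <- s1r - (l / dd) * s1d
        f2 <- s2r - (l / dd) * s2d
        ll <- ll - log(f0)
        score <- score + sum(x[dead]) / dd - f1 / f0
        info <- info + f2 / f0 - (f1 / f0)^2
      }
    }
  }
  list(loglik = ll, score = score, info = info)
}

#' @export
print.flt_cox <- function(x, ...) {
  cat(sprintf("Cox regression (%s ties): %d subjects, %d events\n",
              x$ties_method, x$n, x$n_events))
  cat(sprintf("  HR %.3f (CI %.3f-%.3f) per unit, p = %.4g%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p,
              if (!x$converged) "  [did not converge]" else ""))
  invisible(x)
}
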