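#' Offset ANCOVA on log10-transformed lesion parameters
#'
#' Fits the random-intercept model
#' \deqn{\log_{10}(y_{1ij}) = \log_{10}(y_{0ij}) + (\beta_0 + b_i) +
#'       \beta_1 x_{1ij} + \varepsilon_{ij},}
#' where \eqn{y_{0ij}} and \eqn{y_{1ij}} are a lesion's pre and post values,
#' \eqn{x_{1ij}} indicates a nodal lesion (0 = primary, 1 = node),
#' \eqn{b_i \sim N(0, \sigma_b^2)} is a cross-patient random intercept and
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)} is lesion-level error. The
#' baseline enters as an offset (coefficient fixed at 1), so the fit is a
#' mixed model for the log-ratio \eqn{z_{ij} = \log_{10}(y_{1ij}/y_{0ij})}.
#'
#' Estimation is by maximum likelihood (default) via profiling: for a fixed
#' variance ratio \eqn{\lambda = \sigma_b^2/\sigma^2} the fixed effects and
#' \eqn{\sigma^2} have closed-form generalized-least-squares solutions
#' (the per-patient covariance blocks \eqn{I + \lambda J} invert
#' analytically), and a deterministic 1-D bounded search maximizes the
#' profile log-likelihood over \eqn{\lambda \ge 0}. ML is the default so
#' that the AIC counts all four parameters
#' \eqn{(\beta_0, \beta_1, \sigma_b^2, \sigma^2)}; REML is available for
#' variance-component reporting.
#'
#' Effect sizes are back-transformed to the natural scale:
#' \eqn{10^{\beta_0} - 1} is the mean relative change for primaries and
#' \eqn{10^{\beta_0 + \beta_1} - 1} for nodes, each with a Wald confidence
#' interval computed on the log10 scale and back-transformed endpoint-wise.
#'
#' @param data Data frame with columns `y0`, `y1` (positive), `patient`
#'   (patient identifier) and `node` (0/1 or logical lesion-type
#'   indicator). Rows with missing values are dropped listwise.
#' @param covariate Optional name of an additional numeric fixed-effect
#'   column in `data` (e.g. biologically effective dose).
#' @param method `"ML"` (default) or `"REML"`.
#' @param ci_method `"normal"` (Wald z, default) or `"t"` (Wald t with
#'   `n_lesions - p` degrees of freedom).
#' @param lambda_max Upper bound of the variance-ratio search (default 200,
#'   i.e. patient heterogeneity up to 200x the lesion-level variance).
#' @return Object of class `flt_ancova`: fixed effects with SEs and Wald
#'   p-values, `sigma_b2`, `sigma2`, `loglik` (ML log-likelihood), `aic`,
#'   back-transformed effects with CIs, `variance_partition`, `converged`,
#'   `boundary` (TRUE when the variance ratio is pinned at 0 or the search
#'   bound), `n_patients`, `n_lesions`, and the fixed-effect covariance
#'   `vcov`.
#' @seealso [back_transform_effect()], [effect_ci()], [variance_partition()]
#' @export
fit_ancova <- function(data, covariate = NULL,
                       method = c("ML", "REML"),
                       ci_method = c("normal", "t"),
                       lambda_max = 200) {
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("y0", "y1", "patient", "node") %in% names(data)))
  cols <- c("y0", "y1", "patient", "node", covariate)
  data <- data[stats::complete.cases(data[cols]), cols, drop = FALSE]
  if (any(data$y0 <= 0) || any(data$y1 <= 0))
    stop("y0 and y1 must be strictly positive (log-transformable)")
  g <- factor(data$patient)
  if (nlevels(g) < 2L) stop("need at least 2 patients")
  z <- log10(data$y1 / data$y0)
  node <- as.numeric(data$node)
  if (!all(node %in% c(0, 1))) stop("node must be a 0/1 indicator")

  drop_beta1 <- length(unique(node)) < 2L
  X <- if (drop_beta1) cbind(intercept = rep(1, length(z)))
       else cbind(intercept = 1, node = node)
  if (!is.null(covariate)) {
    cv <- data[[covariate]]
    if (stats::var(cv) == 0)
      stop("covariate '", covariate, "' is constant (collinear with intercept)")
    X <- cbind(X, cv)
    colnames(X)[ncol(X)] <- covariate
  }
  p <- ncol(X)
  n <- length(z)
  if (n <= p) stop("too few lesions for the requested fixed effects")

  reml <- method == "REML"
  obj <- function(lambda) ancova_gls(z, X, g, lambda, reml)$ll
  ll0 <- obj(0)
  opt <- stats::optimize(obj, c(0, lambda_max), maximum = TRUE, tol = 1e-9)
  if (ll0 >= opt$objective) {
    lambda_hat <- 0
  } else {
    lambda_hat <- opt$maximum
  }
  fit <- ancova_gls(z, X, g, lambda_hat, reml)
  boundary <- lambda_hat < 1e-7 || lambda_hat > lambda_max * (1 - 1e-6)
  identifiable <- any(tabulate(g) > 1L)
  if (!identifiable) boundary <- TRUE

  # ML log-likelihood at the estimates (for AIC even under REML)
  ll_ml <- if (reml) ancova_gls(z, X, g, lambda_hat, reml = FALSE)$ll else fit$ll
  k <- p + 2L
  aic <- -2 * ll_ml + 2 * k

  beta <- drop(fit$beta)
  vcov_beta <- fit$sigma2 * solve(fit$XtVX)
  se <- sqrt(diag(vcov_beta))
  dfree <- if (ci_method == "t") n - p else Inf
  pval <- 2 * stats::pt(-abs(beta / se), df = dfree)

  sigma2 <- fit$sigma2
  sigma_b2 <- lambda_hat * sigma2

  eff_primary <- effect_ci(beta[1], se[1], df = dfree)
  eff_node <- NULL
  if (!drop_beta1) {
    se_contrast <- sqrt(vcov_beta[1, 1] + vcov_beta[2, 2] + 2 * vcov_beta[1, 2])
    eff_node <- effect_ci(beta[1] + beta[2], se_contrast, df = dfree)
  }

  structure(list(
    beta = beta, se = se, p_value = pval, vcov = vcov_beta,
    sigma_b2 = sigma_b2, sigma2 = sigma2, lambda = lambda_hat,
    loglik = ll_ml, loglik_obj = fit$ll, aic = aic, k = k,
    method = method, ci_method = ci_method,
    effect_primary_pct = eff_primary,
    effect_node_pct = eff_node,
    variance_partition = variance_partition(sigma_b2, sigma2),
    converged = TRUE, boundary = boundary,
    random_effect_identifiable = identifiable,
    n_patients = nlevels(g), n_lesions = n,
    beta1_dropped = drop_beta1, covariate = covariate),
    class = "flt_ancova")
}

# GLS solution at a fixed variance ratio lambda.  Per-patient covariance
# blocks are I + lambda*J, inverted analytically as
# I - (lambda/(1+lambda*m)) J; log|I + lambda*J| = log(1 + lambda*m).
ancova_gls <- function(z, X, g, lambda, reml = FALSE) {
  n <- length(z); p <- ncol(X)
  XtVX <- matrix(0, p, p); XtVz <- numeric(p); zVz <- 0; logdet <- 0
  for (idx in split(seq_len(n), g)) {
    Xi <- X[idx, , drop = FALSE]; zi <- z[idx]; m <- length(idx)
    ci <- lambda / (1 + lambda * m)
    sX <- colSums(Xi); sz <- sum(zi)
    XtVX <- XtVX + crossprod(Xi) - ci * tcrossprod(sX)
    XtVz <- XtVz + drop(crossprod(Xi, zi)) - ci * sX * sz
    zVz <- zVz + sum(zi^2) - ci * sz^2
    logdet <- logdet + log1p(lambda * m)
  }
  beta <- solve(XtVX, XtVz)
  rss <- zVz - sum(XtVz * beta)
  rss <- max(rss, .Machine$double.eps)
  if (reml) {
    sigma2 <- rss / (n - p)
    # REML criterion: -(1/2)[(n-p)log(2*pi*sigma2) + (n-p) + log|V0|
    #                        + log|X' V0^{-1} X|]
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + (n - p) + logdet +
                    determinant(XtVX, logarithm = TRUE)$modulus[1])
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + n + logdet)
  }
  list(beta = beta, sigma2 = sigma2, ll = ll, XtVX = XtVX, logdet = logdet)
}

#' @export
print.flt_ancova <- function(x, digits = 4, ...) {
  cat(sprintf("Offset ANCOVA with patient random intercept (%s)\n", x$method))
  cat(sprintf("  %d lesions in %d patients\n", x$n_lesions, x$n_patients))
  tab <- data.frame(estimate = x$beta, se = x$se, p = x$p_value)
  print(round(tab, digits))
  cat(sprintf("  sigma_b^2 = %.5f, sigma^2 = %.5f (patient share %.1f%%)\n",
              x$sigma_b2, x$sigma2, 100 * x$variance_partition))
  cat(sprintf("  logLik = %.3f, AIC = %.2f%s\n", x$loglik, x$aic,
              if (x$boundary) "  [variance ratio at boundary]" else ""))
  ep <- x$effect_primary_pct
  cat(sprintf("  primaries: %.1f%% (CI %.1f to %.1f)\n",
              ep$point, ep$lower, ep$upper))
  if (!is.null(x$effect_node_pct)) {
    en <- x$effect_node_pct
    cat(sprintf("  nodes:     %.1f%% (CI %.1f to %.1f)\n",
                en$point, en$lower, en$upper))
  }
  invisible(x)
}

#' Fit the offset ANCOVA with and without an additional covariate
#'
#' Fits the base model and an extended model adding a linear fixed effect
#' of `covariate` (e.g. biologically effective dose), and reports the AIC
#' difference `AIC(extended) - AIC(base)`. A negative difference indicates
#' that the covariate improves the fit.
#'
#' @inheritParams fit_ancova
#' @param covariate Name of the covariate column, required here.
#' @return List with `base`, `extended` (`NULL` when the covariate is
#'   degenerate) and `delta_aic`.
#' @export
fit_ancova_with_covariate <- function(data, covariate, ...) {
  base <- fit_ancova(data, covariate = NULL, ...)
  if (stats::var(data[[covariate]], na.rm = TRUE) == 0) {
    warning("covariate '", covariate,
            "' is constant; extended model skipped")
    return(list(base = base, extended = NULL, delta_aic = NA_real_))
  }
  extended <- fit_ancova(data, covariate = covariate, ...)
  list(base = base, extended = extended,
       delta_aic = extended$aic - base$aic)
}

#' Back-transform a log10-scale effect to a percent change
#'
#' `(10^beta - 1) * 100`: the mean relative change implied by a log10-scale
#' fixed effect (use `beta0` for primaries, `beta0 + beta1` for nodes).
#'
#' @param beta Numeric vector of log10-scale effects.
#' @return Percent change.
#' @examples
#' back_transform_effect(-0.127)  # about -25%
#' @export
back_transform_effect <- function(beta) {
  (10^beta - 1) * 100
}

#' Wald confidence interval for a back-transformed effect
#'
#' Builds `beta +/- crit * se` on the log10 scale and back-transforms the
#' endpoints. The interval is symmetric on the log scale and therefore
#' asymmetric in percent.
#'
#' @param beta Log10-scale effect estimate.
#' @param se Its standard error (positive).
#' @param level Confidence level, default 0.95.
#' @param df Degrees of freedom for the critical value; `Inf` (default)
#'   gives the normal quantile.
#' @return List with `point`, `lower`, `upper` (percent).
#' @export
effect_ci <- function(beta, se, level = 0.95, df = Inf) {
  if (se < 0) stop("se must be nonnegative")
  crit <- stats::qt(1 - (1 - level) / 2, df = df)
  list(point = back_transform_effect(beta),
       lower = back_transform_effect(beta - crit * se),
       upper = back_transform_effect(beta + crit * se))
}

#' Variance partition of the random-intercept model
#'
#' Fraction of the total residual variation attributable to cross-patient
#' heterogeneity: `sigma_b2 / (sigma2 + sigma_b2)`.
#'
#' @param sigma_b2 Cross-patient variance (nonnegative).
#' @param sigma2 Lesion-level residual variance (nonnegative).
#' @return Fraction in `[0, 1]`.
#' @examples
#' variance_partition(0.00224, 0.00556)  # 0.287
#' @export
variance_partition <- function(sigma_b2, sigma2) {
  if (any(sigma_b2 < 0) || any(sigma2 < 0)) stop("variances must be nonnegative")
  if (any(sigma_b2 + sigma2 <= 0)) stop("total variance must be positive")
  sigma_b2 / (sigma_b2 + sigma2)
}

#' Assemble model input from a tidy cohort table
#'
#' Builds the `(y0, y1, patient, node)` data frame for [fit_ancova()] from
#' a long cohort table, for one parameter at a time. Model A pairs the two
#' baseline scans (`y0` = Scan1, `y1` = Scan2, the reproducibility model);
#' model B pairs the latest baseline with the on-treatment scan
#' (`y0` = S2 if present else S1, `y1` = S3, the response model). Lesions
#' missing a required scan are dropped listwise.
#'
#' @param cohort Tidy cohort data frame (see [generate_cohort()]).
#' @param model `"A"` or `"B"`.
#' @param parameter One of `"volume_cm3"`, `"suv_mean"`, `"suv_max"`.
#' @param schedules Optional schedule table (see [response_records()]);
#'   adds a `bed` column for use as a covariate (model B only).
#' @return Data frame with columns `y0`, `y1`, `patient`, `node`,
#'   `lesion_id` (+ `bed`).
#' @export
model_input_from_cohort <- function(cohort, model = c("B", "A"),
                                    parameter = c("suv_mean", "suv_max",
                                                  "volume_cm3"),
                                    schedules = NULL) {
  model <- match.arg(model)
  parameter <- match.arg(parameter)
  key <- c("patient_id", "lesion_id", "lesion_type")
  wide <- stats::reshape(
    cohort[c(key, "scan_label", parameter)],
    idvar = key, timevar = "scan_label", direction = "wide")
  val <- function(lab) wide[[paste(parameter, lab, sep = ".")]]
  if (model == "A") {
    y0 <- val("S1"); y1 <- val("S2")
  } else {
    s1 <- val("S1"); s2 <- val("S2")
    y0 <- ifelse(is.na(s2), s1, s2)
    y1 <- val("S3")
  }
  out <- data.frame(y0 = y0, y1 = y1, patient = wide$patient_id,
                    node = as.numeric(wide$lesion_type == "node"),
                    lesion_id = wide$lesion_id)
  out <- out[stats::complete.cases(out[c("y0", "y1")]), ]
  if (!is.null(schedules)) {
    ab <- if ("alpha_beta_Gy" %in% names(schedules)) schedules$alpha_beta_Gy else 10
    schedules$bed <- bed(schedules$n_fractions_at_scan3,
                         schedules$dose_per_fraction_Gy, ab)
    out <- merge(out, schedules[c("patient_id", "bed")],
                 by.x = "patient", by.y = "patient_id")
  }
  out
}
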