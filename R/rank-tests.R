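#' Spearman rank correlation with tie handling
#'
#' Computes Spearman's rho as the Pearson correlation of average ranks and a
#' two-sided p-value. The default p-value uses the t approximation with
#' `n - 2` degrees of freedom; for small samples (`n <= 10`) an exact
#' permutation p-value is available, computed by full enumeration of all
#' `n!` orderings (ties in either variable are preserved as average ranks
#' while permuting).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @param method `"t-approx"` (default) or `"exact"` (requires `n <= 10`).
#' @return A list of class `flt_cor` with elements `rho`, `p_two_sided`,
#'   `n` and `method`.
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_cor <- function(x, y, method = c("t-approx", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("rho undefined for constant input")
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 10L) stop("exact permutation only supported for n <= 10")
    p <- spearman_perm_pvalue(rx, ry)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(1, max(p, .Machine$double.xmin))
  }
  structure(list(rho = rho, p_two_sided = p, n = n, method = method),
            class = "flt_cor")
}

#' @export
print.flt_cor <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (%s)\n  rho = %.4f, p = %.4g, n = %d\n",
              x$method, x$rho, x$p_two_sided, x$n))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank sum test
#'
#' Two-sided rank sum test of a location difference between two independent
#' samples, using average ranks for ties. The exact null distribution of the
#' Mann-Whitney U statistic is used when `n1 + n2 <= 20` and there are no
#' ties; otherwise a normal approximation with tie-corrected variance and a
#' continuity correction is applied.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @return A list of class `flt_ranksum` with `statistic` (U for the first
#'   sample), `p_two_sided`, `n1`, `n2` and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty")
  r <- rank(c(x, y))
  ties <- any(duplicated(c(x, y)))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (!ties && n1 + n2 <= 20L) {
    if (u > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    nt <- table(r)
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    zc <- abs(u - mu) - 0.5           # continuity correction
    z <- if (sigma2 > 0) max(zc, 0) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal_approx"
  }
  structure(list(statistic = u, p_two_sided = p, n1 = n1, n2 = n2,
                 method = method),
            class = "flt_ranksum")
}

#' @export
print.flt_ranksum <- function(x, ...) {
  cat(sprintf("Rank sum test (%s)\n  U = %g, p = %.4g, n = %d + %d\n",
              x$method, x$statistic, x$p_two_sided, x$n1, x$n2))
  invisible(x)
}

#' Correlation matrix of baseline lesion parameters
#'
#' Pairwise Spearman correlations among baseline volume, SUV_mean and
#' SUV_max, optionally within a lesion-type subset.
#'
#' @param baseline Data frame with columns `volume_cm3`, `suv_mean`,
#'   `suv_max` (one row per lesion).
#' @return Data frame with one row per parameter pair: `rho`, `p`, `n`.
#' @export
baseline_correlations <- function(baseline) {
  pars <- c("volume_cm3", "suv_mean", "suv_max")
  stopifnot(all(pars %in% names(baseline)))
  pairs <- utils::combn(pars, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ct <- spearman_cor(baseline[[a]], baseline[[b]])
    data.frame(param_a = a, param_b = b, rho = ct$rho,
               p = ct$p_two_sided, n = ct$n)
  })
  do.call(rbind, out)
}
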