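# Independent oracles used across the suite.  These are deliberately naive
# implementations (full-matrix algebra, exhaustive enumeration) kept
# separate from the package's computational paths.

# Full-matrix ML log-likelihood of the offset ANCOVA at fixed (lambda,
# sigma2), with GLS fixed effects: V = sigma2 * (I + lambda * Z Z').
oracle_ancova_loglik <- function(z, X, patient, lambda, sigma2) {
  Z <- stats::model.matrix(~ 0 + factor(patient))
  V0 <- diag(length(z)) + lambda * tcrossprod(Z)
  V0i <- solve(V0)
  beta <- solve(t(X) %*% V0i %*% X, t(X) %*% V0i %*% z)
  r <- z - X %*% beta
  q <- drop(t(r) %*% V0i %*% r)
  -0.5 * (length(z) * log(2 * pi * sigma2) +
            determinant(V0, logarithm = TRUE)$modulus[1] + q / sigma2)
}

# Dense grid search over (lambda, sigma2); returns the best log-likelihood.
oracle_ancova_grid <- function(z, X, patient, lambda_max = 2,
                               n_grid = 50) {
  best <- -Inf
  s2_hat <- stats::var(z)
  for (lam in seq(0, lambda_max, length.out = n_grid)) {
    for (s2 in seq(s2_hat / 5, s2_hat * 3, length.out = n_grid)) {
      ll <- oracle_ancova_loglik(z, X, patient, lam, s2)
      if (ll > best) best <- ll
    }
  }
  best
}

# Exhaustive permutation p-value for Spearman's rho (feasible to n = 7).
oracle_spearman_perm <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho_obs <- abs(stats::cor(rx, ry))
  perms <- all_permutations(length(ry))
  rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= rho_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive two-sided rank-sum p-value by enumerating all n1-subsets.
oracle_ranksum_perm <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  subsets <- utils::combn(n, n1)
  u_all <- apply(subsets, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(u_all <= u_obs); hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Naive Cox partial log-likelihood (Efron), written as a direct translation
# of the estimator definition with per-subject loops.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in sort(unique(time[event]))) {
    dead <- which(time == t0 & event)
    risk <- which(time >= t0)
    d <- length(dead)
    sum_dead <- sum(exp(beta * x[dead]))
    sum_risk <- sum(exp(beta * x[risk]))
    ll <- ll + beta * sum(x[dead])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_risk - (l / d) * sum_dead)
    }
  }
  ll
}

# Deterministic small cohort fixture: 3 patients, 6 lesions, fixed values.
tiny_model_input <- function() {
  data.frame(
    y0 = c(2.1, 1.4, 3.0, 1.1, 2.6, 1.8),
    y1 = c(1.6, 1.0, 2.2, 0.7, 2.1, 1.2),
    patient = c("A", "A", "B", "B", "C", "C"),
    node = c(0, 1, 0, 1, 0, 1))
}
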