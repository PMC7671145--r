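# Phylogenetic signal statistics for tip-indexed traits: maximum-likelihood
# Pagel's lambda with a likelihood-ratio test against lambda = 0, and
# Blomberg's K with a tip-label permutation test.

#' Simulate Brownian-motion trait values on a covariance matrix
#'
#' Draws one or more trait vectors from the multivariate normal
#' distribution with mean `root_state` and covariance `rate * C`, the
#' distribution Brownian motion induces at the tips.
#'
#' @param C Phylogenetic covariance matrix (see [phylo_vcv()]).
#' @param rate Brownian rate (trait variance per unit branch length).
#' @param root_state Trait value at the root.
#' @param n Number of independent replicate vectors.
#' @return If `n == 1` a named vector; otherwise an `n` x tips matrix.
#' @export
simulate_bm <- function(C, rate = 1, root_state = 0, n = 1) {
  if (rate <= 0) stop("`rate` must be > 0")
  U <- chol_or_stop(C)
  z <- matrix(rnorm(n * nrow(C)), n, nrow(C))
  x <- root_state + sqrt(rate) * z %*% U
  colnames(x) <- rownames(C)
  if (n == 1L) x[1L, ] else x
}

new_signal_estimate <- function(statistic, value, p_value, ...) {
  structure(c(list(statistic = statistic, value = value, p_value = p_value),
              list(...)),
            class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("%s = %.4f  (n = %d, P = %.4g; %s)\n",
              if (x$statistic == "lambda") "Pagel's lambda" else "Blomberg's K",
              x$value, x$n_tips, x$p_value, x$test))
  invisible(x)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Estimates the lambda multiplier on shared-history covariances by
#' maximizing the Gaussian likelihood of the trait under covariance
#' `sigma2 * lambda_transform(C, lambda)`, with the mean profiled by GLS
#' and the rate by its maximum-likelihood value.  Significance is a
#' likelihood-ratio test against lambda = 0 (no phylogenetic structure) on
#' one chi-square degree of freedom.
#'
#' @param trait Named numeric vector (tip labels); tips with `NA` are
#'   dropped together with the matching rows/columns of `C`.
#' @param C Phylogenetic covariance matrix.
#' @param tol Optimizer tolerance on lambda.
#' @return A `"signal_estimate"` with the estimate, the LRT p-value, and
#'   log-likelihoods at the optimum, at 0 and at 1.
#' @export
pagels_lambda <- function(trait, C, tol = 1e-8) {
  a <- align_trait(trait, C)
  upper <- min(lambda_max(a$C), 1)
  ll <- function(lam)
    profile_loglik_mean(a$y, lambda_transform(a$C, lam))$loglik
  opt <- optimize(ll, c(0, upper), maximum = TRUE, tol = tol)
  # optimize() can sit just off a boundary optimum; check the endpoints.
  cand <- c(opt$maximum, 0, upper)
  vals <- c(opt$objective, ll(0), ll(upper))
  best <- which.max(vals)
  lam_hat <- cand[best]
  ll_hat <- vals[best]
  ll0 <- vals[2L]
  lrt <- max(0, 2 * (ll_hat - ll0))
  new_signal_estimate(
    "lambda", value = lam_hat,
    p_value = pchisq(lrt, df = 1, lower.tail = FALSE),
    test = "LRT vs lambda = 0 (chisq, 1 df)",
    n_tips = length(a$y),
    loglik = ll_hat, loglik0 = ll0, loglik1 = ll(min(1, upper)),
    bounds = c(0, upper), tol = tol)
}

# Observed MSE0/MSE ratio underlying Blomberg's K: MSE0 is the mean squared
# deviation of tip values from the GLS (phylogenetically corrected) mean,
# MSE the GLS rate estimate.
k_ratio <- function(y, U, ow) {
  n <- length(y)
  yw <- whiten(U, y)
  mu <- sum(ow * yw) / sum(ow * ow)
  mse0 <- sum((y - mu)^2) / (n - 1)
  r <- yw - ow * mu
  mse <- sum(r * r) / (n - 1)
  mse0 / mse
}

#' Blomberg's K with permutation test
#'
#' K is the observed ratio of trait variance among tips to the GLS rate
#' estimate, scaled by its expectation under Brownian motion on the same
#' tree, so K = 1 is exactly Brownian signal, K < 1 less, K > 1 more.
#' Significance comes from permuting trait values across tips: the p-value
#' is the proportion of permutations (the observed arrangement included)
#' whose variance ratio is at least the observed one.
#'
#' @inheritParams pagels_lambda
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional seed for the permutation stream.
#' @return A `"signal_estimate"`.
#' @export
blombergs_k <- function(trait, C, n_perm = 1000, seed = NULL) {
  if (n_perm < 99) stop("`n_perm` must be >= 99")
  a <- align_trait(trait, C)
  n <- length(a$y)
  U <- chol_or_stop(a$C)
  ow <- whiten(U, rep(1, n))
  Cinv_sum <- sum(ow * ow)                       # 1' C^-1 1
  expected <- (sum(diag(a$C)) - n / Cinv_sum) / (n - 1)
  obs <- k_ratio(a$y, U, ow)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, k_ratio(sample(a$y), U, ow))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  new_signal_estimate(
    "K", value = obs / expected, p_value = p,
    test = sprintf("permutation (one-tailed, %d permutations)", n_perm),
    n_tips = n, observed_ratio = obs, expected_ratio = expected,
    perm_ratios = perm, n_perm = n_perm, seed = seed)
}
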