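# Internal numerical helpers shared by the signal, regression and
# prediction code.  All GLS algebra goes through one Cholesky whitening
# path so the modules agree to machine precision.

# Align a named trait vector with a covariance matrix, dropping tips with
# missing values (per-trait pruning; no imputation).
align_trait <- function(trait, C, min_n = 4L) {
  if (is.null(names(trait))) stop("trait vector must be named by tip label")
  if (any(!is.finite(trait) & !is.na(trait)))
    stop("non-finite trait values present")
  keep <- names(trait)[!is.na(trait)]
  keep <- keep[keep %in% rownames(C)]
  if (length(keep) < min_n)
    stop("need at least ", min_n, " tips with data; have ", length(keep))
  list(y = trait[keep], C = C[keep, keep, drop = FALSE], tips = keep)
}

# Upper-triangular Cholesky factor with a helpful failure message.
chol_or_stop <- function(C) {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(out))
    stop("covariance matrix is not positive definite; ",
         "increase eps (near-zero branch lengths) or check the tree")
  out
}

# Whiten columns of M under covariance C = t(U) %*% U: returns U^-T M,
# so crossprod(whiten(U, x), whiten(U, y)) == t(x) %*% solve(C) %*% y.
whiten <- function(U, M) backsolve(U, M, transpose = TRUE)

# Profile log-likelihood machinery for a single-mean Gaussian on a tree:
# mu profiled by GLS, sigma2 by its ML value (quadratic form / n).
profile_loglik_mean <- function(y, C) {
  n <- length(y)
  U <- chol_or_stop(C)
  yw <- whiten(U, y)
  ow <- whiten(U, rep(1, n))
  mu <- sum(ow * yw) / sum(ow * ow)
  r <- yw - ow * mu
  s2 <- sum(r * r) / n
  logdet <- 2 * sum(log(diag(U)))
  list(mu = mu, sigma2 = s2,
       loglik = -0.5 * (n * log(2 * pi * s2) + logdet + n))
}

# Effective sample size from the initial positive sequence of
# autocorrelations (Geyer-style truncation on the lag-1 pairing).
ess <- function(x) {
  n <- length(x)
  if (n < 4L || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

# Derive a reproducible stream of sub-seeds from one master seed without
# touching the caller's RNG more than once.
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max %/% 2L, k)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
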