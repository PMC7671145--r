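# Phylogenetic generalized least squares for bivariate ln-ln allometries:
# the regression, its confidence/prediction bands under the phylogenetic
# covariance, studentized-residual outlier diagnostics, and tests against
# isometric slopes.

#' Fit a bivariate PGLS regression
#'
#' Generalized least squares of `y` on `x` with residual covariance
#' proportional to a lambda-transformed phylogenetic covariance matrix.
#' With `lambda = 0` (or an identity `C`) the fit reduces exactly to
#' ordinary least squares.  The covariance is rescaled to unit mean tip
#' depth before fitting, so the residual standard error is on the scale of
#' a single full-depth lineage; coefficients, R-squared and F are
#' invariant to that rescaling.
#'
#' @param x Named ln-scale predictor vector (tip labels).
#' @param y Named ln-scale response vector; tips missing either variable
#'   are dropped along with the matching rows of `C`.
#' @param C Phylogenetic covariance matrix from [phylo_vcv()].
#' @param lambda Either a fixed value in \[0, 1\] (default 1, pure
#'   Brownian residuals) or `"ml"` to profile lambda by maximum
#'   likelihood inside the regression.
#' @param xname,yname Variable names used in reports.
#' @return An object of class `"pgls_fit"`: coefficients (intercept,
#'   slope), their standard errors, residual standard error `SE`,
#'   R-squared, adjusted R-squared, F statistic, residual df, Brownian
#'   rate `sigma2`, the lambda used, fitted values and (raw and whitened)
#'   residuals.
#' @examples
#' C <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' fit_pgls(c(A = 0, B = 1, C = 2), c(A = 0, B = 1, C = 1), C, lambda = 1)
#' @export
fit_pgls <- function(x, y, C, lambda = 1, xname = "x", yname = "y") {
  if (is.null(names(x)) || is.null(names(y)))
    stop("`x` and `y` must be named by tip label")
  tips <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  tips <- tips[tips %in% rownames(C)]
  n <- length(tips)
  if (n < 3L) stop("need at least 3 tips with complete data; have ", n)
  x <- x[tips]; y <- y[tips]
  if (sd(x) == 0) stop("predictor is constant: design matrix rank-deficient")
  Csub <- C[tips, tips, drop = FALSE]

  if (identical(lambda, "ml")) {
    lam <- optimize(function(l) pgls_loglik(x, y, Csub, l),
                    c(0, min(lambda_max(Csub), 1)),
                    maximum = TRUE, tol = 1e-8)$maximum
  } else {
    if (!is.numeric(lambda) || length(lambda) != 1L)
      stop("`lambda` must be a number or \"ml\"")
    lam <- lambda
  }
  Cs <- lambda_transform(Csub, lam)
  Cs <- Cs / mean(diag(Cs))                       # unit mean tip depth
  U <- chol_or_stop(Cs)
  X <- cbind(`(Intercept)` = 1, slope = x)
  Xw <- whiten(U, X)
  yw <- whiten(U, y)
  qrX <- qr(Xw)
  if (qrX$rank < 2L) stop("design matrix rank-deficient after whitening")
  beta <- qr.coef(qrX, yw)
  res_w <- yw - Xw %*% beta
  rss <- sum(res_w^2)
  ow <- whiten(U, rep(1, n))
  mu <- sum(ow * yw) / sum(ow * ow)               # GLS mean of y
  tss <- sum((yw - ow * mu)^2)
  df <- n - 2L
  sigma2 <- rss / df
  XtCiX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtCiX_inv) <- list(colnames(X), colnames(X))
  se_beta <- sqrt(sigma2 * diag(XtCiX_inv))
  r2 <- 1 - rss / tss
  fitted <- drop(X %*% beta)

  structure(list(
    coefficients = setNames(as.numeric(beta), c("intercept", "slope")),
    se_coef = setNames(as.numeric(se_beta), c("intercept", "slope")),
    SE = sqrt(sigma2), sigma2 = sigma2,
    r.squared = r2,
    adj.r.squared = 1 - (1 - r2) * (n - 1) / df,
    fstatistic = (tss - rss) / (rss / df),
    df = df, n = n, lambda = lam,
    p_slope = 2 * pt(-abs(beta[2] / se_beta[2]), df),
    fitted = setNames(fitted, tips),
    residuals = setNames(y - fitted, tips),
    residuals_whitened = drop(res_w),
    xname = xname, yname = yname,
    x = x, y = y, X = X, C = Cs, chol = U,
    cov_unscaled = XtCiX_inv), class = "pgls_fit")
}

# Profile ML log-likelihood of the regression at a given lambda (beta by
# GLS, sigma2 at its ML value); used for lambda = "ml".
pgls_loglik <- function(x, y, C, lam) {
  n <- length(y)
  Cs <- lambda_transform(C, lam)
  U <- chol_or_stop(Cs)
  Xw <- whiten(U, cbind(1, x))
  yw <- whiten(U, y)
  beta <- qr.coef(qr(Xw), yw)
  rss <- sum((yw - Xw %*% beta)^2)
  s2 <- rss / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(U))) + n)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS: ln %s ~ ln %s  (n = %d, lambda = %.3f)\n",
              x$yname, x$xname, x$n, x$lambda))
  cat(sprintf("  slope     %8.4f  (se %.4f)\n",
              x$coefficients["slope"], x$se_coef["slope"]))
  cat(sprintf("  intercept %8.4f  (se %.4f)\n",
              x$coefficients["intercept"], x$se_coef["intercept"]))
  cat(sprintf("  SE %.4f   R2 %.4f (adj %.4f)   F %.1f on 1,%d df\n",
              x$SE, x$r.squared, x$adj.r.squared, x$fstatistic, x$df))
  invisible(x)
}

#' Confidence and prediction bands for a PGLS fit
#'
#' Confidence bands carry the sampling variance of the fitted line; the
#' prediction band adds the full Brownian tip variance `c00` of a new,
#' independent full-depth lineage, so it strictly contains the confidence
#' band everywhere.
#'
#' @param fit A `"pgls_fit"`.
#' @param grid Predictor (ln-scale) values at which to evaluate the bands;
#'   defaults to a 50-point grid over the observed range.
#' @param level Coverage level in (0, 1).
#' @param c00 Tip variance assigned to a new observation, on the scale of
#'   the unit-depth covariance used in the fit.  Default: mean tip depth
#'   of that covariance (1 after the fit's internal rescaling).
#' @return A data frame of class `"interval_band"` with columns `x`,
#'   `fit`, `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi`.
#' @export
pgls_intervals <- function(fit, grid = NULL, level = 0.95, c00 = NULL) {
  if (!inherits(fit, "pgls_fit")) stop("`fit` must be a pgls_fit")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("`level` must be inside (0, 1)")
  if (is.null(grid))
    grid <- seq(min(fit$x), max(fit$x), length.out = 50L)
  if (is.null(c00)) c00 <- mean(diag(fit$C))
  tq <- qt(1 - (1 - level) / 2, fit$df)
  X0 <- cbind(1, grid)
  line <- drop(X0 %*% fit$coefficients)
  v_line <- fit$sigma2 * rowSums((X0 %*% fit$cov_unscaled) * X0)
  v_pred <- fit$sigma2 * c00 + v_line
  out <- data.frame(
    x = grid, fit = line,
    ci_lo = line - tq * sqrt(v_line), ci_hi = line + tq * sqrt(v_line),
    pi_lo = line - tq * sqrt(v_pred), pi_hi = line + tq * sqrt(v_pred))
  attr(out, "level") <- level
  class(out) <- c("interval_band", "data.frame")
  out
}

#' Count observations outside the prediction band
#'
#' Evaluates the fit's prediction interval at each observed predictor
#' value and flags responses falling outside it.
#'
#' @inheritParams pgls_intervals
#' @return Data frame with one row per tip: observed values, bounds, and
#'   an `outside` flag.
#' @export
pi_coverage <- function(fit, level = 0.95, c00 = NULL) {
  band <- pgls_intervals(fit, grid = fit$x, level = level, c00 = c00)
  data.frame(tip = names(fit$x), x = fit$x, y = fit$y,
             pi_lo = band$pi_lo, pi_hi = band$pi_hi,
             outside = fit$y < band$pi_lo | fit$y > band$pi_hi,
             row.names = NULL)
}

#' Outlier diagnostics from studentized PGLS residuals
#'
#' Whitens the regression by the inverse Cholesky factor of the fitted
#' covariance (turning PGLS into an ordinary regression), computes
#' externally studentized (leave-one-out) residuals, and reports
#' Bonferroni-adjusted two-sided p-values; tips with adjusted p < 0.05
#' are flagged.
#'
#' @param fit A `"pgls_fit"` with at least 4 tips.
#' @return Data frame with one row per tip: studentized residual, raw and
#'   Bonferroni p-values, and an `outlier` flag, sorted by |residual|.
#' @export
outlier_diagnostics <- function(fit) {
  if (!inherits(fit, "pgls_fit")) stop("`fit` must be a pgls_fit")
  n <- fit$n
  if (n <= 3L) stop("studentization undefined for n <= 3")
  Xw <- whiten(fit$chol, fit$X)
  yw <- whiten(fit$chol, fit$y)
  lmw <- lm(yw ~ Xw - 1)
  ti <- rstudent(lmw)
  # an (all but) exact fit has no leave-one-out error scale: nothing to flag
  if (sum(fit$residuals_whitened^2) < 1e-16 * sum(yw^2)) ti[] <- 0
  ti[!is.finite(ti)] <- 0
  p <- 2 * pt(-abs(ti), df = n - 3L)
  out <- data.frame(tip = names(fit$x), studentized = as.numeric(ti),
                    p_value = p, p_bonferroni = pmin(1, p * n),
                    row.names = NULL)
  out$outlier <- out$p_bonferroni < 0.05
  out[order(-abs(out$studentized)), ]
}

#' Compare a fitted slope against an isometric expectation
#'
#' Isometry means slope 1 for a length-length ln-ln regression and slope 3
#' for mass against a linear dimension.  The report gives the t statistic
#' for the departure from `b_iso`, its two-sided p-value on the fit's
#' residual df, and the verbal classification at alpha = 0.05.
#'
#' @param fit A `"pgls_fit"`.
#' @param b_iso Isometric slope (1 or 3 in practice).
#' @return A list of class `"isometry_report"`.
#' @export
isometry_report <- function(fit, b_iso) {
  b <- fit$coefficients["slope"]
  se <- fit$se_coef["slope"]
  t <- (b - b_iso) / se
  p <- 2 * pt(-abs(t), fit$df)
  cls <- if (p >= 0.05) "isometry"
         else if (b > b_iso) "positive allometry" else "negative allometry"
  structure(list(slope = as.numeric(b), se = as.numeric(se), b_iso = b_iso,
                 t = as.numeric(t), p_value = as.numeric(p),
                 classification = cls, df = fit$df,
                 response = fit$yname, predictor = fit$xname),
            class = "isometry_report")
}

#' @export
print.isometry_report <- function(x, ...) {
  cat(sprintf("%s ~ %s: b = %.3f (se %.3f) vs b_iso = %g -> %s (P = %.3g)\n",
              x$response, x$predictor, x$slope, x$se, x$b_iso,
              x$classification, x$p_value))
  invisible(x)
}

#' Plot a PGLS fit with its confidence and prediction bands
#'
#' Base-graphics scatter of the ln-ln data with the fitted line, the
#' confidence band (long dash) and the prediction band (short dash).
#'
#' @param x A `"pgls_fit"`.
#' @param level Band coverage level.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the interval band used.
#' @export
plot.pgls_fit <- function(x, level = 0.95, ...) {
  band <- pgls_intervals(x, level = level)
  rng <- range(band$pi_lo, band$pi_hi, x$y)
  graphics::plot(x$x, x$y, ylim = rng,
                 xlab = paste("ln", x$xname), ylab = paste("ln", x$yname),
                 pch = 19, col = "grey30", ...)
  graphics::lines(band$x, band$fit, lwd = 2)
  graphics::lines(band$x, band$ci_lo, lty = 2)
  graphics::lines(band$x, band$ci_hi, lty = 2)
  graphics::lines(band$x, band$pi_lo, lty = 3)
  graphics::lines(band$x, band$pi_hi, lty = 3)
  invisible(band)
}
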