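# Bayesian phylogenetic prediction of a trait at a query tip: Gibbs
# sampling of the bivariate regression (intercept, slope, Brownian rate)
# under a lambda-transformed phylogenetic covariance, with a posterior
# predictive draw for the query at every retained iteration.
#
# Priors are flat on the coefficients and Jeffreys (1/sigma2) on the rate,
# which makes both conditionals conjugate (normal / inverse-gamma): the
# sampler is rejection-free and its posterior mean coincides with the PGLS
# point estimate.

#' MCMC settings for phylogenetic prediction
#'
#' @param n_posterior Total pre-thinning iterations.
#' @param burn_in Iterations discarded from the start (`< n_posterior`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Optional RNG seed; fixed seed gives bit-identical draws.
#' @param lambda Fixed lambda applied to the covariance for this trait
#'   (typically the trait's estimated phylogenetic signal).
#' @return A list of class `"mcmc_config"`; `retained` is the number of
#'   draws that will be kept.
#' @export
mcmc_config <- function(n_posterior = 20000, burn_in = 5000, thin = 100,
                        seed = NULL, lambda = 1) {
  if (burn_in >= n_posterior) stop("`burn_in` must be < `n_posterior`")
  if (thin < 1) stop("`thin` must be >= 1")
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  structure(list(n_posterior = as.integer(n_posterior),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, lambda = lambda,
                 retained = as.integer((n_posterior - burn_in) / thin)),
            class = "mcmc_config")
}

# Sufficient statistics for the Gibbs sampler and the conditional-normal
# prediction, all O(1) per iteration once computed.
prediction_workspace <- function(tree, x, y, lambda, query) {
  tips_all <- tree$tip.label
  if (!query %in% tips_all) stop("query tip ", query, " not in tree")
  if (!query %in% names(x)) stop("query needs a predictor value in `x`")
  if (query %in% names(y) && !is.na(y[query]))
    stop("query trait already observed; nothing to predict")
  obs <- intersect(tips_all, names(y)[!is.na(y)])
  obs <- intersect(obs, names(x)[!is.na(x)])
  if (length(obs) < 4L) stop("need >= 4 observed tips")
  C <- phylo_vcv(tree)[c(obs, query), c(obs, query)]
  C <- lambda_transform(C, lambda)
  C <- C / mean(diag(C[obs, obs]))                 # unit mean observed depth
  n <- length(obs)
  Coo <- C[obs, obs]
  U <- chol_or_stop(Coo)
  X <- cbind(1, x[obs])
  Xw <- whiten(U, X)
  yw <- whiten(U, y[obs])
  qrX <- qr(Xw)
  beta_hat <- qr.coef(qrX, yw)
  A <- chol2inv(qr.R(qrX))                         # (X' C^-1 X)^-1
  rss_hat <- sum((yw - Xw %*% beta_hat)^2)
  # conditional-normal weights for the query
  cqo <- C[query, obs]
  w <- drop(backsolve(U, whiten(U, cqo)))          # C_oo^-1 C_oq
  list(n = n, obs = obs, query = query,
       xq = c(1, x[[query]]),
       beta_hat = beta_hat, A = A, cholA = chol(A),
       rss_hat = rss_hat, df = n - 2L,
       yCy = sum(yw^2), XCy = drop(crossprod(Xw, yw)),
       XCX = crossprod(Xw),
       wy = sum(w * y[obs]), wX = drop(w %*% X),
       c_cond = C[query, query] - sum(w * cqo))
}

#' Closed-form conditional prediction at fixed parameters
#'
#' Mean and variance of the query trait given the observed tips, the
#' regression coefficients and the Brownian rate: the conditional normal
#' of a jointly Gaussian (observed, query) trait vector.  This is the
#' deterministic kernel the MCMC integrates over the posterior of
#' `(beta, sigma2)`.
#'
#' @param tree Tree containing the query tip (see [graft_query()]).
#' @param x Named ln-scale predictor including the query.
#' @param y Named ln-scale response on observed tips (query absent/NA).
#' @param beta Length-2 coefficient vector (intercept, slope).
#' @param sigma2 Brownian rate on the unit-depth covariance scale.
#' @param lambda Fixed lambda for the covariance.
#' @param query Query tip label; default the tip lacking `y`.
#' @return List with `mean` and `var` of the query's ln-scale trait.
#' @export
predictive_moments <- function(tree, x, y, beta, sigma2, lambda = 1,
                               query = NULL) {
  if (is.null(query)) query <- find_query(tree, x, y)
  ws <- prediction_workspace(tree, x, y, lambda, query)
  m <- sum(ws$xq * beta) + ws$wy - sum(ws$wX * beta)
  list(mean = as.numeric(m), var = as.numeric(sigma2 * ws$c_cond))
}

find_query <- function(tree, x, y) {
  cand <- setdiff(intersect(tree$tip.label, names(x)[!is.na(x)]),
                  names(y)[!is.na(y)])
  if (length(cand) != 1L)
    stop("cannot infer the query tip (", length(cand),
         " candidates); pass `query` explicitly")
  cand
}

#' Bayesian phylogenetic prediction of a trait at a query tip
#'
#' Gibbs-samples the posterior of the bivariate regression (flat prior on
#' the coefficients, Jeffreys on the rate) under the lambda-transformed
#' phylogenetic covariance restricted to the observed tips, and draws the
#' query's trait from its conditional normal at every retained iteration.
#' Sampling is on the ln scale; summaries (mean, quartiles, credible
#' bounds) are computed on the back-transformed natural-scale draws, with
#' ln-scale draws kept alongside.
#'
#' @param tree Tree containing the query tip (typically from
#'   [graft_query()]).
#' @param x Named ln-scale predictor for all tips including the query.
#' @param y Named ln-scale response; the query must be absent or `NA`.
#' @param config An [mcmc_config()]; its `lambda` is the fixed signal
#'   value for this trait.
#' @param query Query tip label; inferred when unambiguous.
#' @param trait Name of the response used in reports.
#' @return An object of class `"prediction_result"`: natural-scale mean,
#'   lower/upper quartiles, 2.5/97.5 percentiles, 50% credible interval,
#'   effective sample size, and the retained draws on both scales.
#' @export
predict_tip <- function(tree, x, y, config = mcmc_config(), query = NULL,
                        trait = "trait") {
  if (!inherits(config, "mcmc_config")) stop("`config` must be an mcmc_config")
  if (is.null(query)) query <- find_query(tree, x, y)
  ws <- prediction_workspace(tree, x, y, config$lambda, query)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_keep <- config$retained
  warn <- character(0)
  if (n_keep < 50)
    warn <- c(warn, sprintf("only %d retained draws; summaries will be noisy",
                            n_keep))
  draws_ln <- numeric(n_keep)
  beta_draws <- matrix(NA_real_, n_keep, 2L)
  sigma2_draws <- numeric(n_keep)
  sigma2 <- ws$rss_hat / ws$df
  keep_at <- ws_keep_index(config)
  k <- 0L
  sq_c <- sqrt(ws$c_cond)
  for (it in seq_len(config$n_posterior)) {
    beta <- ws$beta_hat + sqrt(sigma2) * drop(crossprod(ws$cholA, rnorm(2L)))
    rss <- ws$yCy - 2 * sum(beta * ws$XCy) +
      sum(beta * drop(ws$XCX %*% beta))
    sigma2 <- 1 / rgamma(1L, shape = ws$n / 2, rate = rss / 2)
    if (keep_at[it]) {
      k <- k + 1L
      mu_q <- sum(ws$xq * beta) + ws$wy - sum(ws$wX * beta)
      draws_ln[k] <- mu_q + sqrt(sigma2) * sq_c * rnorm(1L)
      beta_draws[k, ] <- beta
      sigma2_draws[k] <- sigma2
    }
  }
  draws <- exp(draws_ln)
  qs <- quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(
    query = query, trait = trait, lambda = config$lambda,
    mean = mean(draws), median = qs[3],
    lower_quartile = qs[2], upper_quartile = qs[4],
    q2.5 = qs[1], q97.5 = qs[5],
    ci50 = c(qs[2], qs[4]), ci95 = c(qs[1], qs[5]),
    mean_ln = mean(draws_ln), sd_ln = sd(draws_ln),
    ess = ess(draws_ln), n_draws = n_keep,
    draws = draws, draws_ln = draws_ln,
    beta_draws = beta_draws, sigma2_draws = sigma2_draws,
    n_obs = ws$n, warnings = warn,
    config = config), class = "prediction_result")
}

ws_keep_index <- function(config) {
  idx <- logical(config$n_posterior)
  at <- config$burn_in + config$thin * seq_len(config$retained)
  idx[at[at <= config$n_posterior]] <- TRUE
  idx
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s prediction for %s (lambda = %.3f, %d draws, ESS %.0f)\n",
              x$trait, x$query, x$lambda, x$n_draws, x$ess))
  cat(sprintf("  mean %.4g   quartiles [%.4g, %.4g]   95%% [%.4g, %.4g]\n",
              x$mean, x$lower_quartile, x$upper_quartile, x$q2.5, x$q97.5))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Leave-one-out validation of phylogenetic prediction
#'
#' Withholds the trait of each named specimen in turn, predicts it with
#' [predict_tip()] from the remaining tips, and compares the vector of
#' predicted means against the actual values with Welch's unequal-variance
#' two-sample t-test.
#'
#' @param tree Specimen-level tree (tips = specimen ids).
#' @param table Specimen table with `specimen_id`, `species` and the trait
#'   column (natural units).
#' @param trait Trait column name (e.g. `"mass_kg"`).
#' @param taxa Species names and/or specimen ids selecting the specimens
#'   to validate.
#' @param config An [mcmc_config()].
#' @param predictor Predictor column name.
#' @return List of class `"validation_result"`: a per-specimen data frame
#'   (`predicted`, `actual`, both natural units), the Welch test, and the
#'   two means.
#' @export
iterative_validation <- function(tree, table, trait, taxa,
                                 config = mcmc_config(),
                                 predictor = "hw_cm") {
  ids <- as.character(table$specimen_id)
  pick <- ids %in% taxa | as.character(table$species) %in% taxa
  if (!any(pick)) stop("no specimens match `taxa`")
  bad <- setdiff(taxa, c(ids, as.character(table$species)))
  if (length(bad)) stop("taxa not in table: ", paste(bad, collapse = ", "))
  targets <- ids[pick]
  if (any(is.na(table[[trait]][pick])))
    stop("validation specimens must have an observed ", trait)
  x <- setNames(log(table[[predictor]]), ids)
  y_full <- setNames(log(table[[trait]]), ids)
  seeds <- if (is.null(config$seed)) rep(list(NULL), length(targets))
           else as.list(derive_seeds(config$seed, length(targets)))
  pred <- vapply(seq_along(targets), function(i) {
    y <- y_full
    y[targets[i]] <- NA
    cfg <- config
    cfg$seed <- seeds[[i]]
    predict_tip(tree, x, y, cfg, query = targets[i], trait = trait)$mean
  }, numeric(1))
  actual <- exp(y_full[targets])
  welch <- t.test(pred, actual, var.equal = FALSE)
  structure(list(
    table = data.frame(specimen_id = targets, predicted = pred,
                       actual = as.numeric(actual), row.names = NULL),
    predicted_mean = mean(pred), actual_mean = mean(actual),
    t = unname(welch$statistic), p_value = welch$p.value,
    welch = welch, trait = trait), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Leave-one-out validation of %s (%d specimens)\n",
              x$trait, nrow(x$table)))
  cat(sprintf("  predicted mean %.2f vs actual mean %.2f  (Welch P = %.3g)\n",
              x$predicted_mean, x$actual_mean, x$p_value))
  invisible(x)
}

#' Predict size traits for a suite of fossils
#'
#' Grafts each fossil onto the specimen-level tree at each of its stated
#' placements and predicts each requested trait, optionally under both the
#' raw response data and the captive-mass-corrected (x 0.75) response.
#' Mass is the only trait the correction applies to; snout-vent length is
#' never predicted for fossils.
#'
#' @param tree Specimen-level tree (tips = specimen ids).
#' @param table Specimen table (natural units) with `hw_cm` plus the trait
#'   columns.
#' @param fossils List of fossil specifications: each a list with `name`,
#'   `hw_cm`, and `placements` -- a named list of anchors, each either
#'   `"root"` or a character vector of species names (mapped to their
#'   specimens' MRCA).
#' @param traits Traits to predict, a subset of `c("mass_kg", "tl_cm")`.
#' @param corrections `"raw"`, `"corrected"` or both; corrections other
#'   than `"raw"` multiply each mass by 0.75 before refitting.
#' @param configs Named list of [mcmc_config()] per trait (names matching
#'   `traits`); a single config is recycled.
#' @param eps Grafting branch length.
#' @return Data frame with one row per fossil x placement x trait x
#'   correction: lower quartile, mean, upper quartile, 95% bounds
#'   (natural units), plus the full `"prediction_result"` objects in the
#'   `"results"` attribute.
#' @export
predict_fossil_suite <- function(tree, table, fossils,
                                 traits = c("mass_kg", "tl_cm"),
                                 corrections = c("raw", "corrected"),
                                 configs = mcmc_config(),
                                 eps = 1e-6 * tree_depth(tree)) {
  if ("svl_cm" %in% traits)
    stop("snout-vent length is not predicted for fossils")
  if (inherits(configs, "mcmc_config"))
    configs <- setNames(rep(list(configs), length(traits)), traits)
  ids <- as.character(table$specimen_id)
  rows <- list()
  results <- list()
  for (f in fossils) {
    if (is.null(f$hw_cm) || is.na(f$hw_cm)) stop("fossil ", f$name,
                                                 " is missing hw_cm")
    for (pl in names(f$placements)) {
      anchor <- f$placements[[pl]]
      if (!identical(anchor, "root")) {
        # anchors may be species names or specimen ids; address the MRCA of
        # all matching specimens (a single specimen anchors at its tip)
        anchor_ids <- ids[as.character(table$species) %in% anchor |
                            ids %in% anchor]
        if (!length(anchor_ids))
          stop("no specimens match the anchors for fossil ", f$name)
        anchor <- anchor_ids
      }
      gtree <- graft_query(tree, graft_spec(f$name, anchor), eps = eps)
      x <- c(setNames(log(table$hw_cm), ids), setNames(log(f$hw_cm), f$name))
      for (tr in traits) {
        corrs <- if (tr == "mass_kg") corrections else "raw"
        for (cr in corrs) {
          yv <- table[[tr]]
          if (cr == "corrected") yv <- yv * 0.75
          y <- setNames(log(yv), ids)
          cfg <- configs[[tr]]
          if (!is.null(cfg$seed))  # independent streams per prediction cell
            cfg$seed <- (cfg$seed + 7919L * length(results)) %%
              .Machine$integer.max
          res <- predict_tip(gtree, x, y, cfg, query = f$name,
                             trait = tr)
          key <- paste(f$name, pl, tr, cr, sep = "|")
          results[[key]] <- res
          rows[[key]] <- data.frame(
            fossil = f$name, placement = pl, trait = tr, correction = cr,
            hw_cm = f$hw_cm,
            lower_quartile = res$lower_quartile, mean = res$mean,
            upper_quartile = res$upper_quartile,
            q2.5 = res$q2.5, q97.5 = res$q97.5,
            ess = res$ess, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "results") <- results
  out
}
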