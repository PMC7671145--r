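# Gibbs-sampled phylogenetic prediction: closed-form kernel, collapse onto
# a twin tip, agreement with PGLS, determinism, and validation plumbing.

make_pred_fixture <- function(seed, n = 20, lambda = 1) {
  set.seed(seed)
  tr <- simulate_tree(n)
  C <- phylo_vcv(tr)
  x <- simulate_bm(C, rate = 0.5, root_state = 2.5)
  y <- setNames(-4 + 3 * x +
                  simulate_bm(lambda_transform(C, lambda), rate = 0.06),
                names(x))
  list(tree = tr, x = x, y = y)
}

test_that("fixed-parameter prediction equals dense conditional-normal algebra", {
  fx <- make_pred_fixture(30)
  g <- graft_query(fx$tree, graft_spec("Q", sample(names(fx$x), 2)),
                   eps = 1e-6)
  xq <- c(fx$x, Q = 2.9)
  beta <- c(-4, 3); sigma2 <- 0.06
  for (lam in c(1, 0.85)) {
    got <- predictive_moments(g, xq, fx$y, beta, sigma2, lambda = lam,
                              query = "Q")
    # independent route: joint covariance conditioned with dense solves
    Cg <- ape::vcv.phylo(g)
    Cl <- Cg * lam; diag(Cl) <- diag(Cg)
    obs <- names(fx$y)
    Cl <- Cl[c(obs, "Q"), c(obs, "Q")] / mean(diag(Cl[obs, obs]))
    mu <- beta[1] + beta[2] * xq[c(obs, "Q")]
    ref <- brute_conditional(mu, sigma2 * Cl, fx$y[obs], length(obs) + 1L)
    expect_equal(got$mean, ref$mean, tolerance = 1e-10)
    expect_equal(got$var, ref$var, tolerance = 1e-10)
  }
})

test_that("prediction collapses onto a twin tip as eps shrinks, at lambda 1", {
  fx <- make_pred_fixture(31)
  twin <- names(fx$y)[1]
  g <- graft_query(fx$tree, graft_spec("Q", twin), eps = 1e-9)
  xq <- c(fx$x, Q = unname(fx$x[twin]))
  res <- predict_tip(g, xq, fx$y,
                     mcmc_config(6000, 1000, 5, seed = 1, lambda = 1),
                     query = "Q")
  mcse <- res$sd_ln / sqrt(res$ess)
  expect_lt(abs(res$mean_ln - fx$y[[twin]]), max(2 * mcse, 1e-4))
  expect_lt(res$sd_ln, 1e-3)
})

test_that("posterior coefficient means agree with PGLS point estimates", {
  fx <- make_pred_fixture(32, n = 30, lambda = 0.9)
  C <- phylo_vcv(fx$tree)
  fit <- fit_pgls(fx$x, fx$y, C, lambda = 0.9)
  g <- graft_query(fx$tree, graft_spec("Q", "root"), eps = 1e-6)
  xq <- c(fx$x, Q = 3.5)
  res <- predict_tip(g, xq, fx$y,
                     mcmc_config(22000, 2000, 10, seed = 2, lambda = 0.9),
                     query = "Q")
  for (j in 1:2) {
    draws <- res$beta_draws[, j]
    mcse <- sd(draws) / sqrt(phylosize:::ess(draws))
    expect_lt(abs(mean(draws) - fit$coefficients[j]), 3 * mcse)
  }
  # BLUP: flat-prior posterior mean of the predictive equals the GLS BLUP
  blup <- predictive_moments(g, xq, fx$y, fit$coefficients, fit$sigma2,
                             lambda = 0.9, query = "Q")$mean
  mcse_pred <- res$sd_ln / sqrt(res$ess)
  expect_lt(abs(res$mean_ln - blup), 3 * mcse_pred)
})

test_that("summaries are ordered, positive, and bit-reproducible under a seed", {
  fx <- make_pred_fixture(33)
  g <- graft_query(fx$tree, graft_spec("Q", "root"), eps = 1e-6)
  xq <- c(fx$x, Q = 2)
  cfg <- mcmc_config(4000, 500, 10, seed = 99, lambda = 1)
  r1 <- predict_tip(g, xq, fx$y, cfg, query = "Q")
  r2 <- predict_tip(g, xq, fx$y, cfg, query = "Q")
  expect_identical(r1$draws, r2$draws)
  expect_lt(r1$lower_quartile, r1$upper_quartile)
  expect_gt(r1$lower_quartile, 0)
  expect_true(r1$ci50[1] >= r1$ci95[1] && r1$ci50[2] <= r1$ci95[2])
  r3 <- predict_tip(g, xq, fx$y, mcmc_config(4000, 500, 10, seed = 100,
                                             lambda = 1), query = "Q")
  expect_false(identical(r1$draws, r3$draws))
  # short chains carry an explicit warning in the result
  short <- predict_tip(g, xq, fx$y, mcmc_config(600, 100, 20, seed = 1),
                       query = "Q")
  expect_match(short$warnings, "retained draws", all = FALSE)
})

test_that("root-grafted queries are predicted with more variance than nested ones", {
  # compare at equal tip depth (pendant brings both queries to the present):
  # a full-depth lineage from the root shares no history, so conditioning on
  # the extant data removes none of its Brownian variance
  fx <- make_pred_fixture(34)
  pair <- sample(names(fx$x), 2)
  node_depth <- phylo_vcv(fx$tree)[pair[1], pair[2]]
  g_in <- graft_query(fx$tree,
                      graft_spec("Q", pair, pendant = 1 - node_depth),
                      eps = 1e-6)
  g_root <- graft_query(fx$tree, graft_spec("Q", "root", pendant = 1),
                        eps = 1e-6)
  xq <- c(fx$x, Q = 2.5)
  v_in <- predictive_moments(g_in, xq, fx$y, c(-4, 3), 0.06,
                             lambda = 1, query = "Q")$var
  v_root <- predictive_moments(g_root, xq, fx$y, c(-4, 3), 0.06,
                               lambda = 1, query = "Q")$var
  expect_gt(v_root, v_in)
})

test_that("structureless data predict identically at any placement", {
  fx <- make_pred_fixture(35)
  y_flat <- setNames(rep(2.7, length(fx$y)), names(fx$y))
  xq <- c(fx$x, Q = 2.5)
  g1 <- graft_query(fx$tree, graft_spec("Q", sample(names(fx$x), 2)), 1e-6)
  g2 <- graft_query(fx$tree, graft_spec("Q", "root"), 1e-6)
  m1 <- predictive_moments(g1, xq, y_flat, c(2.7, 0), 0.01, query = "Q")
  m2 <- predictive_moments(g2, xq, y_flat, c(2.7, 0), 0.01, query = "Q")
  expect_equal(m1$mean, m2$mean, tolerance = 1e-9)
  expect_equal(m1$mean, 2.7, tolerance = 1e-9)
})

test_that("guard rails: observed query, ambiguous query, bad config", {
  fx <- make_pred_fixture(36)
  g <- graft_query(fx$tree, graft_spec("Q", "root"), eps = 1e-6)
  xq <- c(fx$x, Q = 2)
  yq <- c(fx$y, Q = 1)
  expect_error(predict_tip(g, xq, yq, mcmc_config(), query = "Q"),
               "already observed")
  expect_error(mcmc_config(n_posterior = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("leave-one-out validation predicts within the data's scale", {
  sim <- simulate_specimens(small_design(40))
  # validate the two largest-HW species, gavial-style
  sp_means <- tapply(sim$table$hw_cm, sim$table$species, mean)
  taxa <- names(sort(sp_means, decreasing = TRUE))[1:2]
  val <- iterative_validation(sim$tree, sim$table, "mass_kg", taxa,
                              mcmc_config(4000, 500, 20, seed = 5,
                                          lambda = 0.9))
  expect_true(all(val$table$predicted > 0))
  expect_equal(nrow(val$table),
               sum(sim$table$species %in% taxa))
  expect_true(val$p_value >= 0 && val$p_value <= 1)
  # predictions land on the right order of magnitude
  expect_lt(abs(log(val$predicted_mean / val$actual_mean)), log(3))
  expect_error(iterative_validation(sim$tree, sim$table, "mass_kg",
                                    c(taxa, "nope"), mcmc_config()),
               "nope")
})
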