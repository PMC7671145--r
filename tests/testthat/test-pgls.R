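# PGLS regression, interval bands, outlier diagnostics and isometry tests.

test_that("PGLS under an identity covariance reproduces OLS exactly", {
  set.seed(20)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    tips <- paste0("t", 1:n)
    C <- diag(n); dimnames(C) <- list(tips, tips)
    x <- setNames(rnorm(n), tips)
    y <- setNames(1 + 2 * x + rnorm(n), tips)
    f <- fit_pgls(x, y, C, lambda = 1)
    ref <- lm(y ~ x)
    s <- summary(ref)
    expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(unname(f$se_coef), unname(s$coefficients[, 2]),
                 tolerance = 1e-8)
    expect_equal(f$SE, s$sigma, tolerance = 1e-8)
    expect_equal(f$r.squared, s$r.squared, tolerance = 1e-8)
    expect_equal(f$fstatistic, unname(s$fstatistic[1]), tolerance = 1e-8)
    expect_equal(f$df, unname(s$df[2]))
  }
})

test_that("perfect collinearity gives slope 1, intercept 0, R2 = 1", {
  tips <- c("A", "B", "C")
  C <- diag(3); dimnames(C) <- list(tips, tips)
  f <- fit_pgls(setNames(1:3, tips), setNames(1:3, tips), C)
  expect_equal(unname(f$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(f$r.squared, 1, tolerance = 1e-12)
})

test_that("3-tip fit solves the GLS normal equations", {
  tr <- tree3()
  C <- phylo_vcv(tr)
  x <- c(A = 0, B = 1, C = 2)
  y <- c(A = 0, B = 1, C = 1)
  f <- fit_pgls(x, y, C, lambda = 1)
  V <- C / mean(diag(C))
  ref <- brute_gls(x, y, V[names(x), names(x)])
  expect_equal(unname(f$coefficients), unname(ref$beta), tolerance = 1e-10)
  expect_equal(f$sigma2, ref$rss / 1, tolerance = 1e-10)
})

test_that("coefficients match an independent GLS implementation", {
  tr <- croc_example_tree()
  set.seed(21)
  C <- phylo_vcv(tr)
  x <- simulate_bm(C, rate = 0.5, root_state = 2.5)
  y <- setNames(-4 + 3 * x + simulate_bm(C, rate = 0.06), names(x))
  f <- fit_pgls(x, y, C, lambda = 1)
  d <- data.frame(x = x[tr$tip.label], y = y[tr$tip.label],
                  tip = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = d,
                   correlation = ape::corBrownian(1, tr, form = ~tip))
  expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-6)
})

test_that("fit is invariant to predictor shifts and tree rescaling", {
  set.seed(22)
  tr <- simulate_tree(20)
  C <- phylo_vcv(tr)
  x <- simulate_bm(C)
  y <- setNames(1 + 0.8 * x + simulate_bm(C, rate = 0.1), names(x))
  f0 <- fit_pgls(x, y, C)
  f_shift <- fit_pgls(x + 10, y, C)
  expect_equal(f_shift$coefficients[["slope"]], f0$coefficients[["slope"]],
               tolerance = 1e-10)
  expect_equal(f_shift$coefficients[["intercept"]],
               f0$coefficients[["intercept"]] -
                 10 * f0$coefficients[["slope"]], tolerance = 1e-8)
  f_scale <- fit_pgls(x, y, 7.3 * C)
  expect_equal(f_scale$coefficients, f0$coefficients, tolerance = 1e-10)
  expect_equal(f_scale$r.squared, f0$r.squared, tolerance = 1e-10)
  expect_equal(f_scale$SE, f0$SE, tolerance = 1e-10)
})

test_that("interval bands match textbook OLS formulas under identity C", {
  set.seed(23)
  n <- 30
  tips <- paste0("t", 1:n)
  C <- diag(n); dimnames(C) <- list(tips, tips)
  x <- setNames(rnorm(n), tips)
  y <- setNames(2 + x + rnorm(n), tips)
  f <- fit_pgls(x, y, C)
  grid <- seq(-2, 2, length.out = 11)
  band <- pgls_intervals(f, grid, level = 0.95)
  ref <- lm(y ~ x)
  ci <- predict(ref, data.frame(x = grid), interval = "confidence")
  pi <- predict(ref, data.frame(x = grid), interval = "prediction")
  expect_equal(band$fit, unname(ci[, "fit"]), tolerance = 1e-10)
  expect_equal(band$ci_lo, unname(ci[, "lwr"]), tolerance = 1e-10)
  expect_equal(band$ci_hi, unname(ci[, "upr"]), tolerance = 1e-10)
  expect_equal(band$pi_lo, unname(pi[, "lwr"]), tolerance = 1e-10)
  expect_equal(band$pi_hi, unname(pi[, "upr"]), tolerance = 1e-10)
})

test_that("bands are nested, contain the line, and widen with level", {
  set.seed(24)
  sim <- simulate_specimens(small_design(31))
  ids <- sim$table$specimen_id
  C <- phylo_vcv(sim$tree)
  f <- fit_pgls(setNames(log(sim$table$hw_cm), ids),
                setNames(log(sim$table$mass_kg), ids), C, lambda = "ml")
  b95 <- pgls_intervals(f, level = 0.95)
  b99 <- pgls_intervals(f, level = 0.99)
  expect_true(all(b95$pi_lo < b95$ci_lo & b95$ci_hi < b95$pi_hi))
  expect_true(all(b95$ci_lo <= b95$fit & b95$fit <= b95$ci_hi))
  expect_true(all(b99$ci_lo < b95$ci_lo & b99$ci_hi > b95$ci_hi))
  expect_true(all(b99$pi_lo < b95$pi_lo & b99$pi_hi > b95$pi_hi))
  expect_error(pgls_intervals(f, level = 1.2), "level")
})

test_that("an injected gross outlier is flagged and clean tips are not", {
  set.seed(25)
  hits <- 0L
  false_flags <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    tr <- simulate_tree(50)
    C <- phylo_vcv(tr)
    x <- simulate_bm(C)
    y <- setNames(0.8 * x + simulate_bm(lambda_transform(C, 0.9),
                                        rate = 0.04), names(x))
    victim <- sample(names(y), 1)
    y[victim] <- y[victim] + 10 * 0.2
    diag_tab <- outlier_diagnostics(fit_pgls(x, y, C, lambda = "ml"))
    if (isTRUE(diag_tab$outlier[diag_tab$tip == victim])) hits <- hits + 1L
    false_flags <- false_flags + sum(diag_tab$outlier &
                                       diag_tab$tip != victim)
  }
  expect_gte(hits / n_rep, 0.95)
  expect_lte(false_flags / n_rep, 0.5)
})

test_that("residual vector of zeros flags nothing", {
  tips <- paste0("t", 1:10)
  C <- diag(10); dimnames(C) <- list(tips, tips)
  x <- setNames(1:10, tips)
  y <- setNames(2 + 3 * (1:10), tips)
  expect_false(any(outlier_diagnostics(fit_pgls(x, y, C))$outlier))
})

test_that("isometry classification follows the slope t-test", {
  fake <- function(b, se, df) structure(
    list(coefficients = c(intercept = 0, slope = b),
         se_coef = c(intercept = 0, slope = se), df = df,
         yname = "y", xname = "x"), class = "pgls_fit")
  exact <- isometry_report(fake(1, 0.05, 54), 1)
  expect_equal(exact$t, 0)
  expect_equal(exact$classification, "isometry")
  neg <- isometry_report(fake(0.802, 0.064 / 1.96, 53), 1)
  expect_equal(neg$classification, "negative allometry")
  iso <- isometry_report(fake(2.953, 0.193 / 1.96, 69), 3)
  expect_equal(iso$classification, "isometry")
  pos <- isometry_report(fake(3.26, 0.05, 69), 3)
  expect_equal(pos$classification, "positive allometry")
})

test_that("degenerate inputs fail loudly", {
  tips <- c("A", "B", "C", "D")
  C <- diag(4); dimnames(C) <- list(tips, tips)
  expect_error(fit_pgls(setNames(rep(1, 4), tips),
                        setNames(rnorm(4), tips), C), "constant")
  f3 <- fit_pgls(c(A = 0, B = 1, C = 2), c(A = 0, B = 1, C = 1),
                 phylo_vcv(tree3()))
  expect_error(outlier_diagnostics(f3), "n <= 3")
})
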