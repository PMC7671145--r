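# End-to-end orchestration: load tree + specimen table (+ fossil specs),
# ln-transform, estimate signal, fit the PGLS allometries with diagnostics
# and bands, optionally validate by leave-one-out prediction, predict
# fossil sizes, and write CSV/JSON reports.  Identical (inputs, config,
# seed) produce identical outputs, MCMC summaries included.

#' Validate and load a specimen table
#'
#' Schema: columns `specimen_id`, `species`, `hw_cm`, `mass_kg`, `svl_cm`,
#' `tl_cm`; empty cells mean missing (tail-damaged individuals lack
#' `tl_cm`).  All violations are collected and reported together before
#' any computation.
#'
#' @param path CSV path, or a data frame to validate in place.
#' @return The validated data frame.
#' @export
read_specimens <- function(path) {
  tab <- if (is.data.frame(path)) path
         else read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "species", "hw_cm", "mass_kg", "svl_cm", "tl_cm")
  probs <- character(0)
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    probs <- c(probs, paste("missing column(s):",
                            paste(missing_cols, collapse = ", ")))
  if (!length(missing_cols)) {
    for (col in c("hw_cm", "mass_kg", "svl_cm", "tl_cm"))
      if (!is.numeric(tab[[col]]))
        probs <- c(probs, paste0("non-numeric values in ", col))
    if (is.numeric(tab$hw_cm) && any(is.na(tab$hw_cm)))
      probs <- c(probs, "missing hw_cm (the predictor must be complete)")
    for (col in c("hw_cm", "mass_kg", "svl_cm", "tl_cm"))
      if (is.numeric(tab[[col]]) && any(tab[[col]] <= 0, na.rm = TRUE))
        probs <- c(probs, paste0("non-positive values in ", col))
    if (anyDuplicated(tab$specimen_id))
      probs <- c(probs, "duplicate specimen_id values")
  }
  if (length(probs))
    stop("specimen table validation failed:\n  - ",
         paste(probs, collapse = "\n  - "))
  tab
}

#' Reduce captive masses to wild-equivalent masses
#'
#' Captive individuals run heavier than wild animals of equal length;
#' multiplying each recorded mass by `factor` (default 0.75, a 25%
#' reduction) gives the conservative wild-equivalent dataset.  The
#' returned table carries a provenance flag and a second application is
#' refused.
#'
#' @param table Specimen data frame with positive `mass_kg`.
#' @param factor Positive multiplier (< 1 for a reduction).
#' @return The corrected table with attribute `mass_corrected = TRUE`.
#' @export
correct_captive_mass <- function(table, factor = 0.75) {
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("`factor` must be a single positive number")
  if (isTRUE(attr(table, "mass_corrected")))
    stop("mass correction already applied to this table (provenance flag)")
  if (any(table$mass_kg <= 0, na.rm = TRUE))
    stop("masses must be positive")
  table$mass_kg <- table$mass_kg * factor
  attr(table, "mass_corrected") <- TRUE
  attr(table, "mass_correction_factor") <- factor
  table
}

#' Read fossil query specifications from YAML
#'
#' Expected layout: a top-level `fossils` list whose entries have `name`,
#' `hw_cm`, and `placements` -- a mapping from placement label to either
#' the string `root` or a list of anchor species names.
#'
#' @param path YAML file path.
#' @return A list in the format [predict_fossil_suite()] accepts.
#' @export
read_fossil_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$fossils)) stop("YAML must contain a `fossils` list")
  lapply(spec$fossils, function(f) {
    if (is.null(f$name) || is.null(f$hw_cm) || is.null(f$placements))
      stop("each fossil needs name, hw_cm and placements")
    f$placements <- lapply(f$placements, function(a)
      if (identical(a, "root")) "root" else as.character(unlist(a)))
    f
  })
}

#' Configuration for a full pipeline run
#'
#' @param tree Newick path or `"phylo"` object (species-level).
#' @param specimens CSV path or data frame.
#' @param fossils YAML path, fossil list, or `NULL` to skip prediction.
#' @param out_dir Output directory (created if needed).
#' @param eps Near-zero branch length for polytomy resolution and
#'   grafting; `NULL` means `1e-6 *` tree depth.
#' @param lambda_mode Lambda handling inside the PGLS fits: `1` (pure
#'   Brownian, default), a fixed numeric value, or `"ml"`.
#' @param pred_lambda Per-trait fixed lambda for prediction, named by
#'   trait column; `NULL` means use each trait's estimated signal.
#' @param mcmc An [mcmc_config()] for fossil prediction.
#' @param mcmc_validation An [mcmc_config()] for leave-one-out validation
#'   (conventionally an abbreviated draw).
#' @param correction `"raw"`, `"corrected"`, or `"both"` mass handling.
#' @param level Interval coverage level.
#' @param validate_taxa Species/specimen names for leave-one-out mass
#'   validation, or `NULL` to skip.
#' @param aliases Named character vector renaming table species to tree
#'   tips (`c(old = "new")`).
#' @param n_perm Permutations for Blomberg's K.
#' @param plots Emit per-fit band plots (PNG)?
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(tree, specimens, fossils = NULL,
                       out_dir = tempfile("phylosize_run_"),
                       eps = NULL, lambda_mode = 1, pred_lambda = NULL,
                       mcmc = mcmc_config(),
                       mcmc_validation = mcmc_config(),
                       correction = c("both", "raw", "corrected"),
                       level = 0.95, validate_taxa = NULL,
                       aliases = NULL, n_perm = 1000L,
                       plots = TRUE, seed = 1L) {
  correction <- match.arg(correction)
  structure(list(tree = tree, specimens = specimens, fossils = fossils,
                 out_dir = out_dir, eps = eps, lambda_mode = lambda_mode,
                 pred_lambda = pred_lambda, mcmc = mcmc,
                 mcmc_validation = mcmc_validation, correction = correction,
                 level = level, validate_taxa = validate_taxa,
                 aliases = aliases, n_perm = as.integer(n_perm),
                 plots = plots, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full allometry-and-prediction analysis
#'
#' Stages: load and validate inputs; expand species tips into specimen
#' polytomies; estimate Pagel's lambda and Blomberg's K per ln variable;
#' fit the PGLS allometries (total length, mass raw/corrected, snout-vent
#' length on head width, plus mass on snout-vent length as a benchmark)
#' with outlier diagnostics, prediction-band coverage and isometry tests;
#' optionally validate mass prediction by leave-one-out on named taxa;
#' optionally predict fossil sizes.  Reports are written as CSV plus a
#' JSON manifest; the returned object carries every intermediate result.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list of class `"phylosize_run"` with elements
#'   `signal`, `fits`, `outliers`, `isometry`, `coverage`, `validation`,
#'   `fossil_predictions`, `manifest`, and the file paths written.
#' @export
run_full <- function(cfg) {
  if (!inherits(cfg, "run_config")) stop("`cfg` must be a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 4L)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message("phylosize: ", msg)
  }

  ## -- load ----------------------------------------------------------------
  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree
          else read_newick(file = cfg$tree)
  tab <- read_specimens(cfg$specimens)
  if (!is.null(cfg$aliases)) {
    hit <- tab$species %in% names(cfg$aliases)
    tab$species[hit] <- unname(cfg$aliases[tab$species[hit]])
  }
  off_tree <- setdiff(unique(tab$species), tree$tip.label)
  if (length(off_tree)) {
    note("dropping species absent from tree: ",
         paste(off_tree, collapse = ", "))
    tab <- tab[!tab$species %in% off_tree, ]
  }
  eps <- if (is.null(cfg$eps)) 1e-6 * tree_depth(tree) else cfg$eps
  xtree <- expand_individuals(tree, tab, eps = eps)
  C <- phylo_vcv(xtree)
  ids <- as.character(tab$specimen_id)
  ln <- list(hw_cm = setNames(log(tab$hw_cm), ids),
             mass_kg = setNames(log(tab$mass_kg), ids),
             svl_cm = setNames(log(tab$svl_cm), ids),
             tl_cm = setNames(log(tab$tl_cm), ids))

  ## -- phylogenetic signal -------------------------------------------------
  signal <- do.call(rbind, lapply(names(ln), function(v) {
    lam <- pagels_lambda(ln[[v]], C)
    K <- blombergs_k(ln[[v]], C, n_perm = cfg$n_perm, seed = seeds[1])
    data.frame(variable = v,
               lambda = lam$value, lambda_p = lam$p_value,
               K = K$value, K_p = K$p_value, n = lam$n_tips)
  }))

  ## -- PGLS ----------------------------------------------------------------
  tab_corr <- correct_captive_mass(tab)
  ln_mass_corr <- setNames(log(tab_corr$mass_kg), ids)
  fits <- list(tl_hw = fit_pgls(ln$hw_cm, ln$tl_cm, C, cfg$lambda_mode,
                                "hw_cm", "tl_cm"))
  if (cfg$correction %in% c("raw", "both"))
    fits$mass_hw_raw <- fit_pgls(ln$hw_cm, ln$mass_kg, C, cfg$lambda_mode,
                                 "hw_cm", "mass_kg")
  if (cfg$correction %in% c("corrected", "both"))
    fits$mass_hw_corrected <- fit_pgls(ln$hw_cm, ln_mass_corr, C,
                                       cfg$lambda_mode, "hw_cm", "mass_kg")
  fits$svl_hw <- fit_pgls(ln$hw_cm, ln$svl_cm, C, cfg$lambda_mode,
                          "hw_cm", "svl_cm")
  fits$mass_svl <- fit_pgls(ln$svl_cm, ln$mass_kg, C, cfg$lambda_mode,
                            "svl_cm", "mass_kg")
  pgls_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(model = nm, SE = f$SE, df = f$df,
               slope = f$coefficients["slope"],
               intercept = f$coefficients["intercept"],
               slope_se = f$se_coef["slope"], p_value = f$p_slope,
               r_squared = f$r.squared, adj_r_squared = f$adj.r.squared,
               f_statistic = f$fstatistic, lambda = f$lambda,
               row.names = NULL)
  }))
  outliers <- do.call(rbind, lapply(names(fits), function(nm)
    cbind(model = nm, outlier_diagnostics(fits[[nm]]))))
  b_iso <- c(tl_hw = 1, mass_hw_raw = 3, mass_hw_corrected = 3,
             svl_hw = 1, mass_svl = 3)
  isometry <- do.call(rbind, lapply(names(fits), function(nm) {
    r <- isometry_report(fits[[nm]], b_iso[[nm]])
    data.frame(model = nm, slope = r$slope, se = r$se, b_iso = r$b_iso,
               t = r$t, p_value = r$p_value,
               classification = r$classification)
  }))
  coverage <- do.call(rbind, lapply(names(fits), function(nm) {
    cov <- pi_coverage(fits[[nm]], level = cfg$level)
    data.frame(model = nm, n = nrow(cov), outside_pi = sum(cov$outside))
  }))

  ## -- leave-one-out validation --------------------------------------------
  validation <- NULL
  if (!is.null(cfg$validate_taxa)) {
    vcfg <- cfg$mcmc_validation
    vcfg$seed <- seeds[2]
    vcfg$lambda <- pred_lambda_for(cfg, signal, "mass_kg")
    validation <- iterative_validation(xtree, tab, "mass_kg",
                                       cfg$validate_taxa, vcfg)
  }

  ## -- fossil prediction ---------------------------------------------------
  fossil_pred <- NULL
  if (!is.null(cfg$fossils)) {
    fossils <- if (is.character(cfg$fossils)) read_fossil_yaml(cfg$fossils)
               else cfg$fossils
    configs <- lapply(c(mass_kg = "mass_kg", tl_cm = "tl_cm"), function(tr) {
      mc <- cfg$mcmc
      mc$seed <- seeds[3]
      mc$lambda <- pred_lambda_for(cfg, signal, tr)
      mc
    })
    corrs <- switch(cfg$correction, raw = "raw", corrected = "corrected",
                    both = c("raw", "corrected"))
    fossil_pred <- predict_fossil_suite(
      xtree, tab, fossils, traits = c("mass_kg", "tl_cm"),
      corrections = corrs, configs = configs, eps = eps)
    low_ess <- fossil_pred$ess < 50
    if (any(low_ess))
      note("low effective sample size for ",
           paste(fossil_pred$fossil[low_ess], fossil_pred$trait[low_ess],
                 sep = ":", collapse = ", "))
    hw_rng <- range(tab$hw_cm)
    extrap <- vapply(fossils, function(f)
      f$hw_cm < hw_rng[1] || f$hw_cm > hw_rng[2], logical(1))
    if (any(extrap))
      note("head width outside the extant range (extrapolation): ",
           paste(vapply(fossils[extrap], `[[`, "", "name"), collapse = ", "))
  }

  ## -- write reports -------------------------------------------------------
  paths <- list(
    signal = write_report(signal, cfg$out_dir, "signal.csv"),
    pgls = write_report(pgls_tab, cfg$out_dir, "pgls.csv"),
    outliers = write_report(outliers, cfg$out_dir, "outliers.csv"),
    isometry = write_report(isometry, cfg$out_dir, "isometry.csv"),
    coverage = write_report(coverage, cfg$out_dir, "pi_coverage.csv"))
  if (!is.null(validation))
    paths$validation <- write_report(
      cbind(validation$table,
            welch_t = validation$t, welch_p = validation$p_value),
      cfg$out_dir, "validation.csv")
  if (!is.null(fossil_pred)) {
    fp <- fossil_pred
    attr(fp, "results") <- NULL
    paths$fossil_predictions <- write_report(fp, cfg$out_dir,
                                             "fossil_predictions.csv")
  }
  if (isTRUE(cfg$plots)) {
    for (nm in names(fits)) {
      grDevices::png(file.path(cfg$out_dir, paste0("fit_", nm, ".png")),
                     width = 900, height = 700)
      plot(fits[[nm]], level = cfg$level, main = nm)
      grDevices::dev.off()
    }
  }
  manifest <- list(
    package = "phylosize",
    version = as.character(packageVersion("phylosize")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed, eps = eps,
    lambda_mode = cfg$lambda_mode, correction = cfg$correction,
    level = cfg$level, n_perm = cfg$n_perm,
    mcmc = unclass(cfg$mcmc)[c("n_posterior", "burn_in", "thin")],
    n_specimens = nrow(tab), n_species = length(unique(tab$species)),
    warnings = warnings_log,
    config_hash = config_hash(cfg))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$manifest <- manifest_path

  invisible(structure(list(signal = signal, fits = fits,
                           pgls_table = pgls_tab, outliers = outliers,
                           isometry = isometry, coverage = coverage,
                           validation = validation,
                           fossil_predictions = fossil_pred,
                           manifest = manifest, paths = paths,
                           table = tab, tree = xtree),
                      class = "phylosize_run"))
}

pred_lambda_for <- function(cfg, signal, trait) {
  if (!is.null(cfg$pred_lambda) && trait %in% names(cfg$pred_lambda))
    return(cfg$pred_lambda[[trait]])
  min(1, signal$lambda[signal$variable == trait])
}

write_report <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

# Stable fingerprint of the analysis-relevant configuration (the output
# location does not affect results and is excluded).
config_hash <- function(cfg) {
  plain <- cfg
  plain$out_dir <- NULL
  plain$tree <- if (inherits(cfg$tree, "phylo")) write_newick(cfg$tree)
                else cfg$tree
  if (is.data.frame(plain$specimens))
    plain$specimens <- nrow(plain$specimens)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, force = TRUE, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.phylosize_run <- function(x, ...) {
  cat("phylosize run:", x$manifest$n_specimens, "specimens,",
      x$manifest$n_species, "species\n")
  cat("PGLS models:\n")
  print(x$pgls_table[, c("model", "slope", "intercept", "SE", "r_squared",
                         "df")], row.names = FALSE)
  if (!is.null(x$validation))
    cat(sprintf("validation: predicted %.2f vs actual %.2f (Welch P=%.3g)\n",
                x$validation$predicted_mean, x$validation$actual_mean,
                x$validation$p_value))
  if (!is.null(x$fossil_predictions))
    cat("fossil predictions:", nrow(x$fossil_predictions), "rows\n")
  cat("outputs in:", dirname(x$paths$manifest), "\n")
  invisible(x)
}
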