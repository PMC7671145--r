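# Seeded generator of trees and specimen tables with the statistical
# structure the allometric analysis assumes, plus ground truth, so every
# stage of the pipeline is testable without external data.
#
# The default configuration emulates the study design the package targets:
# 22 extant species sampled as 76 sexually mature individuals (1-9 per
# species), ln-ln allometries of mass / total length / snout-vent length on
# head width with Brownian-motion residual structure at lambda = 0.9,
# captive masses inflated 25% over wild mass, two longirostrine outlier
# species displaced above the length allometries, and 20 individuals with
# damaged tails (missing total length).

#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the emulated study design; every rate and size is
#' overridable.  Slopes, intercepts and residual standard deviations are
#' per trait on the natural-log scale; the tree has unit depth so residual
#' SDs are per full-depth lineage.
#'
#' @param n_species Number of extant species (tree tips).
#' @param n_individuals Total specimens across species.
#' @param max_per_species Cap on specimens per species.
#' @param slopes,intercepts Named (mass_kg, svl_cm, tl_cm) true ln-ln
#'   coefficients against ln head width.
#' @param resid_sd Named residual standard deviations (ln units per unit
#'   depth).
#' @param lambda_true Phylogenetic signal of the residuals, in \[0, 1\].
#' @param hw_bm_rate Brownian rate of ln head width on the species tree.
#' @param hw_root Root state of ln head width (ln cm).
#' @param ind_noise_frac Within-species variance as a fraction of the
#'   species-level Brownian variance.
#' @param captive_inflation Multiplier applied to wild mass to obtain the
#'   recorded captive mass (>= 1).
#' @param n_outlier_species Number of longirostrine-mimic outlier species.
#' @param outlier_offset ln-unit displacement added to the outliers' total
#'   and snout-vent lengths.
#' @param n_tl_missing Number of individuals with missing total length.
#' @param birth Pure-birth speciation rate for [simulate_tree()].
#' @param seed RNG seed; every dataset is reproducible from (config, seed).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_species = 22L, n_individuals = 76L,
                       max_per_species = 9L,
                       slopes = c(mass_kg = 2.953, svl_cm = 0.768,
                                  tl_cm = 0.80235),
                       intercepts = c(mass_kg = -4.785, svl_cm = 2.525,
                                      tl_cm = 3.05),
                       resid_sd = c(mass_kg = 0.251, svl_cm = 0.097,
                                    tl_cm = 0.073),
                       lambda_true = 0.9,
                       hw_bm_rate = 0.12, hw_root = 2.5,
                       ind_noise_frac = 0.05,
                       captive_inflation = 1.25,
                       n_outlier_species = 2L, outlier_offset = 0.4,
                       n_tl_missing = 20L,
                       birth = 1, seed = 42L) {
  stopifnot(n_species >= 3L, n_individuals >= n_species,
            all(resid_sd > 0), hw_bm_rate > 0, birth > 0,
            lambda_true >= 0, lambda_true <= 1,
            captive_inflation >= 1, ind_noise_frac >= 0)
  traits <- c("mass_kg", "svl_cm", "tl_cm")
  if (!all(traits %in% names(slopes)) || !all(traits %in% names(intercepts))
      || !all(traits %in% names(resid_sd)))
    stop("slopes, intercepts and resid_sd must name mass_kg, svl_cm, tl_cm")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric pure-birth species tree
#'
#' Yule tree conditioned on the number of tips, rescaled to unit depth.
#'
#' @param n_species Number of tips (>= 3).
#' @param birth Speciation rate.
#' @param seed Optional seed; a fixed seed gives a deterministic tree.
#' @return An ultrametric `"phylo"` with tips `sp01, sp02, ...` and depth 1.
#' @export
simulate_tree <- function(n_species = 22L, birth = 1, seed = NULL) {
  if (n_species < 3L) stop("`n_species` must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_species, birth = birth, death = 0)
  tr$edge.length <- tr$edge.length / tree_depth(tr)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Simulate a specimen table with known ground truth
#'
#' Ln head width evolves by Brownian motion on the species tree; each size
#' trait is `intercept + slope * ln HW` plus a Brownian residual on the
#' lambda-transformed tree; individuals add independent noise to both.
#' Captive mass inflation, longirostrine outlier offsets, and missing
#' total lengths are applied after the allometric model, mirroring how the
#' corresponding features arise in real specimen tables.
#'
#' @param tree Species tree (unit depth recommended); default simulated
#'   from the config.
#' @param cfg A [sim_config()].
#' @return List with `table` (specimen data frame: `specimen_id`,
#'   `species`, `hw_cm`, `mass_kg`, `svl_cm`, `tl_cm`), `tree` (the
#'   specimen-level expanded tree), `species_tree`, and `truth` (true
#'   coefficients, species-level ln values and residuals, outlier species,
#'   wild masses).
#' @export
simulate_specimens <- function(cfg = sim_config(),
                               tree = simulate_tree(cfg$n_species, cfg$birth,
                                                    cfg$seed)) {
  set.seed(cfg$seed + 1L)
  n_sp <- ape::Ntip(tree)
  sp <- tree$tip.label
  depth <- tree_depth(tree)
  C <- phylo_vcv(tree)
  Clam <- lambda_transform(C, cfg$lambda_true)

  # individuals per species: everyone gets one, remainder spread at random
  counts <- setNames(rep(1L, n_sp), sp)
  extra <- cfg$n_individuals - n_sp
  while (extra > 0L) {
    open <- names(counts)[counts < cfg$max_per_species]
    pick <- sample(open, min(extra, length(open)), replace = FALSE)
    counts[pick] <- counts[pick] + 1L
    extra <- extra - length(pick)
  }

  hw_sp <- simulate_bm(C, rate = cfg$hw_bm_rate, root_state = cfg$hw_root)
  traits <- c("mass_kg", "svl_cm", "tl_cm")
  e_sp <- sapply(traits, function(tr)
    simulate_bm(Clam, rate = cfg$resid_sd[[tr]]^2))
  outliers <- if (cfg$n_outlier_species > 0L)
    sample(sp, cfg$n_outlier_species) else character(0)

  species <- rep(sp, counts)
  ids <- unlist(lapply(sp, function(s)
    sprintf("%s_%d", s, seq_len(counts[[s]]))), use.names = FALSE)
  n <- length(ids)
  sd_ind_x <- sqrt(cfg$ind_noise_frac * cfg$hw_bm_rate * depth)
  ln_hw <- hw_sp[species] + rnorm(n, 0, sd_ind_x)
  ln_y <- sapply(traits, function(tr) {
    sd_ind <- sqrt(cfg$ind_noise_frac * cfg$resid_sd[[tr]]^2 * depth)
    v <- cfg$intercepts[[tr]] + cfg$slopes[[tr]] * ln_hw +
      e_sp[species, tr] + rnorm(n, 0, sd_ind)
    if (tr != "mass_kg") v[species %in% outliers] <-
        v[species %in% outliers] + cfg$outlier_offset
    v
  })
  wild_mass <- exp(ln_y[, "mass_kg"])
  tab <- data.frame(specimen_id = ids, species = species,
                    hw_cm = exp(ln_hw),
                    mass_kg = wild_mass * cfg$captive_inflation,
                    svl_cm = exp(ln_y[, "svl_cm"]),
                    tl_cm = exp(ln_y[, "tl_cm"]),
                    stringsAsFactors = FALSE)
  if (cfg$n_tl_missing > 0L)
    tab$tl_cm[sample(n, min(cfg$n_tl_missing, n))] <- NA
  list(table = tab,
       tree = expand_individuals(tree, tab),
       species_tree = tree,
       truth = list(cfg = cfg, counts = counts, hw_species = hw_sp,
                    resid_species = e_sp, outlier_species = outliers,
                    wild_mass = setNames(wild_mass, ids)))
}

#' Generate fossil queries with known true trait values
#'
#' Creates query tips whose head widths span below, within and above the
#' extant range, grafted at an MRCA, at a deeper MRCA, and at the root
#' respectively (mirroring conservative fossil placement).  True ln trait
#' values are drawn from the same generative model, conditionally on the
#' simulated species residuals given each fossil's graft position, so
#' prediction calibration can be scored against them.
#'
#' @param sim Output of [simulate_specimens()].
#' @param eps Grafting branch length on the species tree.
#' @param hw_cm Optional length-3 head widths (below/within/above range).
#' @return List of fossil specifications, each with `name`, `hw_cm`,
#'   `placements` (anchor species or `"root"`), and `truth` (named true
#'   natural-unit values for `mass_kg` and `tl_cm`).
#' @export
make_fossil_queries <- function(sim, eps = 1e-6, hw_cm = NULL) {
  cfg <- sim$truth$cfg
  set.seed(cfg$seed + 2L)
  stree <- sim$species_tree
  sp <- stree$tip.label
  hw_rng <- range(log(sim$table$hw_cm))
  if (is.null(hw_cm))
    hw_cm <- exp(c(hw_rng[1] - 0.5, mean(hw_rng), hw_rng[2] + 1.0))
  anchors <- list(small = sample(sp, 2L),
                  mid = sample(sp, max(3L, length(sp) %/% 2L)),
                  large = "root")
  traits <- c("mass_kg", "tl_cm")
  fossils <- vector("list", 3L)
  for (i in 1:3) {
    name <- paste0("fossil_", names(anchors)[i])
    spec <- graft_spec(name, anchors[[i]])
    g <- graft_query(stree, spec, eps = eps)
    Cg <- lambda_transform(phylo_vcv(g), cfg$lambda_true)
    Coo <- Cg[sp, sp]
    U <- chol_or_stop(Coo)
    cqo <- Cg[name, sp]
    w <- drop(backsolve(U, whiten(U, cqo)))
    c_cond <- Cg[name, name] - sum(w * cqo)
    truth <- sapply(traits, function(tr) {
      e_obs <- sim$truth$resid_species[sp, tr]
      e_q <- sum(w * e_obs) +
        rnorm(1, 0, cfg$resid_sd[[tr]] * sqrt(max(c_cond, 0)))
      exp(cfg$intercepts[[tr]] + cfg$slopes[[tr]] * log(hw_cm[i]) + e_q)
    })
    fossils[[i]] <- list(name = name, hw_cm = hw_cm[i],
                         placements = setNames(list(anchors[[i]]), "main"),
                         truth = truth)
  }
  names(fossils) <- vapply(fossils, `[[`, "", "name")
  fossils
}

#' Hand-built crocodylian-style example tree
#'
#' A synthetic 22-species ultrametric tree (unit depth) whose clade
#' structure mimics the extant crocodylian radiation -- an alligatoroid
#' clade, a crocodylid clade and a two-species gavialid clade -- for
#' integration tests and examples.  Branch lengths are invented; the tree
#' is not an inference from data.
#'
#' @return A `"phylo"` object with 22 binomial-style tip labels.
#' @export
croc_example_tree <- function() {
  f <- system.file("extdata", "crocodylia_synthetic.nwk",
                   package = "phylosize", mustWork = TRUE)
  read_newick(file = f)
}
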