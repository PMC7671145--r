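# Independent oracles used across the suite.  Each deliberately takes a
# different computational route than the package code it checks.

# Shared-path covariance via patristic distances: cov(i, j) =
# (depth_i + depth_j - d_ij) / 2, with d from ape::cophenetic.phylo.
brute_vcv <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(depth) <- tree$tip.label
  tips <- tree$tip.label
  C <- (outer(depth[tips], depth[tips], "+") - d[tips, tips]) / 2
  diag(C) <- depth[tips]
  C
}

# GLS solved literally from the normal equations with dense inverses.
brute_gls <- function(x, y, V) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  list(beta = drop(beta),
       rss = drop(t(r) %*% Vi %*% r),
       cov_unscaled = solve(t(X) %*% Vi %*% X))
}

# Conditional normal of component q of a joint Gaussian, by direct dense
# partitioned-matrix conditioning.
brute_conditional <- function(mu, Sigma, y_obs, q) {
  o <- setdiff(seq_along(mu), q)
  So <- Sigma[o, o]
  w <- Sigma[q, o] %*% solve(So)
  list(mean = drop(mu[q] + w %*% (y_obs - mu[o])),
       var = drop(Sigma[q, q] - w %*% Sigma[o, q]))
}

# Specimen ids belonging to a set of species.
specimens_of <- function(table, species)
  as.character(table$specimen_id[table$species %in% species])

# Small ultrametric fixture trees.
tree3 <- function() read_newick("((A:1,B:1):1,C:2);")
tree5 <- function() read_newick("(((A:1,B:1):1,(C:1.5,D:1.5):0.5):1,E:3);")

# A compact synthetic study design: fewer replicates-heavy knobs but the
# same structure (species tree, individuals, allometry, signal).
small_design <- function(seed, n_species = 10L, n_individuals = 30L) {
  sim_config(n_species = n_species, n_individuals = n_individuals,
             n_tl_missing = 6L, seed = seed)
}
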