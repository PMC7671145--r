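# Tree I/O and surgery: the phylogeny handling the allometric analysis
# depends on.  Trees are ape "phylo" objects throughout; every function here
# validates the properties downstream code assumes (rooted, branch lengths
# present and non-negative, unique tip labels).

#' Read a rooted Newick tree with mandatory branch lengths
#'
#' Thin, strict wrapper around [ape::read.tree()].  Unlike the underlying
#' parser, this function refuses trees with missing or negative branch
#' lengths and trees that are not rooted: the downstream Brownian-motion
#' variance-covariance construction is meaningless without complete,
#' non-negative edge lengths and a root.
#'
#' @param text Newick string (exactly one tree).  Mutually exclusive with
#'   `file`.
#' @param file Path to a Newick file containing one tree.
#' @return An object of class `"phylo"`.  Polytomies are legal input.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (is.null(text)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  if (!nzchar(gsub("\\s", "", text))) stop("empty Newick input")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop("malformed Newick near position ",
         newick_error_position(text), ": could not parse input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_tree(tr)
  tr
}

# Best-effort location of the first syntactically suspicious character, so
# parse errors point somewhere useful.
newick_error_position <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  1L
}

validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length))
    stop("tree has no branch lengths; every edge must carry one")
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length)))
    stop("missing branch length on ",
         sum(!is.finite(tr$edge.length)),
         " edge(s); branch lengths are required on all edges")
  if (any(tr$edge.length < 0))
    stop("negative branch length(s) are not allowed")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  # Newick nesting defines the root; polytomies (including basal ones, as in
  # star trees) are legal input.
  invisible(tr)
}

#' Write a tree as a Newick string
#'
#' @param tree A `"phylo"` object.
#' @param file Optional path; when given the string is also written to disk.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_tree(tree)
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Root-to-tip depth of a tree
#'
#' Maximum root-to-tip path length; for an ultrametric tree this is the
#' common depth of every tip.
#'
#' @param tree A `"phylo"` object.
#' @return A single non-negative number in the tree's time units.
#' @export
tree_depth <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Brownian-motion variance-covariance matrix from path sums
#'
#' Entry (i, j) is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.  Under Brownian motion the trait
#' covariance between two tips is proportional to this shared path.
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @examples
#' phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)  # all nodes, root = 0
  if (n == 1L) {
    C <- matrix(depth[1L], 1L, 1L,
                dimnames = list(tree$tip.label, tree$tip.label))
    return(C)
  }
  m <- ape::mrca(tree)                       # pairwise MRCA node numbers
  C <- matrix(depth[m], n, n)
  diag(C) <- depth[seq_len(n)]
  dimnames(C) <- list(tree$tip.label, tree$tip.label)
  C
}

#' Largest valid Pagel's lambda for a covariance matrix
#'
#' The lambda transformation multiplies off-diagonal covariances; on an
#' ultrametric tree any lambda in \[0, 1\] is valid, and slightly larger
#' values remain valid until some off-diagonal entry would exceed the
#' smaller of the two corresponding diagonal entries.
#'
#' @param C A phylogenetic covariance matrix.
#' @return Upper bound for lambda (at least 1 on strictly ultrametric
#'   trees without zero-length terminal branches).
#' @export
lambda_max <- function(C) {
  n <- nrow(C)
  if (n < 2L) return(1)
  d <- diag(C)
  bound <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cij <- C[i, j]
    if (cij > 0) bound <- min(bound, min(d[i], d[j]) / cij)
  }
  if (!is.finite(bound)) 1 else bound
}

#' Pagel's lambda branch-length transformation of a covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) covariances by `lambda`
#' while leaving tip variances unchanged: `lambda = 1` is pure Brownian
#' motion, `lambda = 0` erases the phylogeny.
#'
#' @param C A phylogenetic covariance matrix.
#' @param lambda Multiplier, usually in \[0, 1\].  Values above 1 are
#'   accepted up to the ultrametric bound of [lambda_max()] (with a
#'   warning beyond 1); negative values are an error.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda))
    stop("`lambda` must be a single finite number")
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (lambda > 1) {
    lmax <- lambda_max(C)
    if (lambda > lmax + 1e-12)
      stop("lambda = ", lambda, " exceeds the ultrametric bound ",
           signif(lmax, 6))
    warning("lambda > 1; valid here but at the edge of the ultrametric bound")
  }
  out <- C * lambda
  diag(out) <- diag(C)
  out
}

#' Expand species tips into per-individual polytomies
#'
#' Replaces each species tip by the specimens measured for that species,
#' joined as a hard polytomy arbitrarily resolved into a caterpillar of
#' near-zero (`eps`) internal branches.  This carries within-species
#' sampling into a tip-level analysis while keeping the added branch
#' lengths far too short to represent real divergence.  Root-to-tip depths
#' are preserved exactly: the caterpillar's height is absorbed into the
#' species' stem branch, so conspecific tip covariances equal the species
#' depth minus at most `(k - 1) * eps`.
#'
#' @param tree Species-level rooted tree with branch lengths.
#' @param table Data frame with at least `specimen_id` and `species`
#'   columns; every species must match a tip label.  Caterpillar order
#'   follows table order, so runs are reproducible.
#' @param eps Near-zero branch length for the resolved polytomies.
#'   Default `1e-6 *` tree depth.
#' @return A fully bifurcating `"phylo"` object whose tips are specimen
#'   ids.  Species with a single specimen keep their tip, relabeled.
#' @export
expand_individuals <- function(tree, table,
                               eps = 1e-6 * tree_depth(tree)) {
  validate_tree(tree)
  if (!all(c("specimen_id", "species") %in% names(table)))
    stop("`table` needs `specimen_id` and `species` columns")
  if (anyDuplicated(table$specimen_id))
    stop("duplicate specimen ids: ",
         paste(unique(table$specimen_id[duplicated(table$specimen_id)]),
               collapse = ", "))
  unmatched <- setdiff(unique(table$species), tree$tip.label)
  if (length(unmatched))
    stop("species absent from tree: ", paste(unmatched, collapse = ", "))
  if (!is.numeric(eps) || eps <= 0) stop("`eps` must be > 0")

  out <- tree
  for (sp in unique(table$species)) {
    ids <- as.character(table$specimen_id[table$species == sp])
    k <- length(ids)
    tip_idx <- which(out$tip.label == sp)
    if (k == 1L) {
      out$tip.label[tip_idx] <- ids
      next
    }
    height <- (k - 1L) * eps
    pend <- out$edge.length[out$edge[, 2] == tip_idx]
    if (pend <= height)
      stop("eps too large: caterpillar height ", height,
           " exceeds the terminal branch of ", sp, " (", pend, ")")
    sub <- caterpillar_tree(ids, eps)
    sub$root.edge <- 0
    out$edge.length[out$edge[, 2] == tip_idx] <- pend - height
    out <- ape::bind.tree(out, sub, where = which(out$tip.label == sp),
                          position = 0)
  }
  validate_tree(out)
  out
}

# Ultrametric caterpillar of k >= 2 tips with internal branches eps and
# total height (k - 1) * eps; tip order follows `ids`.
caterpillar_tree <- function(ids, eps) {
  k <- length(ids)
  s <- sprintf("(%s:%.17g,%s:%.17g)", ids[1], eps, ids[2], eps)
  if (k > 2L)
    for (j in 3:k)
      s <- sprintf("(%s:%.17g,%s:%.17g)", s, eps, ids[j], (j - 1) * eps)
  ape::read.tree(text = paste0(s, ";"))
}

#' Specify where a query tip should be grafted
#'
#' Graft addresses are phylogenetic, not positional: a query attaches at a
#' named tip, at the most recent common ancestor of two or more named tips,
#' or at the root, so a specification survives re-reading the tree.
#'
#' @param name Label for the new query tip.
#' @param anchor Character vector: `"root"`, a single tip label, or two or
#'   more tip labels whose MRCA is the attachment node.
#' @param pendant Length of the query's terminal branch; `NULL` means use
#'   the grafting `eps`.
#' @return An object of class `"graft_spec"`.
#' @export
graft_spec <- function(name, anchor, pendant = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (!is.character(anchor) || !length(anchor))
    stop("`anchor` must be a character vector")
  if (!is.null(pendant) && (!is.numeric(pendant) || pendant < 0))
    stop("`pendant` must be >= 0")
  structure(list(name = name, anchor = anchor, pendant = pendant),
            class = "graft_spec")
}

#' @export
print.graft_spec <- function(x, ...) {
  cat("graft_spec:", x$name, "->",
      if (identical(x$anchor, "root")) "root"
      else paste0("MRCA(", paste(x$anchor, collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Graft a query tip onto a tree with a near-zero stem
#'
#' Attaches a new tip at the node addressed by a [graft_spec()]: an
#' `eps`-length stem splits the branch immediately above the attachment
#' node, so all original pairwise tip covariances are preserved to within
#' `eps` and the query's covariance with every descendant of the node
#' equals the node's depth (to within `eps`).  Grafting at `"root"` adds
#' the query as a child of the root, sharing no history with any other
#' tip.
#'
#' @param tree Rooted `"phylo"` object.
#' @param spec A [graft_spec()].
#' @param eps Stem length (default `1e-6 *` tree depth); the pendant
#'   branch defaults to `eps` too unless the spec overrides it.
#' @return The grafted `"phylo"` object.
#' @export
graft_query <- function(tree, spec, eps = 1e-6 * tree_depth(tree)) {
  validate_tree(tree)
  if (!inherits(spec, "graft_spec")) stop("`spec` must be a graft_spec")
  if (spec$name %in% tree$tip.label)
    stop("tip name collision: ", spec$name, " is already in the tree")
  pendant <- if (is.null(spec$pendant)) eps else spec$pendant
  root_node <- ape::Ntip(tree) + 1L

  if (identical(spec$anchor, "root")) {
    # new binary root: the query becomes sister to the entire original tree,
    # whose old root hangs on an eps stem (original covariances shift <= eps)
    n <- ape::Ntip(tree)
    remap <- function(v) ifelse(v > n, v + 2L, v)
    edge <- cbind(remap(tree$edge[, 1]), remap(tree$edge[, 2]))
    edge <- rbind(c(n + 2L, n + 3L), edge, c(n + 2L, n + 1L))
    out <- structure(list(edge = edge,
                          edge.length = c(eps, tree$edge.length, pendant),
                          tip.label = c(tree$tip.label, spec$name),
                          Nnode = tree$Nnode + 1L), class = "phylo")
    return(ape::reorder.phylo(out, "cladewise"))
  }
  missing_anchor <- setdiff(spec$anchor, tree$tip.label)
  if (length(missing_anchor))
    stop("anchor tip(s) not in tree: ", paste(missing_anchor, collapse = ", "))
  if (length(spec$anchor) == 1L) {
    node <- which(tree$tip.label == spec$anchor)
  } else {
    node <- ape::getMRCA(tree, spec$anchor)
    if (is.null(node)) stop("could not resolve MRCA of anchors")
  }
  if (node == root_node)
    return(graft_query(tree, graft_spec(spec$name, "root", spec$pendant), eps))
  stem_edge <- tree$edge.length[tree$edge[, 2] == node]
  pos <- min(eps, stem_edge / 2)  # stay on the branch above the node
  phytools::bind.tip(tree, spec$name, edge.length = pendant,
                     where = node, position = pos)
}

#' Remove a query tip
#'
#' Inverse of [graft_query()]: dropping the query restores the original
#' pairwise covariances to within the grafting `eps`.
#'
#' @param tree A `"phylo"` object.
#' @param name Tip label to remove.
#' @return The pruned `"phylo"` object.
#' @export
drop_query <- function(tree, name) {
  if (!name %in% tree$tip.label) stop("no tip named ", name)
  ape::drop.tip(tree, name)
}
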