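#' Parse a Newick string into a validated ultrametric phylogeny
#'
#' Wraps [ape::read.tree()] and then enforces the invariants every likelihood
#' in this package assumes: the tree is rooted, strictly bifurcating, has
#' branch lengths on every edge, unique non-empty tip labels, and is
#' ultrametric within a relative tolerance of `tol` times the crown age.
#' Tip ages are then snapped exactly to 0 (the present) so that downstream
#' branching-time arithmetic is exact; the snap absorbs Newick decimal
#' truncation.
#'
#' Ages throughout the package are in Ma before present (t = 0 is the
#' present). Polytomies are rejected rather than resolved, because the
#' likelihoods assume binary trees; outgroup removal is the caller's job via
#' [extract_clade()].
#'
#' @param text A Newick string (single tree, trailing semicolon).
#' @param tol Relative ultrametricity tolerance (default 1e-6 of crown age).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text, tol = 1e-6) {
  stopifnot(is.character(text), length(text) == 1)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))),
    warning = function(w) abort(paste0("Newick parse error: ", conditionMessage(w)))
  )
  if (is.null(tree)) abort("Newick parse error: input did not contain a tree.")
  validate_phylo(tree, tol = tol)
}

#' Validate (and tip-snap) a phylogeny
#'
#' @param tree A `phylo` object.
#' @param tol Relative ultrametricity tolerance.
#' @return The validated tree with root-to-tip depths equalized exactly.
#' @export
validate_phylo <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) abort("Expected an object of class 'phylo'.")
  if (is.null(tree$edge.length)) abort("Tree has no branch lengths; they are required.")
  if (anyNA(tree$edge.length)) abort("Tree has missing branch lengths.")
  if (any(tree$edge.length < 0)) abort("Tree has negative branch lengths.")
  n <- length(tree$tip.label)
  if (n < 2) abort("Tree must have at least 2 tips.")
  if (any(tree$tip.label == "") || anyNA(tree$tip.label)) {
    abort("Tip labels must be non-empty.")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("Duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  # strictly bifurcating: a rooted binary tree has n - 1 internal nodes
  tab <- tabulate(tree$edge[, 1])
  if (tree$Nnode != n - 1 || any(tab[tab > 0] != 2)) {
    abort("Tree is non-binary (contains polytomies or unbranched nodes).")
  }
  depth <- node_depths(tree)
  tipd <- depth[seq_len(n)]
  crown <- max(tipd)
  if (crown <= 0) abort("Tree has zero depth.")
  off <- abs(tipd - crown)
  if (any(off > tol * crown)) {
    worst <- tree$tip.label[which.max(off)]
    abort(paste0(
      "Tree is not ultrametric within tolerance: tip '", worst,
      "' deviates by ", format(max(off)), " (crown age ", format(crown), ")."
    ))
  }
  # snap tip ages exactly to 0 by stretching terminal branches
  term <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (crown - tipd)
  tree
}

# root-to-node path lengths, preorder
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  depth <- numeric(n + nnode)
  root <- n + 1L
  # edges in preorder: ape's cladewise order guarantees parents before children
  e <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(e$edge))) {
    depth[e$edge[i, 2]] <- depth[e$edge[i, 1]] + e$edge.length[i]
  }
  depth
}

#' Node ages (Ma before present) for an ultrametric tree
#'
#' @param tree A validated ultrametric `phylo`.
#' @return Numeric vector of ages indexed by node id (tips first, then
#'   internal nodes); tips have age 0.
#' @export
node_ages <- function(tree) {
  depth <- node_depths(tree)
  crown <- max(depth[seq_len(length(tree$tip.label))])
  pmax(crown - depth, 0)
}

#' Branching times of an ultrametric phylogeny
#'
#' Ages of the internal nodes, sorted descending so the crown age comes
#' first. These are the sufficient statistics for every trait-free
#' birth-death likelihood in the package.
#'
#' @param tree A validated ultrametric `phylo`.
#' @return Numeric vector of length `n_tips - 1`, strictly positive,
#'   descending.
#' @export
branching_times <- function(tree) {
  tree <- validate_phylo(tree)
  bt <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  if (any(bt <= 0)) abort("Branching times must be strictly positive.")
  bt
}

#' Extract the clade spanned by a set of tips
#'
#' Returns the subtree rooted at the most recent common ancestor of
#' `tip_subset`, which must be monophyletic in `tree`; branch lengths are
#' preserved, so the subtree's crown age is the MRCA age.
#'
#' @param tree A validated `phylo`.
#' @param tip_subset Character vector of tip labels (non-empty subset of the
#'   tree's tips).
#' @return A `phylo` with `length(tip_subset)` tips.
#' @export
extract_clade <- function(tree, tip_subset) {
  tree <- validate_phylo(tree)
  tip_subset <- unique(as.character(tip_subset))
  if (length(tip_subset) == 0) abort("tip_subset must be non-empty.")
  missing <- setdiff(tip_subset, tree$tip.label)
  if (length(missing)) {
    abort(paste0("Tips not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(tip_subset) == length(tree$tip.label)) return(tree)
  if (length(tip_subset) == 1) abort("tip_subset must contain at least 2 tips.")
  mrca <- ape::getMRCA(tree, tip_subset)
  desc <- tips_below(tree, mrca)
  intruders <- setdiff(desc, tip_subset)
  if (length(intruders)) {
    abort(paste0(
      "tip_subset is not monophyletic; intruding tips: ",
      paste(intruders, collapse = ", ")
    ))
  }
  sub <- ape::extract.clade(tree, mrca)
  validate_phylo(sub)
}

# labels of tips descending from an internal node
tips_below <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  e <- ape::reorder.phylo(tree, "cladewise")$edge
  keep <- logical(n + tree$Nnode)
  keep[node] <- TRUE
  for (i in seq_len(nrow(e))) {
    if (keep[e[i, 1]]) keep[e[i, 2]] <- TRUE
  }
  tree$tip.label[keep[seq_len(n)]]
}

#' Lineage-through-time series
#'
#' One point per branching age plus the present; the lineage count starts at
#' 2 at the crown age and steps +1 at each subsequent branching, ending at
#' the number of tips.
#'
#' @param tree A validated ultrametric `phylo`.
#' @return A tibble with columns `age` (Ma, descending) and `n_lineages`.
#' @export
ltt_points <- function(tree) {
  bt <- branching_times(tree)
  n <- length(bt) + 1
  tibble(
    age = c(bt, 0),
    n_lineages = c(seq(2, n), n)
  )
}

#' Write a phylogeny to a Newick string
#'
#' Branch lengths are emitted with 9 significant digits so that
#' `parse_newick(write_newick(tree))` round-trips topology and branch lengths
#' to 1e-9.
#'
#' @param tree A `phylo`.
#' @return A single Newick string with trailing semicolon.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 9)
}
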