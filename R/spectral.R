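## Spectral clade detection: the graph Laplacian of the phylogeny (all
## vertices, edges weighted by inverse branch length), its spectral
## density, the eigengap cluster count, k-means cluster assignment on the
## Laplacian eigenvectors, and cross-tree partition consistency.

#' Spectral profile of a phylogeny's graph Laplacian
#'
#' Builds `L = D - W` on the tree graph (all `2n - 1` vertices) with
#' `W[u, v] = 1 / branch length` for adjacent vertices, and returns its
#' spectrum together with a Gaussian kernel density of the log
#' eigenvalues, the eigengaps and the suggested cluster count. `k` weakly
#' connected blocks leave `k` near-zero eigenvalues separated from the
#' rest by orders of magnitude, so the eigengap is measured
#' multiplicatively: `k*` maximizes the ratio of successive ascending
#' eigenvalues among the leading `max_k` positions (the additive gap is
#' dominated by the arbitrary spread of the high spectrum on trees).
#'
#' @param tree A validated `phylo`.
#' @param max_k Largest cluster count considered.
#' @param min_bl Branch-length floor before inversion (guards zero-length
#'   edges).
#' @return A `spectral_profile`: list with `eigenvalues` (descending),
#'   `eigengaps` (the successive-eigenvalue ratios, positions 2..max_k),
#'   `k_star`, `density` (tibble), the eigenvector matrix and bookkeeping
#'   fields.
#' @export
laplacian_spectrum <- function(tree, max_k = 10, min_bl = 1e-8) {
  tree <- validate_phylo(tree)
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  W <- matrix(0, nn, nn)
  bl <- pmax(tree$edge.length, min_bl)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]
    v <- tree$edge[i, 2]
    W[u, v] <- W[v, u] <- 1 / bl[i]
  }
  deg <- rowSums(W)
  L <- diag(deg) - W
  e <- eigen(L, symmetric = TRUE)
  vals_desc <- pmax(e$values, 0)
  vals_asc <- rev(vals_desc)
  vecs_asc <- e$vectors[, rev(seq_len(nn)), drop = FALSE]
  k_star <- eigengap_from_spectrum(vals_asc, max_k, n)
  gaps <- eigengap_ratios(vals_asc, max_k, n)
  lv <- vals_desc[vals_desc > 1e-12]
  dens <- density(log(lv), kernel = "gaussian")
  structure(
    list(
      eigenvalues = vals_desc,
      eigengaps = gaps,
      k_star = as.integer(k_star),
      density = tibble(log_eigenvalue = dens$x, density = dens$y),
      vectors_asc = vecs_asc,
      n_tips = n,
      construction = "L = D - W, W = 1/branch length on tree edges",
      tree = tree
    ),
    class = "spectral_profile"
  )
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat("<spectral_profile> ", x$n_tips, " tips, k* = ", x$k_star,
    " (leading eigengaps: ", paste(signif(x$eigengaps[1:min(4, length(x$eigengaps))], 3),
      collapse = ", "
    ), ")\n",
    sep = ""
  )
  invisible(x)
}

# multiplicative eigengaps r_i = lambda_{i+1} / lambda_i for i = 2..max_k
# (the first ratio is indeterminate: lambda_1 = 0 on any connected graph)
eigengap_ratios <- function(vals_asc, max_k, n_tips) {
  kk <- max(min(max_k, n_tips - 1, length(vals_asc) - 1), 2)
  d <- 1e-12 * max(vals_asc)
  (vals_asc[3:(kk + 1)] + d) / (vals_asc[2:kk] + d)
}

eigengap_from_spectrum <- function(vals_asc, max_k, n_tips) {
  if (n_tips <= 2) {
    return(1L)
  }
  r <- eigengap_ratios(vals_asc, max_k, n_tips)
  as.integer(which.max(r) + 1)
}

#' Eigengap cluster count
#'
#' The position of the largest multiplicative gap in the ascending
#' spectrum among the leading `max_k` eigenvalues; on trees with weakly
#' connected clades this count equals the number of near-zero
#' eigenvalues. On homogeneous trees the signal is weak and the returned
#' value is a contract, not a finding.
#'
#' @param profile A `spectral_profile` from [laplacian_spectrum()].
#' @param max_k Largest cluster count considered.
#' @return Integer `k*` in `[1, n_tips - 1]`.
#' @export
eigengap_cluster_count <- function(profile, max_k = 10) {
  stopifnot(inherits(profile, "spectral_profile"))
  eigengap_from_spectrum(
    rev(profile$eigenvalues), max_k, profile$n_tips
  )
}

#' Assign tips to k spectral clusters
#'
#' k-means (deterministically seeded, 25 restarts) on the leading `k`
#' Laplacian eigenvectors, restricted to the tip vertices. Cluster ids are
#' canonicalized by decreasing size, ties broken by the smallest tip index.
#'
#' @param tree A validated `phylo` (or a `spectral_profile`).
#' @param k Number of clusters (1 to `n_tips`).
#' @param seed Seed for the k-means restarts.
#' @return A tibble with columns `taxon` and `cluster`.
#' @export
cluster_assignment <- function(tree, k, seed = 1) {
  profile <- if (inherits(tree, "spectral_profile")) tree else laplacian_spectrum(tree)
  tr <- profile$tree
  n <- profile$n_tips
  if (k < 1 || k > n) abort("k must be in [1, n_tips].")
  if (k == 1) {
    return(tibble(taxon = tr$tip.label, cluster = 1L))
  }
  if (k == n) {
    return(tibble(taxon = tr$tip.label, cluster = seq_len(n)))
  }
  X <- profile$vectors_asc[seq_len(n), seq_len(k), drop = FALSE]
  set.seed(seed)
  km <- kmeans(X, centers = k, nstart = 25, iter.max = 100)
  cl <- km$cluster
  # canonical ids: by decreasing size, then first occurrence
  sizes <- table(cl)
  ord <- order(-as.vector(sizes), vapply(names(sizes), function(g) {
    min(which(cl == as.integer(g)))
  }, 0))
  relabel <- integer(k)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(k)
  tibble(taxon = tr$tip.label, cluster = relabel[cl])
}

#' Consistency of spectral partitions across trees
#'
#' Applies [laplacian_spectrum()] + [cluster_assignment()] with `k`
#' clusters to every tree and reports the share of applications returning
#' the modal partition (as an unordered set of tip sets on the common
#' taxa), plus a bootstrap-free spread estimate.
#'
#' @param trees A list of `phylo` objects (e.g. posterior trees).
#' @param k Number of clusters.
#' @param seed Seed passed to the assignments.
#' @return A list with `share_modal` (fraction in `[0, 1]`),
#'   `percent_modal`, `modal_partition` (list of tip sets) and
#'   `assignments` (list of tibbles).
#' @export
cluster_consistency <- function(trees, k, seed = 1) {
  if (length(trees) == 0) abort("cluster_consistency(): empty tree collection.")
  assignments <- lapply(seq_along(trees), function(i) {
    cluster_assignment(trees[[i]], k, seed = seed + i)
  })
  keys <- vapply(assignments, function(a) {
    groups <- split(a$taxon, a$cluster)
    groups <- lapply(groups, sort)
    groups <- groups[order(vapply(groups, `[`, "", 1))]
    paste(vapply(groups, paste, "", collapse = ","), collapse = "|")
  }, "")
  tab <- sort(table(keys), decreasing = TRUE)
  share <- as.vector(tab[1]) / length(keys)
  modal_key <- names(tab)[1]
  modal <- strsplit(strsplit(modal_key, "\\|")[[1]], ",")
  list(
    share_modal = share,
    percent_modal = 100 * share,
    modal_partition = modal,
    assignments = assignments
  )
}
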