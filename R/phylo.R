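#' Read and validate an ultrametric species tree
#'
#' Parses a newick string or file into an `ape` phylo object and checks
#' the requirements of the phylogenetic mixed model: unique non-empty tip
#' labels, branch lengths present, and ultrametricity within a relative
#' tolerance of the tree depth (the Brownian correlation construction
#' assumes a time tree).
#'
#' @param text newick string, or a file path when `file = TRUE`.
#' @param file treat `text` as a path.
#' @param tol relative ultrametricity tolerance (fraction of tree depth),
#'   default 1e-3.
#' @return An `ape::phylo` object.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
read_newick <- function(text, file = FALSE, tol = 1e-3) {
  tr <- if (file) ape::read.tree(text) else ape::read.tree(text = text)
  if (is.null(tr)) st_stop("newick_parse", "could not parse newick input")
  validate_phylogeny(tr, tol = tol)
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object to validate in place.
#' @export
validate_phylogeny <- function(tree, tol = 1e-3) {
  if (!inherits(tree, "phylo")) st_stop("newick_parse", "not a phylo object")
  if (is.null(tree$edge.length))
    st_stop("newick_branch", "tree has no branch lengths")
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyDuplicated(labs))
    st_stop("newick_tips", "tip labels must be unique and non-empty")
  depths <- node_depths(tree)[seq_along(labs)]
  depth <- max(depths)
  if (depth <= 0) st_stop("newick_branch", "tree depth must be positive")
  if (diff(range(depths)) > tol * depth) {
    worst <- order(depths)[c(1L, length(depths))]
    st_stop("newick_ultrametric",
            sprintf("tree is not ultrametric: tips %s (%.4g) vs %s (%.4g)",
                    labs[worst[1]], depths[worst[1]],
                    labs[worst[2]], depths[worst[2]]))
  }
  tree
}

# root-to-node path lengths for every node (tips first, ape numbering)
node_depths <- function(tree) {
  n_node <- max(tree$edge)
  d <- numeric(n_node)
  root <- ape::Ntip(tree) + 1L
  # edges in preorder so parents are set before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; c <- ord$edge[k, 2]
    d[c] <- d[p] + ord$edge.length[k]
  }
  d[root] <- 0
  d
}

#' Brownian phylogenetic correlation matrix
#'
#' Expected trait correlation among species under Brownian motion on an
#' ultrametric tree: the shared root-to-tip path length of each species
#' pair, divided by the tree depth, so the diagonal is exactly 1. The
#' matrix is symmetric positive semi-definite and is used as the
#' covariance structure of the species random effect.
#'
#' @param tree an ultrametric `ape::phylo` (validated).
#' @param species optional character vector giving the row/column order;
#'   defaults to the tree's tip order.
#' @return A correlation matrix with dimnames set to the species names.
#' @export
phylo_correlation <- function(tree, species = NULL) {
  tree <- validate_phylogeny(tree)
  v <- ape::vcv(tree)
  a <- v / max(diag(v))
  diag(a) <- 1
  a <- (a + t(a)) / 2
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(a))
    if (length(missing))
      st_stop("species_missing",
              paste("species absent from tree:",
                    paste(missing, collapse = ", ")))
    a <- a[species, species, drop = FALSE]
  }
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    st_stop("corr_not_psd", "correlation matrix is not positive semi-definite")
  a
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Grows a tree forward in time from two lineages: while fewer than
#' `n_tips` lineages exist, a waiting time is drawn from an exponential
#' distribution with rate `k * birth_rate` (k = current number of
#' lineages) and a uniformly chosen lineage splits. All tips are then
#' extended to the final time, so the tree is exactly ultrametric.
#' Deterministic for a fixed seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param tip_labels optional tip names, default `t1..tn` assigned in
#'   random order.
#' @return An ultrametric `ape::phylo` object.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL,
                          tip_labels = NULL) {
  if (n_tips < 2L) st_stop("yule_invalid", "n_tips must be >= 2")
  if (birth_rate <= 0) st_stop("yule_invalid", "birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- paste0("t", seq_len(n_tips))
  if (length(tip_labels) != n_tips || anyDuplicated(tip_labels))
    st_stop("yule_invalid", "tip_labels must be n_tips unique names")

  # live lineages tracked by birth time; splits recorded as a parent index
  birth <- c(0, 0)            # origin time of each live lineage's branch
  parent_node <- c(NA, NA)    # internal node id each live branch hangs from
  n_internal <- 1L            # root
  edges <- NULL; elens <- NULL
  node_of <- c(1L, 1L)        # internal node (1-based internal id) above lineage
  t_now <- 0
  while (length(birth) < n_tips) {
    k <- length(birth)
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    i <- sample.int(k, 1L)
    n_internal <- n_internal + 1L
    # lineage i ends at new internal node; two children start here
    edges <- rbind(edges, c(node_of[i], n_internal))
    elens <- c(elens, t_now - birth[i])
    birth[i] <- t_now; node_of[i] <- n_internal
    birth <- c(birth, t_now); node_of <- c(node_of, n_internal)
  }
  t_end <- t_now + stats::rexp(1, rate = length(birth) * birth_rate)

  n <- n_tips
  # assemble ape edge matrix: tips 1..n, internals n+1 .. n+n-1
  int_id <- function(j) n + j
  edge <- matrix(0L, nrow = 2L * n - 2L, ncol = 2L)
  edge_len <- numeric(2L * n - 2L)
  m <- if (is.null(edges)) 0L else nrow(edges)
  for (k in seq_len(m)) {
    edge[k, ] <- c(int_id(edges[k, 1]), int_id(edges[k, 2]))
    edge_len[k] <- elens[k]
  }
  for (i in seq_len(n)) {
    edge[m + i, ] <- c(int_id(node_of[i]), i)
    edge_len[m + i] <- t_end - birth[i]
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = tip_labels, Nnode = n - 1L),
                  class = "phylo", order = "cladewise")
  tr <- ape::reorder.phylo(tr, "cladewise")
  validate_phylogeny(tr)
}
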