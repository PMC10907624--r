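# Weighted sample-drug bipartite network, one-mode projection onto drugs,
# median edge filtering, and Louvain community detection.

#' Build the weighted sample-drug bipartite network
#'
#' One node per sample and per drug; the edge joining sample i and drug j
#' carries weight a_ij, the normalized inhibition rate. Exact-zero weights
#' carry no information for the projection (they contribute nothing to any
#' product sum) and are dropped by default.
#'
#' @param m a `response_matrix` (see [normalize_inhibition()]).
#' @param drop_zero drop edges with weight exactly 0 (default TRUE).
#' @return An [igraph::igraph] bipartite graph with vertex attributes `name`
#'   and `type` (FALSE = sample, TRUE = drug) and edge attribute `weight`.
#' @export
build_bipartite <- function(m, drop_zero = TRUE) {
  stopifnot(inherits(m, "response_matrix"))
  if (nrow(m$a) == 0L || ncol(m$a) == 0L) {
    stop("response matrix is empty", call. = FALSE)
  }
  g <- igraph::graph_from_biadjacency_matrix(m$a, weighted = TRUE)
  if (!drop_zero) {
    # re-add explicit zero-weight edges so the graph is dense
    zero <- which(m$a == 0, arr.ind = TRUE)
    if (nrow(zero)) {
      pairs <- rbind(m$sample_ids[zero[, 1]], m$drug_ids[zero[, 2]])
      g <- igraph::add_edges(g, as.vector(pairs), weight = 0)
    }
  }
  g
}

#' Project the bipartite network onto the drug node set
#'
#' The similarity of drugs i and j is the sum over shared samples of the
#' products of their inhibition rates,
#' \deqn{w_{ij} = \sum_k a_{ik} a_{jk},}
#' i.e. the off-diagonal of the Gram matrix A'A of the response matrix.
#'
#' @param g a bipartite graph from [build_bipartite()].
#' @return A `drug_similarity_network`: list with `weights` (symmetric drug x
#'   drug matrix, zero diagonal), `drugs`, and `filter_threshold`
#'   (NULL before filtering).
#' @export
project_onto_drugs <- function(g) {
  stopifnot(igraph::is_bipartite(g))
  a <- igraph::as_biadjacency_matrix(g, attr = "weight", sparse = FALSE)
  w <- crossprod(a)  # t(A) %*% A
  diag(w) <- 0
  structure(
    list(weights = w, drugs = colnames(a), filter_threshold = NULL),
    class = "drug_similarity_network"
  )
}

#' @export
print.drug_similarity_network <- function(x, ...) {
  ew <- edge_weights(x)
  cat(sprintf("drug_similarity_network: %d drugs, %d edges%s\n",
              length(x$drugs), length(ew),
              if (is.null(x$filter_threshold)) "" else
                sprintf(" (filtered at > %.4g)", x$filter_threshold)))
  invisible(x)
}

#' Positive edge weights of a drug similarity network
#' @param n a `drug_similarity_network`.
#' @return numeric vector of weights of all edges (pairs with w > 0).
#' @export
edge_weights <- function(n) {
  stopifnot(inherits(n, "drug_similarity_network"))
  w <- n$weights[upper.tri(n$weights)]
  w[w > 0]
}

#' Keep only edges stronger than the median similarity
#'
#' Computes the median of all pre-filter edge weights and retains edges whose
#' weight strictly exceeds it (so at most half the edges survive; with all
#' weights equal, none do). Drugs isolated by the filter remain as nodes.
#' For an even edge count the median is the midpoint of the two central
#' order statistics.
#'
#' @param n an unfiltered `drug_similarity_network` with >= 1 edge.
#' @return The filtered network, with `filter_threshold` recorded.
#' @export
filter_edges_median <- function(n) {
  stopifnot(inherits(n, "drug_similarity_network"))
  ew <- edge_weights(n)
  if (length(ew) == 0L) stop("network has no edges", call. = FALSE)
  thr <- stats::median(ew)
  w <- n$weights
  w[w <= thr] <- 0
  structure(
    list(weights = w, drugs = n$drugs, filter_threshold = thr),
    class = "drug_similarity_network"
  )
}

#' Detect drug communities by weighted Louvain modularity maximization
#'
#' Runs Louvain on the (typically median-filtered) drug similarity network
#' under a fixed RNG seed. The number of communities is whatever modularity
#' maximization yields; drugs isolated by filtering become singleton
#' communities. Community ids are contiguous from 1.
#'
#' @param n a `drug_similarity_network` with >= 2 drugs.
#' @param resolution Louvain resolution parameter (default 1.0).
#' @param seed RNG seed controlling Louvain's node sweeps (default 0).
#' @return A `cluster_assignment`: list with `membership` (named integer
#'   vector drug -> community id), `modularity`, `resolution`, `seed`.
#' @export
detect_communities <- function(n, resolution = 1.0, seed = 0) {
  stopifnot(inherits(n, "drug_similarity_network"))
  if (length(n$drugs) < 2L) stop("need at least 2 drugs", call. = FALSE)
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_field("resolution", "must be > 0")
  }
  g <- igraph::graph_from_adjacency_matrix(n$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(cl)
  memb <- stats::setNames(as.integer(factor(memb)), names(memb))  # contiguous
  structure(
    list(membership = memb,
         modularity = igraph::modularity(g, memb,
                                         weights = igraph::E(g)$weight),
         resolution = resolution, seed = seed),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("cluster_assignment: %d communities (sizes %s), modularity %.4f\n",
              length(sizes), paste(sizes, collapse = "/"), x$modularity))
  invisible(x)
}
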