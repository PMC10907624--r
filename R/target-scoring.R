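# Protein-target preference scoring between two drug clusters, PPT/G set
# construction, and generic hypergeometric enrichment with BH-FDR.

#' Score protein targets by cluster preference
#'
#' For each protein P, counts the distinct drugs targeting it in each of two
#' clusters (f1, f2) and scores the preference
#' \deqn{S(P) = \log(f_1 / f_2)}
#' (natural log). With the default `zero_policy = "infinite"`, proteins
#' targeted by one cluster only get an infinite sentinel score of the
#' corresponding sign; `"pseudocount"` adds `pseudocount` to both counts
#' before taking the log.
#'
#' @param map named list: drug id -> character vector of protein ids.
#' @param clusters a `cluster_assignment` (or named integer vector
#'   drug -> cluster id).
#' @param pair length-2 integer, the two cluster ids to compare
#'   (default `c(1, 2)`).
#' @param zero_policy `"infinite"` or `"pseudocount"`.
#' @param pseudocount added to f1 and f2 under the pseudocount policy.
#' @return data.frame with columns `protein`, `f1`, `f2`, `score`, sorted by
#'   decreasing score.
#' @export
score_proteins <- function(map, clusters, pair = c(1L, 2L),
                           zero_policy = c("infinite", "pseudocount"),
                           pseudocount = 0.5) {
  zero_policy <- match.arg(zero_policy)
  if (length(map) == 0L) stop("drug-target map is empty", call. = FALSE)
  memb <- if (inherits(clusters, "cluster_assignment")) clusters$membership else clusters
  unclustered <- setdiff(names(map), names(memb))
  if (length(unclustered)) {
    warning(sprintf("ignoring %d unclustered drug(s): %s",
                    length(unclustered),
                    paste(utils::head(unclustered, 5), collapse = ", ")))
  }
  drugs1 <- intersect(names(map), names(memb)[memb == pair[1]])
  drugs2 <- intersect(names(map), names(memb)[memb == pair[2]])
  proteins <- sort(unique(unlist(map[c(drugs1, drugs2)], use.names = FALSE)))
  count_hits <- function(drugs) {
    tab <- table(unlist(lapply(map[drugs], unique), use.names = FALSE))
    out <- stats::setNames(integer(length(proteins)), proteins)
    out[names(tab)] <- as.integer(tab)
    out
  }
  f1 <- count_hits(drugs1)
  f2 <- count_hits(drugs2)
  score <- if (zero_policy == "pseudocount") {
    log((f1 + pseudocount) / (f2 + pseudocount))
  } else {
    s <- log(f1 / f2)           # f1=0 -> -Inf, f2=0 -> +Inf, both 0 -> NaN
    s[f1 == 0 & f2 == 0] <- NA_real_
    s
  }
  out <- data.frame(protein = proteins, f1 = as.integer(f1),
                    f2 = as.integer(f2), score = as.numeric(score),
                    row.names = NULL)
  out[order(-out$score, out$protein), , drop = FALSE]
}

#' Preferentially targeted protein sets (PPT1 / PPT2)
#'
#' PPT1 collects proteins whose preference score strictly exceeds log(2)
#' (at least twice as many distinct cluster-1 drugs); PPT2 those strictly
#' below log(0.5). The sets are disjoint by construction. Thresholds are
#' configurable but default to the canonical two-fold rule; strictness at
#' the boundary means a protein with f1/f2 exactly 2 is excluded.
#'
#' @param scores data.frame from [score_proteins()].
#' @param threshold upper log-ratio threshold (default `log(2)`); the lower
#'   threshold is its negative.
#' @return list with character vectors `ppt1` and `ppt2`.
#' @export
preferential_sets <- function(scores, threshold = log(2)) {
  stopifnot(is.data.frame(scores), threshold > 0)
  ok <- !is.na(scores$score)
  list(
    ppt1 = scores$protein[ok & scores$score > threshold],
    ppt2 = scores$protein[ok & scores$score < -threshold]
  )
}

#' Cluster-exclusive protein target sets (G1 / G2)
#'
#' G1 holds proteins targeted by at least `min_in` distinct drugs of cluster
#' 1 and at most `max_out` of cluster 2; G2 symmetrically. With the default
#' 3-in / 2-out rule the sets are disjoint; if `min_in <= max_out` they can
#' overlap and a warning is raised.
#'
#' @param map,clusters,pair as in [score_proteins()].
#' @param min_in minimum distinct in-cluster drugs (default 3).
#' @param max_out maximum distinct out-cluster drugs (default 2).
#' @return list with character vectors `g1` and `g2`.
#' @export
exclusive_sets <- function(map, clusters, pair = c(1L, 2L),
                           min_in = 3L, max_out = 2L) {
  min_in <- check_count(min_in, "min_in")
  max_out <- check_count(max_out, "max_out", min = 0L)
  if (min_in <= max_out) {
    warning("min_in <= max_out: G1 and G2 may overlap")
  }
  sc <- score_proteins(map, clusters, pair = pair, zero_policy = "pseudocount")
  list(
    g1 = sc$protein[sc$f1 >= min_in & sc$f2 <= max_out],
    g2 = sc$protein[sc$f2 >= min_in & sc$f1 <= max_out]
  )
}

#' Hypergeometric over-representation test with FDR and fold enrichment
#'
#' For each annotation term, tests whether its overlap with the query set is
#' larger than expected when drawing the query at random from the
#' background: p = P(X >= k) with X hypergeometric(K, N - K, n). Fold
#' enrichment is the query annotation rate over the background rate,
#' (k/n) / (K/N). P-values are Benjamini-Hochberg adjusted.
#'
#' @param query protein/gene set (subset of background).
#' @param annotations named list: term -> member set (intersected with the
#'   background before testing).
#' @param background universe of ids.
#' @param fdr_alpha significance level stored alongside (default 0.05).
#' @return data.frame with one row per term (`term`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`, `fdr`, `significant`), sorted by p-value.
#' @export
hypergeom_enrichment <- function(query, annotations, background,
                                 fdr_alpha = 0.05) {
  if (length(background) == 0L) stop("background is empty", call. = FALSE)
  background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray)) {
    stop(sprintf("query ids outside background: %s",
                 paste(utils::head(stray, 5), collapse = ", ")), call. = FALSE)
  }
  query <- unique(query)
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    members <- intersect(unique(annotations[[term]]), background)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (k == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (n == 0L || K == 0L) 0 else (k / n) / (K / N)
    data.frame(term = term, k = k, n = n, K = K, N = N,
               fold_enrichment = fold, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr < fdr_alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric overlap test between two sets
#'
#' Upper-tail probability of observing at least the realized overlap between
#' two subsets of a common universe; large p indicates no discernible
#' overlap beyond chance.
#'
#' @param set_a,set_b subsets of `universe`.
#' @param universe the common universe of ids.
#' @return one-sided p-value P(X >= |A intersect B|).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop("sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  if (k == 0L) return(1)
  stats::phyper(k - 1L, length(set_a), length(universe) - length(set_a),
                length(set_b), lower.tail = FALSE)
}
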