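# Dice similarity of binary fingerprints and intra- vs inter-cluster
# structural homogeneity testing.

#' Dice similarity between two fingerprints
#'
#' \deqn{S_{A,B} = 2c / (a + b)} where a and b are the ON-bit counts of the
#' two fingerprints and c the count of shared ON bits. Fingerprints are bit
#' sets: integer vectors of ON-bit positions (a `list(on_bits = ...)` is
#' also accepted).
#'
#' @param fp_a,fp_b integer vectors of ON-bit positions.
#' @return similarity in \[0, 1\]; symmetric; 1 for identical nonempty sets.
#' @export
dice <- function(fp_a, fp_b) {
  if (is.list(fp_a)) fp_a <- fp_a$on_bits
  if (is.list(fp_b)) fp_b <- fp_b$on_bits
  a <- length(unique(fp_a)); b <- length(unique(fp_b))
  if (a + b == 0L) {
    stop("Dice similarity undefined for two empty fingerprints", call. = FALSE)
  }
  2 * length(intersect(fp_a, fp_b)) / (a + b)
}

#' Pairwise Dice similarity matrix
#' @param fps named list of fingerprints (integer on-bit vectors).
#' @return symmetric matrix of pairwise Dice similarities (unit diagonal).
#' @export
dice_matrix <- function(fps) {
  n <- length(fps)
  m <- diag(1, n)
  dimnames(m) <- list(names(fps), names(fps))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- dice(fps[[i]], fps[[j]])
    }
  }
  m
}

#' Test structural homogeneity of drug clusters
#'
#' Computes all pairwise Dice similarities within each of two clusters and
#' across them, then tests one-sidedly whether the inter-cluster mean is
#' below each intra-cluster mean, with both a Welch t-test and a
#' Mann-Whitney (Wilcoxon rank-sum) variant. Pairwise similarities share
#' drugs and are therefore dependent; both tests ignore this, so a
#' permutation calibration (shuffling cluster labels) is the honest
#' companion check and is exercised in the package tests.
#'
#' @param fps named list of fingerprints.
#' @param clusters a `cluster_assignment` or named integer vector.
#' @param pair the two cluster ids to compare (default `c(1, 2)`).
#' @return A `homogeneity_result`: list with similarity vectors `intra1`,
#'   `intra2`, `inter`, their means, and a data.frame `tests` with columns
#'   `comparison`, `t_p`, `wilcox_p`, `degenerate`.
#' @export
homogeneity_test <- function(fps, clusters, pair = c(1L, 2L)) {
  memb <- if (inherits(clusters, "cluster_assignment")) clusters$membership else clusters
  memb <- memb[intersect(names(fps), names(memb))]
  d1 <- names(memb)[memb == pair[1]]
  d2 <- names(memb)[memb == pair[2]]
  pair_sims <- function(ids_a, ids_b = NULL) {
    if (is.null(ids_b)) {
      if (length(ids_a) < 2L) return(numeric(0))
      cmb <- utils::combn(ids_a, 2L)
      vapply(seq_len(ncol(cmb)),
             function(k) dice(fps[[cmb[1, k]]], fps[[cmb[2, k]]]), numeric(1))
    } else {
      as.vector(vapply(ids_a, function(x) {
        vapply(ids_b, function(y) dice(fps[[x]], fps[[y]]), numeric(1))
      }, numeric(length(ids_b))))
    }
  }
  intra1 <- pair_sims(d1)
  intra2 <- pair_sims(d2)
  if (length(intra1) == 0L) warning("cluster 1 has < 2 drugs; intra1 omitted")
  if (length(intra2) == 0L) warning("cluster 2 has < 2 drugs; intra2 omitted")
  inter <- pair_sims(d1, d2)

  one_test <- function(intra, label) {
    if (length(intra) == 0L) return(NULL)
    degenerate <- stats::var(c(inter, intra)) == 0
    if (degenerate) {
      t_p <- w_p <- 1  # all similarities identical: no evidence either way
    } else {
      t_p <- stats::t.test(inter, intra, alternative = "less")$p.value
      w_p <- stats::wilcox.test(inter, intra, alternative = "less",
                                exact = FALSE)$p.value
    }
    data.frame(comparison = label, t_p = t_p, wilcox_p = w_p,
               degenerate = degenerate)
  }
  tests <- rbind(one_test(intra1, "inter_vs_intra1"),
                 one_test(intra2, "inter_vs_intra2"))
  structure(
    list(intra1 = intra1, intra2 = intra2, inter = inter,
         means = c(intra1 = mean(intra1), intra2 = mean(intra2),
                   inter = mean(inter)),
         tests = tests),
    class = "homogeneity_result"
  )
}

#' @export
print.homogeneity_result <- function(x, ...) {
  cat(sprintf("homogeneity_result: mean Dice intra1 %.3f, intra2 %.3f, inter %.3f\n",
              x$means["intra1"], x$means["intra2"], x$means["inter"]))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
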