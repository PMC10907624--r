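# Per-drug efficacy/toxicity profiles, top-5% candidate selection,
# inter/intra-cluster combination labeling, and the proportion-test
# framework for evaluating inter-cluster combinations.

#' Per-drug efficacy and toxicity profiles
#'
#' Efficacy is the mean normalized inhibition over patient samples, toxicity
#' the mean over healthy samples — the two selection coordinates.
#'
#' @param m a `response_matrix` with at least one patient and one healthy
#'   sample.
#' @param clusters optional `cluster_assignment` (or named vector) providing
#'   the cluster column.
#' @return data.frame with columns `drug`, `cluster`, `efficacy`, `toxicity`.
#' @export
profile_drugs <- function(m, clusters = NULL) {
  stopifnot(inherits(m, "response_matrix"))
  for (cls in c("patient", "healthy")) {
    if (!any(m$sample_class == cls)) {
      stop(sprintf("no '%s' samples in the response matrix", cls), call. = FALSE)
    }
  }
  pat <- m$sample_class == "patient"
  memb <- if (inherits(clusters, "cluster_assignment")) clusters$membership
          else clusters
  data.frame(
    drug = m$drug_ids,
    cluster = if (is.null(memb)) NA_integer_ else
      as.integer(memb[m$drug_ids]),
    efficacy = colMeans(m$a[pat, , drop = FALSE]),
    toxicity = colMeans(m$a[!pat, , drop = FALSE]),
    row.names = NULL
  )
}

#' Select candidate drugs by efficacy/toxicity co-optimization
#'
#' Keeps drugs whose toxicity is strictly below the mean toxicity of all
#' drugs and whose efficacy is strictly above the mean efficacy, ranks the
#' survivors by decreasing `efficacy - toxicity` (ties broken by drug id;
#' `rank_by = "efficacy"` ranks on efficacy alone), caps the list at
#' `ceiling(fraction * n_drugs)` overall, and finally keeps at most
#' `per_cluster` drugs per cluster.
#'
#' @param profiles data.frame from [profile_drugs()] (cluster column
#'   required for the per-cluster cap).
#' @param fraction overall top fraction of the screen to keep (default 0.05).
#' @param per_cluster cap per cluster (default 4).
#' @param rank_by `"margin"` (efficacy - toxicity) or `"efficacy"`.
#' @return The selected rows of `profiles`, ranked, with a `selected`
#'   column set to TRUE; zero rows (with a warning) when no drug beats both
#'   means.
#' @export
select_candidates <- function(profiles, fraction = 0.05, per_cluster = 4L,
                              rank_by = c("margin", "efficacy")) {
  rank_by <- match.arg(rank_by)
  fraction <- check_prob(fraction, "fraction", lo = 0, hi = 1, lo_open = TRUE)
  per_cluster <- check_count(per_cluster, "per_cluster")
  mean_eff <- mean(profiles$efficacy)
  mean_tox <- mean(profiles$toxicity)
  keep <- profiles$efficacy > mean_eff & profiles$toxicity < mean_tox
  if (!any(keep)) {
    warning("no drug beats both the mean-efficacy and mean-toxicity filters")
    out <- profiles[0, , drop = FALSE]
    out$selected <- logical(0)
    return(out)
  }
  sel <- profiles[keep, , drop = FALSE]
  key <- if (rank_by == "margin") sel$efficacy - sel$toxicity else sel$efficacy
  sel <- sel[order(-key, sel$drug), , drop = FALSE]
  cap <- ceiling(fraction * nrow(profiles))
  sel <- utils::head(sel, cap)
  if (!all(is.na(sel$cluster))) {
    by_cl <- split(seq_len(nrow(sel)), sel$cluster)
    keep_idx <- sort(unlist(lapply(by_cl, utils::head, per_cluster)))
    sel <- sel[keep_idx, , drop = FALSE]
  }
  sel$selected <- TRUE
  rownames(sel) <- NULL
  sel
}

#' Enumerate and label drug combinations as inter- or intra-cluster
#'
#' Given selected drugs (or explicit pairs), labels each unordered pair
#' `"inter"` when the two drugs belong to different clusters and
#' `"intra_<cluster>"` otherwise. With four drugs selected per cluster, the
#' full pairing yields 16 inter and 6 + 6 intra combinations.
#'
#' @param drugs character vector of drug ids; all C(n, 2) unordered pairs
#'   are formed. Alternatively a two-column data.frame/matrix of explicit
#'   pairs.
#' @param clusters `cluster_assignment` or named integer vector covering all
#'   drugs involved.
#' @return data.frame with columns `drug1`, `drug2`, `cluster1`, `cluster2`,
#'   `group`.
#' @export
label_combinations <- function(drugs, clusters) {
  memb <- if (inherits(clusters, "cluster_assignment")) clusters$membership
          else clusters
  if (is.data.frame(drugs) || is.matrix(drugs)) {
    pairs <- as.data.frame(drugs)[, 1:2]
    names(pairs) <- c("drug1", "drug2")
  } else {
    drugs <- as.character(drugs)
    if (length(drugs) < 2L) stop("need at least 2 drugs", call. = FALSE)
    cmb <- utils::combn(drugs, 2L)
    pairs <- data.frame(drug1 = cmb[1, ], drug2 = cmb[2, ])
  }
  if (any(pairs$drug1 == pairs$drug2)) {
    stop("self-combinations are not allowed", call. = FALSE)
  }
  missing <- setdiff(unique(c(pairs$drug1, pairs$drug2)), names(memb))
  if (length(missing)) {
    stop(sprintf("unclustered drug(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  pairs$cluster1 <- as.integer(memb[pairs$drug1])
  pairs$cluster2 <- as.integer(memb[pairs$drug2])
  pairs$group <- ifelse(pairs$cluster1 != pairs$cluster2, "inter",
                        paste0("intra_", pairs$cluster1))
  rownames(pairs) <- NULL
  pairs
}

#' Proportion test for inter-cluster combination superiority
#'
#' A combination is a success when its first metric (efficacy-like: higher is
#' better) strictly exceeds the third quartile of that metric over ALL
#' combinations and its second metric (toxicity-like: lower is better) falls
#' strictly below the first quartile. The test asks whether the success
#' proportion among inter-cluster combinations exceeds the null probability
#' `p0` (default 0.33), one-sided. Quartiles use linear interpolation
#' (type 7). The exact mode computes the binomial upper tail
#' P(X >= k | n, p0); the normal mode uses the z approximation without
#' continuity correction.
#'
#' @param records data.frame of combinations with a `group` column and the
#'   two metric columns.
#' @param metric_pair names of the (higher-better, lower-better) columns;
#'   default `c("efficacy", "toxicity")`. The same machinery applies to
#'   synergy-score or combination-ratio column pairs.
#' @param p0 null success probability (default 0.33).
#' @param mode `"exact_binomial"` (default) or `"normal_approx"`.
#' @return A `proportion_test_result`: list with `k`, `n`, `p0`, `p_value`,
#'   `q3` and `q1` thresholds, `metric_pair`, `mode`, and the logical
#'   success vector for the inter group.
#' @export
proportion_test <- function(records,
                            metric_pair = c("efficacy", "toxicity"),
                            p0 = 0.33,
                            mode = c("exact_binomial", "normal_approx")) {
  mode <- match.arg(mode)
  p0 <- check_prob(p0, "p0", lo = 0, hi = 1, lo_open = TRUE, hi_open = TRUE)
  stopifnot(all(metric_pair %in% names(records)), "group" %in% names(records))
  hi_metric <- records[[metric_pair[1]]]
  lo_metric <- records[[metric_pair[2]]]
  q3 <- stats::quantile(hi_metric, 0.75, type = 7, names = FALSE)
  q1 <- stats::quantile(lo_metric, 0.25, type = 7, names = FALSE)
  inter <- records$group == "inter"
  n <- sum(inter)
  if (n == 0L) stop("no inter-cluster combinations", call. = FALSE)
  success <- hi_metric[inter] > q3 & lo_metric[inter] < q1
  k <- sum(success)
  p <- if (mode == "exact_binomial") {
    stats::pbinom(k - 1L, n, p0, lower.tail = FALSE)
  } else {
    z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
    stats::pnorm(z, lower.tail = FALSE)
  }
  structure(
    list(k = k, n = n, p0 = p0, p_value = p, q3 = q3, q1 = q1,
         metric_pair = metric_pair, mode = mode, success = success),
    class = "proportion_test_result"
  )
}

#' @export
print.proportion_test_result <- function(x, ...) {
  cat(sprintf(
    "proportion_test: %d/%d inter-cluster successes (%s > Q3 & %s < Q1), p0 = %.2f, p = %.3g (%s)\n",
    x$k, x$n, x$metric_pair[1], x$metric_pair[2], x$p0, x$p_value, x$mode))
  invisible(x)
}
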