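# Screen containers, min-max inhibition normalization, and complete-submatrix
# extraction.

#' Raw drug-response screen
#'
#' Container for a sample x drug matrix of raw cell-death readouts (arbitrary
#' units) with patient/healthy sample labels and an explicit missing-value
#' mask. Missing cells are stored as `NA` in `values` and flagged in
#' `missing_mask`.
#'
#' @param values numeric sample x drug matrix; `NA` marks missing cells.
#' @param sample_class character vector, one of `"patient"` or `"healthy"`
#'   per sample (row).
#' @param sample_ids,drug_ids optional ids; default to dimnames or generated.
#' @param drug_cluster optional planted cluster labels per drug (used by the
#'   simulator so recovery can be scored downstream).
#'
#' @return An object of class `raw_screen`: a list with elements `values`,
#'   `missing_mask`, `sample_ids`, `drug_ids`, `sample_class`, `drug_cluster`.
#' @export
raw_screen <- function(values, sample_class, sample_ids = NULL,
                       drug_ids = NULL, drug_cluster = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(drug_ids)) {
    drug_ids <- colnames(values)
    if (is.null(drug_ids)) drug_ids <- sprintf("D%03d", seq_len(ncol(values)))
  }
  if (length(sample_ids) != nrow(values) || length(drug_ids) != ncol(values)) {
    stop("id lengths must match matrix dimensions", call. = FALSE)
  }
  sample_class <- match.arg(sample_class, c("patient", "healthy"),
                            several.ok = TRUE)
  if (length(sample_class) != nrow(values)) {
    stop("sample_class must label every sample", call. = FALSE)
  }
  if (!is.null(drug_cluster) && length(drug_cluster) != ncol(values)) {
    stop("drug_cluster must label every drug", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, drug_ids)
  structure(
    list(
      values = values,
      missing_mask = is.na(values),
      sample_ids = sample_ids,
      drug_ids = drug_ids,
      sample_class = stats::setNames(sample_class, sample_ids),
      drug_cluster = if (is.null(drug_cluster)) NULL else
        stats::setNames(drug_cluster, drug_ids)
    ),
    class = "raw_screen"
  )
}

#' @export
print.raw_screen <- function(x, ...) {
  cat(sprintf(
    "raw_screen: %d samples (%d patient, %d healthy) x %d drugs, %.1f%% missing\n",
    nrow(x$values), sum(x$sample_class == "patient"),
    sum(x$sample_class == "healthy"), ncol(x$values),
    100 * mean(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.raw_screen <- function(x) dim(x$values)

#' Normalize raw cell-death readouts to inhibition rates
#'
#' Min-max normalizes raw readouts so that 1 is the highest observed
#' sensitivity and 0 the lowest:
#' \deqn{R = (x - \min x) / (\max x - \min x).}
#' The scope of min/max is either the whole matrix (`"global"`, the default:
#' one uniform measure across the screen) or each drug column separately
#' (`"per_drug"`).
#'
#' @param raw a [raw_screen] with no missing entries (run
#'   [extract_complete_submatrix()] first).
#' @param scope `"global"` or `"per_drug"`.
#'
#' @return A `response_matrix`: list with `a` (sample x drug matrix in
#'   \[0, 1\]), `sample_ids`, `drug_ids`, `sample_class`, `drug_cluster`.
#' @export
normalize_inhibition <- function(raw, scope = c("global", "per_drug")) {
  scope <- match.arg(scope)
  stopifnot(inherits(raw, "raw_screen"))
  if (any(raw$missing_mask)) {
    stop("raw screen contains missing entries; extract a complete submatrix first",
         call. = FALSE)
  }
  x <- raw$values
  if (scope == "global") {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      stop("degenerate range: all values equal within global scope",
           call. = FALSE)
    }
    a <- (x - rng[1]) / (rng[2] - rng[1])
  } else {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    bad <- which(hi == lo)
    if (length(bad)) {
      stop(sprintf("degenerate range: constant drug column(s) %s within per_drug scope",
                   paste(raw$drug_ids[bad], collapse = ", ")), call. = FALSE)
    }
    a <- sweep(sweep(x, 2, lo, "-"), 2, hi - lo, "/")
  }
  structure(
    list(a = a, sample_ids = raw$sample_ids, drug_ids = raw$drug_ids,
         sample_class = raw$sample_class, drug_cluster = raw$drug_cluster),
    class = "response_matrix"
  )
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d samples x %d drugs, a in [%.3f, %.3f]\n",
              nrow(x$a), ncol(x$a), min(x$a), max(x$a)))
  invisible(x)
}

#' Extract the complete (no-missing) submatrix of a screen
#'
#' Greedy heuristic: while missing cells remain, delete either the row or the
#' column with the most missing entries. Under `priority = "max_area"` the
#' row-vs-column choice at each step keeps the larger number of observed
#' cells; under `"rows_first"` the line with the larger absolute missing count
#' is deleted, ties going to the row. After deletion a restoration pass
#' re-adds any deleted line that no longer introduces a missing cell, so the
#' result is maximal: no single deleted row or column can be added back.
#'
#' @param raw a [raw_screen].
#' @param priority `"max_area"` (default) or `"rows_first"`.
#'
#' @return A [raw_screen] restricted to the retained rows and columns (input
#'   order preserved) with zero missing entries.
#' @export
extract_complete_submatrix <- function(raw, priority = c("max_area", "rows_first")) {
  priority <- match.arg(priority)
  stopifnot(inherits(raw, "raw_screen"))
  miss <- raw$missing_mask
  if (nrow(miss) == 0L || ncol(miss) == 0L) {
    stop("raw screen is empty", call. = FALSE)
  }
  keep_r <- rep(TRUE, nrow(miss))
  keep_c <- rep(TRUE, ncol(miss))

  pick <- function(counts, ids, keep) {
    idx <- which(keep)
    cand <- idx[counts[idx] == max(counts[idx])]
    cand[order(ids[cand])][1L]
  }

  repeat {
    sub <- miss[keep_r, keep_c, drop = FALSE]
    if (!any(sub)) break
    if (sum(keep_r) == 0L || sum(keep_c) == 0L) {
      stop("no complete submatrix exists: all rows or columns eliminated",
           call. = FALSE)
    }
    rm_cnt <- rowSums(miss[, keep_c, drop = FALSE])
    cm_cnt <- colSums(miss[keep_r, , drop = FALSE])
    br <- pick(rm_cnt, raw$sample_ids, keep_r)
    bc <- pick(cm_cnt, raw$drug_ids, keep_c)
    nr <- sum(keep_r); nc <- sum(keep_c)
    total_obs <- sum(!sub)
    if (priority == "max_area") {
      # observed cells remaining after each candidate deletion
      rem_row <- total_obs - sum(!miss[br, keep_c])
      rem_col <- total_obs - sum(!miss[keep_r, bc])
      del_row <- if (rem_row != rem_col) rem_row > rem_col else
        rm_cnt[br] >= cm_cnt[bc]
    } else {
      del_row <- rm_cnt[br] >= cm_cnt[bc]
    }
    if (del_row) keep_r[br] <- FALSE else keep_c[bc] <- FALSE
    if (!any(keep_r) || !any(keep_c)) {
      stop("no complete submatrix exists: all rows or columns eliminated",
           call. = FALSE)
    }
  }

  # restoration pass: greedy deletion can strand re-addable lines
  repeat {
    added <- FALSE
    for (i in which(!keep_r)) {
      if (!any(miss[i, keep_c])) { keep_r[i] <- TRUE; added <- TRUE }
    }
    for (j in which(!keep_c)) {
      if (!any(miss[keep_r, j])) { keep_c[j] <- TRUE; added <- TRUE }
    }
    if (!added) break
  }

  raw_screen(
    values = raw$values[keep_r, keep_c, drop = FALSE],
    sample_class = unname(raw$sample_class[keep_r]),
    sample_ids = raw$sample_ids[keep_r],
    drug_ids = raw$drug_ids[keep_c],
    drug_cluster = if (is.null(raw$drug_cluster)) NULL else
      unname(raw$drug_cluster[keep_c])
  )
}
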