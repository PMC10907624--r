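# Plain-text readers/writers for the pipeline's interchange formats: screen
# matrix CSV, drug-target TSV, fingerprint TSV, long-format combination
# surface CSV, edge-list/cluster TSV, and GMT annotation sets.

#' Write / read a screen matrix CSV
#'
#' Layout: first column `sample`, second column `class`
#' (patient/healthy), remaining columns one per drug; empty cells denote
#' missing values.
#'
#' @param raw a [raw_screen].
#' @param path file path.
#' @return `read_screen_csv()` returns a [raw_screen].
#' @export
write_screen_csv <- function(raw, path) {
  stopifnot(inherits(raw, "raw_screen"))
  df <- data.frame(sample = raw$sample_ids,
                   class = unname(raw$sample_class),
                   raw$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_screen_csv
#' @export
read_screen_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("screen CSV needs sample, class and drug columns",
                          call. = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  raw_screen(vals, sample_class = df[[2]], sample_ids = as.character(df[[1]]),
             drug_ids = colnames(df)[-(1:2)])
}

#' Write / read a drug-target map TSV (one drug-protein pair per row)
#' @param map named list drug -> protein id vector.
#' @param path file path.
#' @return `read_target_map_tsv()` returns the named list.
#' @export
write_target_map_tsv <- function(map, path) {
  df <- data.frame(
    drug = rep(names(map), lengths(map)),
    protein = unlist(map, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_target_map_tsv
#' @export
read_target_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(as.character(df[[2]]), factor(df[[1]], levels = unique(df[[1]])))
}

#' Write / read fingerprints TSV (drug, comma-separated on-bit indices,
#' total bit count)
#' @param fps named list of 0-based on-bit integer vectors with attribute
#'   `n_bits`.
#' @param path file path.
#' @return `read_fingerprints_tsv()` returns the named list with `n_bits`.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  df <- data.frame(
    drug = names(fps),
    on_bits = vapply(fps, function(b) paste(b, collapse = ","), character(1)),
    n_bits = attr(fps, "n_bits") %||% (max(unlist(fps)) + 1L)
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprints_tsv
#' @export
read_fingerprints_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fps <- lapply(strsplit(as.character(df$on_bits), ","), as.integer)
  names(fps) <- df$drug
  attr(fps, "n_bits") <- max(df$n_bits)
  fps
}

#' Write / read a combination surface in long format
#'
#' Columns `drug1, drug2, dose1, dose2, response`; rows with `dose2 == 0`
#' carry drug-1 monotherapy, rows with `dose1 == 0` drug-2 monotherapy.
#'
#' @param surface a [dose_response_surface].
#' @param path file path.
#' @return `read_surface_csv()` returns a [dose_response_surface].
#' @export
write_surface_csv <- function(surface, path) {
  stopifnot(inherits(surface, "dose_response_surface"))
  grid <- expand.grid(i = seq_along(surface$doses_a),
                      j = seq_along(surface$doses_b))
  df <- rbind(
    data.frame(drug1 = surface$drug_a, drug2 = surface$drug_b,
               dose1 = surface$doses_a, dose2 = 0,
               response = surface$mono_a),
    data.frame(drug1 = surface$drug_a, drug2 = surface$drug_b,
               dose1 = 0, dose2 = surface$doses_b,
               response = surface$mono_b),
    data.frame(drug1 = surface$drug_a, drug2 = surface$drug_b,
               dose1 = surface$doses_a[grid$i], dose2 = surface$doses_b[grid$j],
               response = surface$combo[cbind(grid$i, grid$j)])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug1", "drug2", "dose1", "dose2", "response")
  if (!all(need %in% names(df))) {
    stop(sprintf("surface CSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  mono_a <- df[df$dose2 == 0 & df$dose1 > 0, ]
  mono_b <- df[df$dose1 == 0 & df$dose2 > 0, ]
  comb <- df[df$dose1 > 0 & df$dose2 > 0, ]
  da <- sort(unique(comb$dose1)); db <- sort(unique(comb$dose2))
  combo <- matrix(NA_real_, length(da), length(db))
  combo[cbind(match(comb$dose1, da), match(comb$dose2, db))] <- comb$response
  if (any(is.na(combo))) stop("incomplete combination grid", call. = FALSE)
  dose_response_surface(
    drug_a = df$drug1[1], drug_b = df$drug2[1], doses_a = da, doses_b = db,
    mono_a = mono_a$response[match(da, mono_a$dose1)],
    mono_b = mono_b$response[match(db, mono_b$dose2)],
    combo = combo
  )
}

#' Write a drug similarity network as a weighted edge list TSV
#' @param n a `drug_similarity_network`.
#' @param path file path.
#' @export
write_edge_list_tsv <- function(n, path) {
  stopifnot(inherits(n, "drug_similarity_network"))
  idx <- which(upper.tri(n$weights) & n$weights > 0, arr.ind = TRUE)
  df <- data.frame(drug1 = n$drugs[idx[, 1]], drug2 = n$drugs[idx[, 2]],
                   weight = n$weights[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cluster assignment as a two-column TSV
#' @param cl a `cluster_assignment`.
#' @param path file path.
#' @export
write_clusters_tsv <- function(cl, path) {
  stopifnot(inherits(cl, "cluster_assignment"))
  df <- data.frame(drug = names(cl$membership),
                   cluster = as.integer(cl$membership))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annotation sets in GMT format (term, description, members...)
#' @param path file path.
#' @return named list term -> character vector of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
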