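# Shared oracles and fixtures, all computed independently of the code paths
# they check.

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      grow(c(prefix, b), max(maxblock, b))
    }
  }
  grow(integer(0), 0L)
  out
}

# exact upper-tail hypergeometric by enumeration with choose()
hyper_upper <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# exact upper-tail binomial by enumeration
binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# brute-force BH step-up rejection set
bh_reject <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= alpha * seq_len(n) / n)
  rej <- logical(n)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# small random raw screen with iid missingness, for extraction tests
random_raw_screen <- function(n_s, n_d, miss, seed) {
  set.seed(seed)
  v <- matrix(runif(n_s * n_d), n_s, n_d)
  v[matrix(runif(n_s * n_d) < miss, n_s, n_d)] <- NA_real_
  raw_screen(v, sample_class = rep(c("patient", "healthy"),
                                   length.out = n_s))
}

# maximum complete-submatrix area by exhaustive row-subset enumeration
max_complete_area <- function(miss) {
  n <- nrow(miss)
  best <- 0L
  for (code in 0:(2^n - 1)) {
    rows <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    if (length(rows) == 0L) next
    cols_ok <- colSums(miss[rows, , drop = FALSE]) == 0L
    best <- max(best, length(rows) * sum(cols_ok))
  }
  best
}

run_clustering <- function(raw) {
  cm <- extract_complete_submatrix(raw)
  m <- normalize_inhibition(cm)
  net <- filter_edges_median(project_onto_drugs(build_bipartite(m)))
  list(complete = cm, clusters = detect_communities(net))
}
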