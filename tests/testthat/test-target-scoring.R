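# Protein preference scores, PPT/G sets, hypergeometric enrichment.

# map with prescribed (f1, f2) counts for one protein per row
map_from_counts <- function(counts) {
  map <- list()
  clusters <- integer(0)
  for (r in seq_len(nrow(counts))) {
    p <- rownames(counts)[r]
    for (i in seq_len(counts[r, 1])) {
      d <- sprintf("C1_%s_%d", p, i)
      map[[d]] <- c(map[[d]], p); clusters[d] <- 1L
    }
    for (i in seq_len(counts[r, 2])) {
      d <- sprintf("C2_%s_%d", p, i)
      map[[d]] <- c(map[[d]], p); clusters[d] <- 2L
    }
  }
  list(map = map, clusters = clusters)
}

test_that("protein scores follow log(f1/f2) with strict PPT thresholds", {
  counts <- matrix(c(4, 2, 3, 3, 5, 1), ncol = 2, byrow = TRUE,
                   dimnames = list(c("PA", "PB", "PC"), NULL))
  x <- map_from_counts(counts)
  sc <- score_proteins(x$map, x$clusters)
  sc <- sc[match(c("PA", "PB", "PC"), sc$protein), ]
  expect_equal(sc$score, c(log(2), 0, log(5)))

  ppt <- preferential_sets(sc)
  # S = log 2 sits exactly at the boundary: excluded by strictness
  expect_false("PA" %in% ppt$ppt1)
  expect_true("PC" %in% ppt$ppt1)
  expect_length(ppt$ppt2, 0)
})

test_that("zero-count policies and antisymmetry behave as documented", {
  counts <- matrix(c(3, 0, 0, 2, 2, 4), ncol = 2, byrow = TRUE,
                   dimnames = list(c("PA", "PB", "PC"), NULL))
  x <- map_from_counts(counts)
  sc <- score_proteins(x$map, x$clusters)
  expect_equal(sc$score[sc$protein == "PA"], Inf)
  expect_equal(sc$score[sc$protein == "PB"], -Inf)
  ppt <- preferential_sets(sc)
  expect_true("PA" %in% ppt$ppt1)
  expect_true("PB" %in% ppt$ppt2)

  scp <- score_proteins(x$map, x$clusters, zero_policy = "pseudocount")
  expect_true(all(is.finite(scp$score)))

  # relabeling clusters negates scores and swaps the sets
  swapped <- 3L - x$clusters
  sc_sw <- score_proteins(x$map, swapped)
  m <- match(sc$protein, sc_sw$protein)
  expect_equal(sc_sw$score[m], -sc$score)
  ppt_sw <- preferential_sets(sc_sw)
  expect_setequal(ppt_sw$ppt1, ppt$ppt2)
  expect_setequal(ppt_sw$ppt2, ppt$ppt1)
})

test_that("exclusive sets apply the at-least-3 / at-most-2 rule", {
  counts <- matrix(c(3, 2, 3, 3, 2, 0, 0, 4), ncol = 2, byrow = TRUE,
                   dimnames = list(c("PA", "PB", "PC", "PD"), NULL))
  x <- map_from_counts(counts)
  ex <- exclusive_sets(x$map, x$clusters)
  expect_true("PA" %in% ex$g1)     # f1=3, f2=2
  expect_false("PB" %in% ex$g1)    # f2=3 too many
  expect_false("PB" %in% ex$g2)
  expect_false("PC" %in% ex$g1)    # f1=2 below min_in
  expect_true("PD" %in% ex$g2)
  expect_error(exclusive_sets(x$map, x$clusters, min_in = 0), "min_in")
})

test_that("biased synthetic maps put own-pool proteins into the matching PPT set", {
  hits <- replicate(20, {
    labels <- stats::setNames(rep(1:2, each = 20), sprintf("D%03d", 1:40))
    seed <- sample.int(1e6, 1)
    map <- simulate_target_map(labels, n_proteins = 40, bias = 0.9,
                               n_targets_per_drug = 5, seed = seed)
    sc <- score_proteins(map, labels)
    ppt <- preferential_sets(sc)
    pool1 <- attr(map, "pools")[[1]]
    scored1 <- intersect(pool1, sc$protein)
    length(intersect(scored1, ppt$ppt1)) / length(scored1)
  })
  expect_gte(mean(hits), 0.8)
})

test_that("hypergeometric enrichment matches exact enumeration", {
  bg <- sprintf("P%02d", 1:20)
  ann <- list(all = bg, term5 = bg[1:5], off = bg[16:20])
  res <- hypergeom_enrichment(bg[1:5], ann, bg)

  r_all <- res[res$term == "all", ]
  expect_equal(r_all$fold_enrichment, 1)
  expect_equal(r_all$p_value, 1)

  r5 <- res[res$term == "term5", ]
  expect_equal(r5$p_value, 1 / choose(20, 5))
  expect_equal(r5$p_value, 6.449948e-05, tolerance = 1e-6)
  expect_equal(r5$fold_enrichment, 4)

  r_off <- res[res$term == "off", ]
  expect_equal(r_off$k, 0L)
  expect_equal(r_off$fold_enrichment, 0)
  expect_equal(r_off$p_value, 1)

  expect_error(hypergeom_enrichment(c("X"), ann, bg), "outside background")
  expect_error(hypergeom_enrichment(bg[1], ann, character(0)), "empty")
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:10, 1))
    fdr <- p.adjust(p, "BH")  # what the package applies internally
    bg <- sprintf("G%02d", 1:20)
    # same rejection set as explicit step-up at several alphas
    for (alpha in c(0.05, 0.2, 0.5)) {
      expect_identical(fdr <= alpha, bh_reject(p, alpha))
    }
  }
})

test_that("enrichment p-values are invariant to protein renaming", {
  bg <- sprintf("P%02d", 1:15)
  ann <- list(a = bg[1:6], b = bg[5:12])
  q <- bg[c(1:4, 8)]
  r1 <- hypergeom_enrichment(q, ann, bg)
  ren <- stats::setNames(sprintf("X%02d", 15:1), bg)
  r2 <- hypergeom_enrichment(unname(ren[q]),
                             lapply(ann, function(s) unname(ren[s])),
                             unname(ren[bg]))
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$fold_enrichment, r2$fold_enrichment)
})

test_that("overlap test equals the exact tail probability", {
  u <- sprintf("U%02d", 1:10)
  expect_equal(overlap_test(u[1:4], u[1:5], u), 5 / 210, tolerance = 1e-12)
  expect_equal(overlap_test(u, u, u), 1)
  expect_equal(overlap_test(u[1:3], u[4:6], u), 1)
  expect_error(overlap_test(u[1:3], "ZZ", u), "subsets")
})
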