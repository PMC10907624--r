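# Efficacy/toxicity profiling, candidate selection, combination labeling,
# proportion testing.

rm_small <- function(a, class) {
  rownames(a) <- sprintf("S%03d", seq_len(nrow(a)))
  colnames(a) <- sprintf("D%03d", seq_len(ncol(a)))
  structure(list(a = a, sample_ids = rownames(a), drug_ids = colnames(a),
                 sample_class = stats::setNames(class, rownames(a)),
                 drug_cluster = NULL),
            class = "response_matrix")
}

test_that("drug profiles are class-wise means of the response matrix", {
  a <- matrix(c(0, 0, 0.8, 0.2), 2, 2)
  m <- rm_small(a, c("patient", "healthy"))
  p <- profile_drugs(m)
  expect_equal(p$efficacy, a[1, ])
  expect_equal(p$toxicity, a[2, ])

  set.seed(3)
  a10 <- matrix(runif(40), 10, 4)
  cls <- rep(c("patient", "healthy"), c(7, 3))
  p10 <- profile_drugs(rm_small(a10, cls))
  expect_lt(max(abs(p10$efficacy - colMeans(a10[1:7, ]))), 1e-12)
  expect_lt(max(abs(p10$toxicity - colMeans(a10[8:10, ]))), 1e-12)

  expect_error(profile_drugs(rm_small(a10, rep("patient", 10))), "healthy")
})

test_that("selection requires beating both means and respects caps", {
  prof <- data.frame(drug = sprintf("D%02d", 1:10),
                     cluster = rep(1:2, 5),
                     efficacy = rep(0.3, 10), toxicity = rep(0.3, 10))
  expect_warning(sel0 <- select_candidates(prof), "no drug")
  expect_equal(nrow(sel0), 0)

  prof$efficacy[1] <- 0.9; prof$toxicity[1] <- 0.05
  sel <- select_candidates(prof)
  expect_equal(sel$drug[1], "D01")
  expect_true(all(sel$efficacy > mean(prof$efficacy)))
  expect_true(all(sel$toxicity < mean(prof$toxicity)))

  # per-cluster cap and overall fraction cap
  set.seed(9)
  prof2 <- data.frame(drug = sprintf("D%03d", 1:200),
                      cluster = rep(1:2, each = 100),
                      efficacy = runif(200), toxicity = runif(200))
  sel2 <- select_candidates(prof2, fraction = 0.05, per_cluster = 4)
  expect_lte(nrow(sel2), ceiling(0.05 * 200))
  expect_true(all(table(sel2$cluster) <= 4))
  expect_true(all(sel2$efficacy > mean(prof2$efficacy)))
  expect_true(all(sel2$toxicity < mean(prof2$toxicity)))
})

test_that("selection is invariant to drug order", {
  set.seed(12)
  prof <- data.frame(drug = sprintf("D%03d", 1:60), cluster = rep(1:2, 30),
                     efficacy = runif(60), toxicity = runif(60))
  sel1 <- select_candidates(prof)
  perm <- sample(60)
  sel2 <- select_candidates(prof[perm, ])
  expect_identical(sel1$drug, sel2$drug)
})

test_that("combination labeling yields 16 inter and 12 intra pairs for 4+4 drugs", {
  drugs <- sprintf("D%02d", 1:8)
  clusters <- stats::setNames(rep(1:2, each = 4), drugs)
  lab <- label_combinations(drugs, clusters)
  expect_equal(nrow(lab), choose(8, 2))
  expect_equal(sum(lab$group == "inter"), 16)
  expect_equal(sum(lab$group != "inter"), 12)
  expect_equal(sum(lab$group == "intra_1"), 6)
  expect_equal(sum(lab$group == "intra_2"), 6)
  expect_true(all((lab$group == "inter") == (lab$cluster1 != lab$cluster2)))

  expect_error(label_combinations(data.frame(d1 = "D01", d2 = "D01"), clusters),
               "self")
  expect_error(label_combinations(c("D01", "ZZZ"), clusters), "unclustered")
})

test_that("proportion test applies pooled Q3/Q1 thresholds to inter pairs", {
  set.seed(21)
  rec <- data.frame(group = rep(c("inter", "intra_1"), c(16, 12)),
                    efficacy = runif(28), toxicity = runif(28))
  pt <- proportion_test(rec)
  expect_equal(pt$q3, unname(quantile(rec$efficacy, 0.75)))
  expect_equal(pt$q1, unname(quantile(rec$toxicity, 0.25)))
  inter <- rec[rec$group == "inter", ]
  expect_equal(pt$k, sum(inter$efficacy > pt$q3 & inter$toxicity < pt$q1))
  expect_equal(pt$n, 16L)

  # all successes: p = p0^n (bulk keeps the pooled quantiles interior)
  bulk <- data.frame(group = "intra_2",
                     efficacy = seq(0, 1, length.out = 100),
                     toxicity = seq(0, 1, length.out = 100))
  rec2 <- rbind(rec, bulk)
  rec2$efficacy[rec2$group == "inter"] <- 2  # above any pooled Q3
  rec2$toxicity[rec2$group == "inter"] <- -1
  pt2 <- proportion_test(rec2)
  expect_equal(pt2$p_value, 0.33^16, tolerance = 1e-12)
  expect_equal(pt2$p_value, 2.2e-8, tolerance = 0.05)

  # zero successes: one-sided p = 1
  rec3 <- rec
  rec3$efficacy[rec3$group == "inter"] <- -1
  pt3 <- proportion_test(rec3)
  expect_equal(pt3$p_value, 1)

  expect_error(proportion_test(rec[rec$group != "inter", ]), "inter")
})

test_that("exact mode matches the enumeration oracle and duality holds", {
  for (n in c(5, 12, 25)) {
    for (k in 0:n) {
      rec <- data.frame(group = rep("inter", n),
                        efficacy = c(rep(2, k), rep(-2, n - k)),
                        toxicity = c(rep(-2, k), rep(2, n - k)))
      # add bulk records so pooled quantiles are interior
      bulk <- data.frame(group = "intra_1",
                         efficacy = seq(0, 1, length.out = 200),
                         toxicity = seq(0, 1, length.out = 200))
      pt <- proportion_test(rbind(rec, bulk))
      expect_equal(pt$k, k)
      expect_equal(pt$p_value, binom_upper(k, n, 0.33), tolerance = 1e-12)
    }
  }

  # swapping metric roles with negated values preserves the success set
  set.seed(30)
  rec <- data.frame(group = rep(c("inter", "intra_2"), c(10, 10)),
                    efficacy = runif(20), toxicity = runif(20))
  pt <- proportion_test(rec)
  dual <- data.frame(group = rec$group,
                     efficacy = -rec$toxicity, toxicity = -rec$efficacy)
  pt_d <- proportion_test(dual)
  expect_identical(pt$success, pt_d$success)

  # normal approximation agrees in direction with the exact tail
  rec_k <- rec
  rec_k$efficacy[1:6] <- 2; rec_k$toxicity[1:6] <- -1
  pe <- proportion_test(rec_k, mode = "exact_binomial")
  pn <- proportion_test(rec_k, mode = "normal_approx")
  expect_equal(pe$k, pn$k)
  expect_lt(abs(pe$p_value - pn$p_value), 0.1)
})
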