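# Hill fitting, synergy reference models, CR and DSS.

ladder <- c(1, 10, 100, 1000, 10000)

test_that("Hill fitting recovers known parameters and flags degeneracy", {
  true <- hill_params(0, 1, 100, 1)
  fit <- fit_hill(ladder, hill_response(ladder, true))
  expect_equal(fit$e_max, 1, tolerance = 0.01)
  expect_equal(fit$ec50, 100, tolerance = 1)
  expect_equal(fit$slope, 1, tolerance = 0.01)
  expect_lt(attr(fit, "rmse"), 1e-6)

  flat <- fit_hill(ladder, rep(0.5, 5))
  expect_true(attr(flat, "degenerate"))
  expect_equal(hill_response(50, flat), 0.5, tolerance = 0.01)

  expect_error(fit_hill(c(1, 10, 100), c(0, 0.5, 1)), "4 dose")

  # midpoint identity
  p <- hill_params(0.1, 0.9, 30, 2)
  expect_equal(hill_response(30, p), 0.5)
  expect_equal(hill_inverse(0.5, p), 30)
})

test_that("expected responses follow the null-model formulas", {
  expect_equal(expected_response("bliss", y_a = 0.5, y_b = 0.5), 0.75)
  expect_equal(expected_response("hsa", y_a = 0.3, y_b = 0.6), 0.6)

  # sham combination: Loewe expectation is the response at the summed dose
  p <- hill_params(0, 1, 100, 1.3)
  for (x in c(5, 50, 500)) {
    expect_equal(expected_response("loewe", x_a = x, x_b = x,
                                   hill_a = p, hill_b = p),
                 hill_response(2 * x, p), tolerance = 1e-6)
  }
  # dose 0 on one side reduces to the other monotherapy
  expect_equal(expected_response("loewe", x_a = 0, x_b = 100,
                                 hill_a = p, hill_b = p),
               hill_response(100, p))
})

test_that("each model scores zero on its own noise-free null surface", {
  sub_a <- hill_params(0, 0.5, 50, 1.2)
  sub_b <- hill_params(0, 0.4, 300, 0.9)
  s_b <- simulate_surface(surface_spec(sub_a, sub_b, interaction = "bliss_independent"))
  expect_equal(synergy_score(s_b, "bliss")$score, 0)
  s_h <- simulate_surface(surface_spec(sub_a, sub_b, interaction = "hsa_max"))
  expect_equal(synergy_score(s_h, "hsa")$score, 0)
  # HSA null scored by Bliss is antagonistic-or-zero (max <= independence)
  expect_lte(synergy_score(s_h, "bliss")$score, 0)
  # Bliss null scored by HSA is synergistic-or-zero
  expect_gte(synergy_score(s_b, "hsa")$score, 0)

  # Loewe on a general dose-additive surface with identifiable curves
  ha <- hill_params(0, 0.9, 50, 1.5)
  hb <- hill_params(0, 0.8, 100, 2)
  s_l <- simulate_surface(surface_spec(ha, hb, interaction = "additive_shift"))
  expect_lt(max(abs(synergy_score(s_l, "loewe")$excess)), 0.01)

  # ZIP on the Bliss null with fitted-curve smoothing
  s_z <- simulate_surface(surface_spec(hill_params(0, 1, 100, 1),
                                       hill_params(0, 1, 100, 1),
                                       interaction = "bliss_independent"))
  expect_lt(max(abs(synergy_score(s_z, "zip")$excess)), 1e-3)
})

test_that("Bliss expectation dominates HSA cell-wise on interior responses", {
  set.seed(2)
  for (i in 1:5) {
    ya <- runif(5, 0.05, 0.95)
    yb <- runif(5, 0.05, 0.95)
    bliss <- outer(ya, yb, function(a, b) a + b - a * b)
    hsa <- outer(ya, yb, pmax)
    expect_true(all(bliss >= hsa))
  }
})

test_that("synergy scores are invariant to swapping the two drugs", {
  ha <- hill_params(0, 0.8, 40, 1.4)
  hb <- hill_params(0, 0.6, 400, 0.8)
  s <- simulate_surface(surface_spec(ha, hb, interaction = "bliss_independent",
                                     shift_delta = 0.05))
  s_sw <- dose_response_surface(s$drug_b, s$drug_a, s$doses_b, s$doses_a,
                                s$mono_b, s$mono_a, t(s$combo))
  for (mod in c("hsa", "bliss", "loewe")) {
    expect_equal(synergy_score(s_sw, mod)$score, synergy_score(s, mod)$score,
                 tolerance = 1e-6)
  }
})

test_that("combination ratio compares the combo to the best single agent", {
  s <- dose_response_surface("a", "b", c(1, 10), c(1, 10),
                             mono_a = c(0.5, 0.5), mono_b = c(0.4, 0.4),
                             combo = matrix(0.8, 2, 2))
  cr <- combination_ratio(s)
  expect_true(all(cr$cr == 1.6))
  expect_equal(cr$summary, 1.6)

  s_eq <- dose_response_surface("a", "b", c(1, 10), c(1, 10),
                                mono_a = c(0.5, 0.7), mono_b = c(0.4, 0.6),
                                combo = outer(c(0.5, 0.7), c(0.4, 0.6), pmax))
  expect_true(all(combination_ratio(s_eq)$cr == 1))

  s_low <- dose_response_surface("a", "b", c(1, 10), c(1, 10),
                                 mono_a = c(0.5, 0.5), mono_b = c(0.4, 0.4),
                                 combo = matrix(0.3, 2, 2))
  expect_true(all(combination_ratio(s_low)$cr < 1))

  # zero single agents: cell undefined, excluded, counted
  s_z <- dose_response_surface("a", "b", c(1, 10), c(1, 10),
                               mono_a = c(0, 0.5), mono_b = c(0, 0.4),
                               combo = matrix(0.3, 2, 2))
  cz <- combination_ratio(s_z)
  expect_equal(cz$n_undefined, 1L)
  expect_true(is.na(cz$cr[1, 1]))
  expect_false(anyNA(cz$cr[-1, -1]))
})

test_that("DSS integrates activity above the threshold on the log-dose axis", {
  expect_equal(dss(ladder, rep(0.05, 5)), 0)
  expect_equal(dss(ladder, rep(1, 5)), 100)
  expect_error(dss(1000, 0.5), "2 dose")

  # step response against an independent trapezoid oracle
  resp <- c(0, 0, 1, 1, 1)
  x <- log10(ladder)
  oracle <- 100 * pracma::trapz(x, pmax(resp - 0.1, 0)) /
    ((1 - 0.1) * (max(x) - min(x)))
  expect_equal(dss(ladder, resp), oracle)
})

test_that("surface validation catches inconsistent grids", {
  expect_error(dose_response_surface("a", "b", c(10, 1), c(1, 10),
                                     c(0, 0), c(0, 0), matrix(0, 2, 2)),
               "increasing")
  expect_error(dose_response_surface("a", "b", c(1, 10), c(1, 10),
                                     c(0, 0, 0), c(0, 0), matrix(0, 2, 2)),
               "dimensions")
  expect_error(dose_response_surface("a", "b", c(1, 10), c(1, 10),
                                     c(0, 2), c(0, 0), matrix(0, 2, 2)),
               "\\[0, 1\\]")
})
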