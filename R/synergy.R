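# Synergy reference models (HSA, Bliss, Loewe, ZIP), the combination ratio,
# and a normalized-AUC drug-sensitivity score. All internal computations use
# the inhibition-fraction scale [0, 1]; summary scores are reported x100 on
# the percent scale conventional for these scoring functions.

#' Dose-response combination surface
#'
#' Monotherapy responses of two drugs on their dose ladders plus the full
#' combination response grid.
#'
#' @param drug_a,drug_b drug ids.
#' @param doses_a,doses_b strictly increasing positive dose grids (nM).
#' @param mono_a,mono_b monotherapy response fractions per dose.
#' @param combo matrix of combination response fractions,
#'   `length(doses_a)` x `length(doses_b)` (rows = doses of drug A).
#' @export
dose_response_surface <- function(drug_a, drug_b, doses_a, doses_b,
                                  mono_a, mono_b, combo) {
  if (is.unsorted(doses_a, strictly = TRUE) || any(doses_a <= 0) ||
      is.unsorted(doses_b, strictly = TRUE) || any(doses_b <= 0)) {
    stop("dose grids must be strictly increasing and positive", call. = FALSE)
  }
  combo <- as.matrix(combo)
  if (length(mono_a) != length(doses_a) || length(mono_b) != length(doses_b) ||
      !all(dim(combo) == c(length(doses_a), length(doses_b)))) {
    stop("monotherapy/combination dimensions must match the dose grids",
         call. = FALSE)
  }
  vals <- c(mono_a, mono_b, combo)
  if (any(vals < -1e-9 | vals > 1 + 1e-9)) {
    stop("responses must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
         mono_a = clamp01(as.numeric(mono_a)), mono_b = clamp01(as.numeric(mono_b)),
         combo = matrix(clamp01(combo), nrow(combo), ncol(combo),
                        dimnames = list(doses_a, doses_b))),
    class = "dose_response_surface"
  )
}

#' @export
print.dose_response_surface <- function(x, ...) {
  cat(sprintf("dose_response_surface: %s x %s on a %d x %d dose grid\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b)))
  invisible(x)
}

#' Loewe dose-additive expected response
#'
#' Solves for the response y satisfying the additivity equation
#' x_a / D_a(y) + x_b / D_b(y) = 1, where D(.) is the inverse Hill curve,
#' by bisection on y (tolerance 1e-6 overshot to 1e-9 for safety). When even
#' the largest jointly achievable response leaves the dose sum above 1, y is
#' clamped to `min(e_max_a, e_max_b)` and flagged.
#'
#' @param x_a,x_b doses (>= 0) of the two drugs.
#' @param hill_a,hill_b [hill_params()] of the monotherapy curves.
#' @return list with `y` (expected response fraction) and `clamped` flag.
#' @export
loewe_expected <- function(x_a, x_b, hill_a, hill_b) {
  stopifnot(inherits(hill_a, "hill_params"), inherits(hill_b, "hill_params"))
  if (x_a < 0 || x_b < 0) stop("doses must be >= 0", call. = FALSE)
  if (x_a == 0 && x_b == 0) {
    return(list(y = max(hill_a$e_min, hill_b$e_min), clamped = FALSE))
  }
  if (x_a == 0) return(list(y = hill_response(x_b, hill_b), clamped = FALSE))
  if (x_b == 0) return(list(y = hill_response(x_a, hill_a), clamped = FALSE))
  if (hill_a$e_max - hill_a$e_min < 1e-9 || hill_b$e_max - hill_b$e_min < 1e-9) {
    stop("degenerate Hill curve is not invertible", call. = FALSE)
  }
  lo <- max(hill_a$e_min, hill_b$e_min)
  hi <- min(hill_a$e_max, hill_b$e_max)
  # dose-sum excess, strictly decreasing in y on (lo, hi)
  f <- function(y) x_a / hill_inverse(y, hill_a) + x_b / hill_inverse(y, hill_b) - 1
  eps <- (hi - lo) * 1e-12
  if (f(hi - eps) > 0) return(list(y = hi, clamped = TRUE))
  if (f(lo + eps) < 0) return(list(y = lo, clamped = TRUE))
  a <- lo + eps; b <- hi - eps
  for (i in 1:200) {
    m <- (a + b) / 2
    if (f(m) > 0) a <- m else b <- m
    if (b - a < 1e-9) break
  }
  list(y = (a + b) / 2, clamped = FALSE)
}

#' Expected combination response under a synergy null model
#'
#' HSA expects the better monotherapy effect, `max(y_a, y_b)`; Bliss expects
#' probabilistic independence, `y_a + y_b - y_a y_b`; Loewe expects dose
#' additivity via [loewe_expected()]. Monotherapy responses `y_a`, `y_b` may
#' be supplied directly (observed values) or are evaluated from the Hill
#' fits. ZIP is surface-level (it refits conditional curves) and is handled
#' in [synergy_score()].
#'
#' @param model `"hsa"`, `"bliss"` or `"loewe"`.
#' @param x_a,x_b doses (required for Loewe).
#' @param hill_a,hill_b [hill_params()] (required for Loewe, or to derive
#'   `y_a`/`y_b` when not given).
#' @param y_a,y_b monotherapy response fractions at `x_a`, `x_b`.
#' @return expected response fraction.
#' @export
expected_response <- function(model = c("hsa", "bliss", "loewe"),
                              x_a = NULL, x_b = NULL,
                              hill_a = NULL, hill_b = NULL,
                              y_a = NULL, y_b = NULL) {
  model <- match.arg(model)
  if (model == "loewe") {
    return(loewe_expected(x_a, x_b, hill_a, hill_b)$y)
  }
  if (is.null(y_a)) y_a <- hill_response(x_a, hill_a)
  if (is.null(y_b)) y_b <- hill_response(x_b, hill_b)
  switch(model,
         hsa = pmax(y_a, y_b),
         bliss = y_a + y_b - y_a * y_b)
}

# ZIP delta surface: Bliss-form expectation from the fitted monotherapy
# curves, observed side smoothed by conditional Hill refits in each
# direction, deltas averaged. Falls back to the raw observation for a
# stratum whose refit fails.
.zip_delta <- function(surface, fit_a, fit_b) {
  ya <- hill_response(surface$doses_a, fit_a)
  yb <- hill_response(surface$doses_b, fit_b)
  expected <- outer(ya, yb, function(a, b) a + b - a * b)
  refit <- function(doses, resp) {
    tryCatch(hill_response(doses, fit_hill(doses, resp)),
             error = function(e) resp)
  }
  smooth_a <- surface$combo  # refit along drug-A dose at each fixed drug-B dose
  for (j in seq_along(surface$doses_b)) {
    smooth_a[, j] <- refit(surface$doses_a, surface$combo[, j])
  }
  smooth_b <- surface$combo
  for (i in seq_along(surface$doses_a)) {
    smooth_b[i, ] <- refit(surface$doses_b, surface$combo[i, ])
  }
  (smooth_a + smooth_b) / 2 - expected
}

#' Score a combination surface against a synergy null model
#'
#' Computes the per-cell excess (observed minus expected response, fraction
#' scale) over all combination cells and summarizes it as
#' 100 x mean(excess) on the percent scale. HSA and Bliss expectations use
#' the observed monotherapy responses; Loewe and ZIP use Hill fits of the
#' monotherapy curves (ZIP additionally smooths the observed surface by
#' conditional refits in both directions and averages the two deltas).
#'
#' @param surface a [dose_response_surface].
#' @param model one of `"hsa"`, `"bliss"`, `"loewe"`, `"zip"`.
#' @return A `synergy_result`: list with `model`, `excess` (matrix), `score`
#'   (percent scale), `clamped` (count of clamped Loewe cells), and the Hill
#'   `fits` when used.
#' @export
synergy_score <- function(surface, model = c("hsa", "bliss", "loewe", "zip")) {
  model <- match.arg(model)
  stopifnot(inherits(surface, "dose_response_surface"))
  clamped <- 0L
  fits <- NULL
  if (model %in% c("loewe", "zip")) {
    fits <- list(a = fit_hill(surface$doses_a, surface$mono_a),
                 b = fit_hill(surface$doses_b, surface$mono_b))
  }
  if (model == "zip") {
    excess <- .zip_delta(surface, fits$a, fits$b)
  } else if (model == "loewe") {
    expected <- matrix(NA_real_, length(surface$doses_a), length(surface$doses_b))
    for (i in seq_along(surface$doses_a)) {
      for (j in seq_along(surface$doses_b)) {
        le <- loewe_expected(surface$doses_a[i], surface$doses_b[j],
                             fits$a, fits$b)
        expected[i, j] <- le$y
        if (le$clamped) clamped <- clamped + 1L
      }
    }
    excess <- surface$combo - expected
  } else {
    expected <- outer(surface$mono_a, surface$mono_b, function(a, b) {
      if (model == "hsa") pmax(a, b) else a + b - a * b
    })
    excess <- surface$combo - expected
  }
  structure(
    list(model = model, excess = excess, score = 100 * mean(excess),
         clamped = clamped, fits = fits),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("synergy_result: %s score %.3f (percent scale, mean excess over %d cells)\n",
              toupper(x$model), x$score, length(x$excess)))
  invisible(x)
}

#' Combination ratio (CR)
#'
#' Per dose pair, the combination response divided by the better of the two
#' single-agent responses at the same doses; CR > 1 means the combination
#' beats either single agent. Cells where both single agents have zero
#' response are undefined, excluded from the summary, and counted.
#'
#' @param surface a [dose_response_surface].
#' @return list with `cr` (matrix, NA where undefined), `summary` (mean over
#'   defined cells) and `n_undefined`.
#' @export
combination_ratio <- function(surface) {
  stopifnot(inherits(surface, "dose_response_surface"))
  best <- outer(surface$mono_a, surface$mono_b, pmax)
  cr <- surface$combo / best
  cr[best == 0] <- NA_real_
  list(cr = cr, summary = mean(cr, na.rm = TRUE),
       n_undefined = sum(best == 0))
}

#' Drug sensitivity score (DSS): normalized area above an activity threshold
#'
#' Trapezoidal area of `max(response - t, 0)` over log10 dose, normalized by
#' the maximal achievable area `(1 - t) * log10-dose range`, times 100.
#' A greater DSS indicates higher sensitivity; responses never exceeding the
#' threshold score 0 and a full-response curve scores 100.
#'
#' @param doses positive doses (>= 2 points, increasing).
#' @param responses response fractions in \[0, 1\].
#' @param activity_threshold response floor t below which activity is ignored
#'   (default 0.10).
#' @return score in \[0, 100\].
#' @export
dss <- function(doses, responses, activity_threshold = 0.10) {
  if (length(doses) < 2L) stop("need at least 2 dose points", call. = FALSE)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  t <- check_prob(activity_threshold, "activity_threshold", hi = 1, hi_open = TRUE)
  x <- log10(doses)
  y <- pmax(responses - t, 0)
  100 * trapezoid(x, y) / ((1 - t) * (max(x) - min(x)))
}
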