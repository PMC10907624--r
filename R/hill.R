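# Four-parameter logistic (Hill) dose-response curves: evaluation, inversion,
# and bounded least-squares fitting. These underpin the Loewe and ZIP synergy
# null models.

#' Hill (4-parameter logistic) curve parameters
#'
#' Response fraction as a function of dose x:
#' \deqn{y(x) = e_{min} + (e_{max} - e_{min}) / (1 + (ec50/x)^{slope}).}
#'
#' @param e_min,e_max minimal/maximal response fractions in \[0, 1\],
#'   `e_min <= e_max`.
#' @param ec50 dose of half-maximal effect (> 0).
#' @param slope Hill coefficient (> 0).
#' @export
hill_params <- function(e_min = 0, e_max = 1, ec50 = 100, slope = 1) {
  if (!is.numeric(e_min) || !is.numeric(e_max) || e_min < 0 || e_max > 1 ||
      e_min > e_max) {
    stop_field("e_min/e_max", "need 0 <= e_min <= e_max <= 1")
  }
  if (!is.numeric(ec50) || ec50 <= 0) stop_field("ec50", "must be > 0")
  if (!is.numeric(slope) || slope <= 0) stop_field("slope", "must be > 0")
  structure(list(e_min = as.numeric(e_min), e_max = as.numeric(e_max),
                 ec50 = as.numeric(ec50), slope = as.numeric(slope)),
            class = "hill_params")
}

#' Evaluate a Hill curve
#' @param dose numeric doses (>= 0; dose 0 returns `e_min`).
#' @param par a [hill_params()].
#' @return response fractions in \[e_min, e_max\].
#' @export
hill_response <- function(dose, par) {
  stopifnot(inherits(par, "hill_params"))
  y <- ifelse(dose <= 0, par$e_min,
              par$e_min + (par$e_max - par$e_min) /
                (1 + (par$ec50 / dose)^par$slope))
  as.numeric(y)
}

#' Invert a Hill curve: dose producing a given response
#'
#' @param y response fraction strictly inside (e_min, e_max).
#' @param par a [hill_params()].
#' @return the dose D(y); 0 for y <= e_min, Inf for y >= e_max.
#' @export
hill_inverse <- function(y, par) {
  stopifnot(inherits(par, "hill_params"))
  ifelse(y <= par$e_min, 0,
         ifelse(y >= par$e_max, Inf,
                par$ec50 * ((y - par$e_min) / (par$e_max - y))^(1 / par$slope)))
}

#' Fit a Hill curve to monotherapy dose-response points
#'
#' Bounded least squares via Levenberg-Marquardt ([minpack.lm::nlsLM]) with a
#' box-constrained `optim` fallback. Parameters are constrained to
#' `e_min, e_max` in \[0, 1\], `ec50` within two decades of the dose range and
#' `slope` in \[0.1, 10\].
#'
#' @param doses positive doses (>= 4 points).
#' @param responses response fractions in \[0, 1\].
#' @return A [hill_params()] with attributes `rmse` (root-mean-square
#'   residual) and `degenerate` (TRUE when the fitted dynamic range
#'   `e_max - e_min` is below 0.01, e.g. on constant responses).
#' @export
fit_hill <- function(doses, responses) {
  if (length(doses) < 4L) stop("need at least 4 dose points", call. = FALSE)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(responses < -1e-9) || any(responses > 1 + 1e-9)) {
    stop("responses must lie in [0, 1]", call. = FALSE)
  }
  responses <- clamp01(responses)
  lower <- c(e_min = 0, e_max = 0, ec50 = min(doses) / 100, slope = 0.1)
  upper <- c(e_min = 1, e_max = 1, ec50 = max(doses) * 100, slope = 10)
  # heuristic start: midpoint-crossing dose, unit slope
  r_lo <- min(responses); r_hi <- max(responses)
  mid <- (r_lo + r_hi) / 2
  ec50_0 <- if (r_hi > r_lo) {
    stats::approx(responses, doses, xout = mid, ties = mean)$y
  } else NA
  if (!is.finite(ec50_0) || ec50_0 <= 0) ec50_0 <- exp(mean(log(range(doses))))
  start <- list(e_min = r_lo, e_max = r_hi, ec50 = ec50_0, slope = 1)

  fit <- tryCatch({
    m <- minpack.lm::nlsLM(
      responses ~ e_min + (e_max - e_min) / (1 + (ec50 / doses)^slope),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    as.list(stats::coef(m))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) {
      yh <- p[1] + (p[2] - p[1]) / (1 + (p[3] / doses)^p[4])
      sum((responses - yh)^2)
    }
    o <- stats::optim(unlist(start), obj, method = "L-BFGS-B",
                      lower = lower, upper = upper)
    fit <- as.list(stats::setNames(o$par, names(lower)))
  }
  if (fit$e_min > fit$e_max) fit[c("e_min", "e_max")] <- fit[c("e_max", "e_min")]
  par <- hill_params(fit$e_min, fit$e_max, fit$ec50, fit$slope)
  res <- responses - hill_response(doses, par)
  attr(par, "rmse") <- sqrt(mean(res^2))
  attr(par, "degenerate") <- (par$e_max - par$e_min) < 0.01
  par
}
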