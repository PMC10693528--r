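#' Three-parameter Weibull (W1.3) dose-response value
#'
#' The W1.3 model describes ATP-based viability as a function of
#' concentration with the lower asymptote fixed at zero:
#' \deqn{f(x) = d \, \exp(-\exp(b (\ln x - \ln e)))}
#' where `d` is the upper asymptote (untreated viability, percent), `e`
#' the scale concentration (uM) at which the response has fallen to
#' `d/exp(1)`, and `b` the slope. For `b > 0` the curve decreases
#' monotonically from `d` to 0.
#'
#' @param x Concentration(s), uM; strictly positive.
#' @param fit A `w13_fit` object or a list with elements `b`, `d`, `e`.
#' @return Predicted viability (same units as `d`).
#' @export
w13_response <- function(x, fit) {
  if (any(!is.finite(x)) || any(x <= 0)) stop("concentration x must be positive")
  fit$d * exp(-exp(fit$b * (log(x) - log(fit$e))))
}

#' Construct a W1.3 fit object
#'
#' @param b Slope parameter.
#' @param d Upper asymptote (> 0).
#' @param e Scale concentration (> 0).
#' @param residual_sse Residual sum of squares (default `NA`).
#' @param converged Logical convergence flag.
#' @return Object of class `w13_fit`.
#' @export
w13_fit <- function(b, d, e, residual_sse = NA_real_, converged = TRUE) {
  if (!is.finite(d) || d <= 0) stop("d must be positive")
  if (!is.finite(e) || e <= 0) stop("e must be positive")
  structure(
    list(b = b, d = d, e = e, residual_sse = residual_sse, converged = converged),
    class = "w13_fit"
  )
}

#' @export
print.w13_fit <- function(x, ...) {
  cat(sprintf(
    "W1.3 fit: b = %.4g, d = %.4g, e = %.4g (converged: %s, SSE = %.4g)\n",
    x$b, x$d, x$e, x$converged, x$residual_sse
  ))
  invisible(x)
}

# Self-start heuristic: d from the top of the curve, e from the dose whose
# mean response is nearest d/2, b from a complementary log-log regression
# of response/d on log dose.
w13_start <- function(dose, viability) {
  means <- tapply(viability, dose, mean)
  doses <- as.numeric(names(means))
  d0 <- max(means)
  e0 <- doses[which.min(abs(means - 0.5 * d0))]
  frac <- pmin(pmax(as.numeric(means) / (d0 * 1.001), 1e-3), 1 - 1e-3)
  cll <- log(-log(frac))
  fit <- stats::lm(cll ~ log(doses))
  b0 <- unname(stats::coef(fit)[2])
  if (!is.finite(b0) || abs(b0) < 1e-6) b0 <- 1
  # refine e from the cloglog intercept: cll = b(log x - log e)
  e_alt <- exp(-unname(stats::coef(fit)[1]) / b0)
  if (is.finite(e_alt) && e_alt > min(doses) / 100 && e_alt < max(doses) * 100) e0 <- e_alt
  list(b = b0, d = d0, e = e0)
}

#' Fit the W1.3 model to range-finder viability data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of percent viability on
#' concentration under the W1.3 model. Requires at least four distinct
#' positive doses and non-constant responses.
#'
#' @param dose Concentrations (uM), positive.
#' @param viability Responses (percent of vehicle control).
#' @param init Optional list with starting values `b`, `d`, `e`; a
#'   self-start heuristic is used when absent.
#' @return A [w13_fit()] object with `residual_sse` and an honest
#'   `converged` flag.
#' @export
fit_w13 <- function(dose, viability, init = NULL) {
  keep <- is.finite(dose) & is.finite(viability)
  dose <- dose[keep]; viability <- viability[keep]
  if (any(dose <= 0)) stop("doses must be positive")
  if (length(unique(dose)) < 4) stop("need at least 4 distinct doses to fit W1.3")
  if (stats::sd(viability) == 0) stop("responses are constant; W1.3 fit is undefined")
  start <- if (is.null(init)) w13_start(dose, viability) else init
  df <- data.frame(x = dose, y = viability)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ d * exp(-exp(b * (log(x) - log(e)))),
      data = df,
      start = list(b = start$b, d = start$d, e = start$e),
      lower = c(b = -Inf, d = 1e-8, e = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("W1.3 fit failed: ", conditionMessage(e))
  )
  est <- stats::coef(fit)
  conv <- isTRUE(fit$convInfo$isConv)
  w13_fit(
    b = unname(est["b"]), d = unname(est["d"]), e = unname(est["e"]),
    residual_sse = sum(stats::resid(fit)^2), converged = conv
  )
}

#' Effective concentration from a W1.3 fit
#'
#' Closed-form inversion of the W1.3 curve: the concentration at which
#' the response has dropped by `p` percent of the upper asymptote,
#' \deqn{EC_p = e \, \exp(\ln(-\ln(1 - p/100)) / b).}
#' At `p = 100 (1 - 1/e)` (about 63.212) this equals the scale parameter
#' exactly.
#'
#' @param fit A [w13_fit()] object with `b != 0`.
#' @param p Percent effect level(s) in (0, 100).
#' @return Concentration(s), uM.
#' @export
ec_from_fit <- function(fit, p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100)) {
    stop("p must lie strictly between 0 and 100")
  }
  if (!isTRUE(fit$converged)) stop("fit did not converge; refusing to extract ECs")
  if (fit$b == 0) stop("b = 0: EC undefined")
  fit$e * exp(log(-log(1 - p / 100)) / fit$b)
}

#' Effective-concentration set for metabolome dose selection
#'
#' Computes the five effective concentrations used to span the
#' dose-response range in the metabolome experiments (EC1 and EC5 for
#' mild effects, EC15 for a robust but low-cytotoxicity effect, EC50 and
#' EC85 for cytotoxicity-related patterns), plus their integer-rounded
#' values used as the actual dose grid.
#'
#' @param fit A [w13_fit()] object.
#' @param p Effect percentages (default `c(1, 5, 15, 50, 85)`).
#' @return List with `ec` (named numeric) and `rounded` (named integer).
#' @export
ec_set <- function(fit, p = c(1, 5, 15, 50, 85)) {
  ec <- ec_from_fit(fit, p)
  names(ec) <- paste0("EC", p)
  list(ec = ec, rounded = round_half_up(ec))
}

# round half away from zero (the everyday "nearest integer" convention,
# unlike base round()'s round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' Select the rounded test-concentration grid
#'
#' Rounds the five effective concentrations to the nearest integer
#' (half-up) for dosing. If rounding collapses two ECs onto the same
#' integer the grid is ambiguous and an error asks for a manual dose
#' grid.
#'
#' @param ecset Result of [ec_set()], or a named numeric vector of ECs.
#' @return Named integer vector of 5 doses, strictly increasing.
#' @export
select_test_concentrations <- function(ecset) {
  ec <- if (is.list(ecset)) ecset$ec else ecset
  rounded <- round_half_up(ec)
  if (anyDuplicated(rounded)) {
    stop(
      "rounded doses collide (", paste(rounded, collapse = ", "),
      "); choose a manual dose grid"
    )
  }
  if (is.unsorted(rounded, strictly = TRUE)) {
    stop("rounded doses are not strictly increasing")
  }
  rounded
}

#' Select the mode-of-action analysis concentration
#'
#' Applies the dose-selection rule for MoA profiling: among the five
#' tested levels, take the highest whose mean ATP viability is still at
#' least `threshold` percent of the vehicle control (i.e. the ATP level
#' decreased by less than 100 - threshold percent). This picks a
#' concentration strong enough to perturb the metabolome but below overt
#' cytotoxicity.
#'
#' @param viability_means Five mean viability percentages, ordered C1-C5.
#' @param threshold Minimum acceptable viability (default 80).
#' @return Level index in 1-5.
#' @export
select_moa_concentration <- function(viability_means, threshold = 80) {
  if (length(viability_means) != 5 || any(!is.finite(viability_means))) {
    stop("viability_means must be 5 finite values ordered C1..C5")
  }
  ok <- which(viability_means >= threshold)
  if (length(ok) == 0) {
    stop("no concentration level keeps viability >= ", threshold, "%")
  }
  max(ok)
}

#' Fit W1.3 curves for every substance in a viability table
#'
#' @param viability Long viability tibble
#'   (`substance_id`, `concentration_uM`, `replicate`, `viability_pct`).
#' @param p Effect percentages for the EC set.
#' @return Tibble with one row per substance: fit parameters, SSE,
#'   convergence, ECs and the rounded dose grid (as list-columns `ec`,
#'   `rounded`).
#' @export
fit_viability_table <- function(viability, p = c(1, 5, 15, 50, 85)) {
  out <- lapply(split(viability, viability$substance_id), function(v) {
    fit <- fit_w13(v$concentration_uM, v$viability_pct)
    ecs <- ec_set(fit, p)
    tibble::tibble(
      substance_id = v$substance_id[1],
      b = fit$b, d = fit$d, e = fit$e,
      residual_sse = fit$residual_sse, converged = fit$converged,
      ec = list(ecs$ec), rounded = list(ecs$rounded)
    )
  })
  dplyr::bind_rows(out)
}
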