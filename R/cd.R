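R_GAS <- 8.314e-3  # kJ mol^-1 K^-1

#' Two-state unfolding parameters
#'
#' Parameter container for the Gibbs-Helmholtz description of two-state
#' thermal unfolding followed by CD at 222 nm.  `dG(T) = dh * (1 - T/tm)
#' + dcp * (T - tm - T * log(T/tm))`; the observed signal is the
#' population-weighted mix of two linear baselines.
#'
#' @param tm Melting temperature in kelvin.
#' @param dh van 't Hoff enthalpy of unfolding at `tm`, kJ/mol (positive
#'   for cooperative unfolding).
#' @param dcp Heat-capacity change, kJ/mol/K (default 0).
#' @param native_baseline,unfolded_baseline `(intercept, slope)` of the
#'   linear baselines (signal units, signal units per K).
#' @return A `two_state_params` list.
#' @export
two_state_params <- function(tm, dh, dcp = 0,
                             native_baseline = c(-25, 0.02),
                             unfolded_baseline = c(-4, 0.01)) {
  stopifnot(tm > 0, length(native_baseline) == 2,
            length(unfolded_baseline) == 2)
  structure(list(tm = tm, dh = dh, dcp = dcp,
                 native_baseline = native_baseline,
                 unfolded_baseline = unfolded_baseline),
            class = "two_state_params")
}

#' Fraction unfolded at temperature T
#'
#' Gibbs-Helmholtz two-state population: `K = exp(-dG/(R T))`,
#' `f = K / (1 + K)`, with `R = 8.314e-3` kJ/mol/K.  At `T = tm` the
#' free energy vanishes and `f = 0.5` exactly, for any `dh` and `dcp`.
#'
#' @param temperature Temperature(s) in kelvin, `> 0`.
#' @param params A [two_state_params()] object.
#' @return Fraction unfolded in `[0, 1]`, vectorised over `temperature`.
#' @export
fraction_unfolded <- function(temperature, params) {
  stopifnot(all(temperature > 0))
  dg <- params$dh * (1 - temperature / params$tm) +
    params$dcp * (temperature - params$tm -
                    temperature * log(temperature / params$tm))
  stats::plogis(-dg / (R_GAS * temperature))
}

two_state_signal <- function(temperature, params) {
  f <- fraction_unfolded(temperature, params)
  nb <- params$native_baseline; ub <- params$unfolded_baseline
  (1 - f) * (nb[1] + nb[2] * temperature) +
    f * (ub[1] + ub[2] * temperature)
}

#' Simulate a CD melt (or refold) curve
#'
#' Ellipticity at 222 nm on a temperature grid, as the two-state signal
#' plus i.i.d. Gaussian noise.  The default grid matches 2 K steps over
#' 5--95 C (278--368 K, 46 points).  Refold hysteresis is phenomenological:
#' the refold branch is generated at an apparent `tm` shifted by
#' `refold_shift` (a negative shift lowers the apparent melting point on
#' refolding, as seen for the zinc-bound wild type).
#'
#' @param params A [two_state_params()] object.
#' @param temperature Temperature grid in kelvin.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed Optional integer seed.
#' @param direction `"melt"` or `"refold"`.
#' @param refold_shift Apparent-tm shift (K) applied when
#'   `direction = "refold"` (default 0: reversible two-state limit).
#' @return A `melt_curve` data frame: `temperature`, `ellipticity`,
#'   `direction`.
#' @export
simulate_melt <- function(params, temperature = seq(278, 368, by = 2),
                          noise_sd = 0, seed = NULL,
                          direction = c("melt", "refold"),
                          refold_shift = 0) {
  direction <- match.arg(direction)
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (direction == "refold" && refold_shift != 0)
    p$tm <- p$tm + refold_shift
  sig <- two_state_signal(temperature, p)
  if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
  melt_curve(temperature, sig, direction)
}

#' @rdname simulate_melt
#' @param ellipticity Signal values for an existing curve.
#' @export
melt_curve <- function(temperature, ellipticity,
                       direction = c("melt", "refold")) {
  direction <- match.arg(direction)
  stopifnot(length(temperature) == length(ellipticity))
  if (length(temperature) < 10)
    stop("a melt curve needs at least 10 points")
  if (any(temperature < 270 | temperature > 380))
    stop("temperatures must be in kelvin within [270, 380]")
  if (is.unsorted(temperature)) stop("temperature must be monotone increasing")
  structure(data.frame(temperature = temperature, ellipticity = ellipticity,
                       direction = direction),
            class = c("melt_curve", "data.frame"))
}

#' Fit the two-state unfolding model to a melt curve
#'
#' Nonlinear least squares over six parameters (tm, dh and the two
#' linear baselines), with `dcp` fixed (default 0).  Starting values:
#' `tm` at the temperature where the signal crosses the midpoint of its
#' range, `dh = 300` kJ/mol, baselines from straight-line fits to the
#' five lowest- and highest-temperature points.  Non-convergence is
#' flagged, never silent.
#'
#' @param curve A `melt_curve`.
#' @param dcp Fixed heat-capacity change (kJ/mol/K, default 0).
#' @param dh_start Starting enthalpy (kJ/mol).
#' @return A `two_state_fit` list: `params` ([two_state_params()]),
#'   `rmse`, `converged`, and the underlying `nls` fit (or `NULL`).
#' @export
fit_melt <- function(curve, dcp = 0, dh_start = 300) {
  stopifnot(inherits(curve, "melt_curve"))
  Tk <- curve$temperature; y <- curve$ellipticity
  n <- length(Tk)
  lo <- stats::lm(y[1:5] ~ Tk[1:5])$coefficients
  hi <- stats::lm(y[(n - 4):n] ~ Tk[(n - 4):n])$coefficients
  mid <- (min(y) + max(y)) / 2
  tm0 <- Tk[which.min(abs(y - mid))]
  model_fun <- function(tm, dh, an, bn, au, bu) {
    two_state_signal(Tk, two_state_params(tm, dh, dcp, c(an, bn), c(au, bu)))
  }
  try_fit <- function(tm0, dh0) tryCatch(
    stats::nls(y ~ model_fun(tm, dh, an, bn, au, bu),
               start = list(tm = tm0, dh = dh0,
                            an = lo[[1]], bn = lo[[2]],
                            au = hi[[1]], bu = hi[[2]]),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port",
               lower = c(tm = min(Tk) - 20, dh = 1,
                         an = -Inf, bn = -Inf, au = -Inf, bu = -Inf),
               upper = c(tm = max(Tk) + 20, dh = 5000,
                         an = Inf, bn = Inf, au = Inf, bu = Inf)),
    error = function(e) e)
  # retry from perturbed starts if the first attempt fails
  starts <- list(c(tm0, dh_start), c(tm0 + 2, dh_start / 2),
                 c(tm0 - 2, dh_start * 2), c(tm0, dh_start / 4))
  fit <- NULL
  for (s in starts) {
    fit <- try_fit(s[1], s[2])
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) {
    return(structure(list(params = NULL, rmse = NA_real_, converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "two_state_fit"))
  }
  cf <- stats::coef(fit)
  params <- two_state_params(cf[["tm"]], cf[["dh"]], dcp,
                             c(cf[["an"]], cf[["bn"]]),
                             c(cf[["au"]], cf[["bu"]]))
  structure(list(params = params,
                 rmse = sqrt(mean(stats::residuals(fit)^2)),
                 converged = fit$convInfo$isConv, fit = fit),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (!x$converged && is.null(x$params)) {
    cat("Two-state fit FAILED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Two-state fit: Tm = %.2f K, dH = %.0f kJ/mol (rmse %.3g%s)\n",
              x$params$tm, x$params$dh, x$rmse,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Area between melt and refold curves (hysteresis)
#'
#' Integrates `|melt - refold|` over the common temperature range after
#' linear interpolation onto a shared grid (trapezoidal rule).  Zero for
#' a reversible transition; grows with the apparent-tm shift of the
#' refold branch.
#'
#' @param melt,refold `melt_curve`s with overlapping temperature ranges.
#' @param n_grid Number of points of the shared grid (default 200).
#' @return Area in signal-units times kelvin (non-negative, symmetric in
#'   its arguments).
#' @export
hysteresis_area <- function(melt, refold, n_grid = 200) {
  stopifnot(inherits(melt, "melt_curve"), inherits(refold, "melt_curve"))
  lo <- max(min(melt$temperature), min(refold$temperature))
  hi <- min(max(melt$temperature), max(refold$temperature))
  if (lo >= hi) stop("melt and refold temperature ranges do not overlap")
  grid <- seq(lo, hi, length.out = n_grid)
  m <- stats::approx(melt$temperature, melt$ellipticity, grid)$y
  r <- stats::approx(refold$temperature, refold$ellipticity, grid)$y
  d <- abs(m - r)
  sum((d[-1] + d[-n_grid]) / 2 * diff(grid))
}

#' Read/write 2-column CD melt files (T_K, ellipticity[, direction])
#'
#' CSV with header; the optional third column holds the direction flag.
#' @param path File path.
#' @param curve A `melt_curve` (for writing).
#' @export
read_melt <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("expected at least 2 columns in ", path)
  dir <- if ("direction" %in% names(tab)) as.character(tab$direction[1])
         else "melt"
  melt_curve(tab[[1]], tab[[2]], direction = dir)
}

#' @rdname read_melt
#' @export
write_melt <- function(curve, path) {
  stopifnot(inherits(curve, "melt_curve"))
  df <- data.frame(temperature_K = sprintf("%.2f", curve$temperature),
                   ellipticity = sprintf("%.6f", curve$ellipticity),
                   direction = curve$direction)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
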