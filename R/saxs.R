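#' Scattering-curve container
#'
#' @param q Momentum transfer in 1/Angstrom, strictly increasing, `q >= 0`.
#' @param intensity Scattered intensity (arbitrary units).
#' @param sigma Optional per-point uncertainties (positive).
#' @return A `scattering_curve` data frame with columns `q`, `intensity`
#'   and (optionally) `sigma`.
#' @export
scattering_curve <- function(q, intensity, sigma = NULL) {
  stopifnot(length(q) == length(intensity), q[1] >= 0)
  if (is.unsorted(q, strictly = TRUE)) stop("q must be strictly increasing")
  df <- data.frame(q = q, intensity = intensity)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q))
    df$sigma <- sigma
  }
  class(df) <- c("scattering_curve", "data.frame")
  df
}

#' Default q grid for theoretical curves: 0.005 to 0.35 1/A, 256 points
#' @export
default_q_grid <- function() seq(0.005, 0.35, length.out = 256)

#' Theoretical scattering by the Debye formula
#'
#' Computes the orientation-averaged scattering intensity of the model's
#' point scatterers in vacuum, I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)
#' with the sinc limit 1 at q r = 0.  This is an exact stand-in for
#' solvent-corrected predictors (CRYSOL): absolute intensity is never
#' interpreted downstream, only curve shape.
#'
#' @param model A model object, or a numeric matrix of coordinates.
#' @param q q grid (1/Angstrom); default [default_q_grid()].
#' @param weights `"unit"` (default) for equal point scatterers or a
#'   numeric vector of per-point form factors.
#' @return A `scattering_curve` (no sigma).
#' @export
debye_scattering <- function(model, q = default_q_grid(), weights = "unit") {
  pts <- if (is.matrix(model)) model else model_coords(model)
  n <- nrow(pts)
  if (is.null(n) || n < 1) stop("model has no scattering points")
  f <- if (identical(weights, "unit")) rep(1, n) else {
    stopifnot(is.numeric(weights), length(weights) == n)
    weights
  }
  d <- as.vector(stats::dist(pts))
  ij <- pair_weights(f)
  self_term <- sum(f^2)
  intensity <- vapply(q, function(qq) {
    if (qq == 0) return(self_term + 2 * sum(ij))
    x <- qq * d
    self_term + 2 * sum(ij * sin(x) / x)
  }, 0)
  scattering_curve(q, intensity)
}

# f_i f_j for all i < j pairs, in dist() ordering
pair_weights <- function(f) {
  n <- length(f)
  if (n < 2) return(numeric(0))
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(2:n, function(k) k:n))
  f[i] * f[j]
}

#' Guinier fit for the radius of gyration
#'
#' Linear fit of ln I versus q^2 over the largest low-q window whose
#' upper limit satisfies `qmax * Rg <= guinier_limit`, enforced
#' iteratively from an initial window.  `Rg = sqrt(-3 * slope)`.
#'
#' @param curve A `scattering_curve`.
#' @param guinier_limit Upper validity bound on `qmax * Rg` (default 1.3).
#' @param min_points Minimum window size (default 5).
#' @return A `guinier_fit` list: `rg`, `i0`, `q_window`, `r_squared`,
#'   `n_points`.
#' @export
guinier_fit <- function(curve, guinier_limit = 1.3, min_points = 5) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q; I <- curve$intensity
  hi <- length(q)
  repeat {
    if (hi < min_points) stop("no valid Guinier window with >= ",
                              min_points, " points")
    qw <- q[1:hi]; Iw <- I[1:hi]
    if (any(Iw <= 0)) stop("non-positive intensities in the Guinier window")
    fit <- stats::lm(log(Iw) ~ I(qw^2))
    slope <- stats::coef(fit)[[2]]
    if (slope >= 0) { hi <- hi - 1; next }
    rg <- sqrt(-3 * slope)
    if (q[hi] * rg <= guinier_limit) {
      r2 <- suppressWarnings(summary(fit)$r.squared)
      return(structure(list(rg = rg, i0 = exp(stats::coef(fit)[[1]]),
                            q_window = c(q[1], q[hi]), r_squared = r2,
                            n_points = hi),
                       class = "guinier_fit"))
    }
    # shrink to the largest window consistent with the current estimate
    hi_new <- max(which(q * rg <= guinier_limit))
    hi <- if (hi_new < hi) hi_new else hi - 1
  }
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I(0) = %.4g, q in [%.4f, %.4f] (%d pts, R2 = %.4f)\n",
              x$rg, x$i0, x$q_window[1], x$q_window[2], x$n_points,
              x$r_squared))
  invisible(x)
}

#' Cross-sectional Guinier fit for elongated particles
#'
#' For a long rod-like particle, ln(q I) versus q^2 is linear over an
#' intermediate-q window and yields the cross-sectional radius of
#' gyration `Rc = sqrt(-2 * slope)`.  The window is chosen automatically
#' (the paper-style "rod Guinier" region is not universal): among sliding
#' windows starting above the full-particle Guinier region, the fit with
#' the highest R-squared and a negative slope is kept, then the upper
#' limit is shrunk until `qmax * Rc <= limit`.
#'
#' @param curve A `scattering_curve`.
#' @param q_min Lower bound of candidate windows; default `1.5 / Rg`
#'   using the overall Guinier Rg, falling back to 0.03 if that fit fails.
#' @param window Number of points per candidate window (default 20).
#' @param limit Upper validity bound on `qmax * Rc` (default 1.3).
#' @return A `cross_section_fit` list: `rc`, `q_window`, `r_squared`.
#' @export
cross_section_fit <- function(curve, q_min = NULL, window = 20, limit = 1.3) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q; I <- curve$intensity
  if (is.null(q_min)) {
    rg <- tryCatch(guinier_fit(curve)$rg, error = function(e) NA)
    q_min <- if (is.na(rg)) 0.03 else 1.5 / rg
  }
  start_idx <- which(q >= q_min & q > 0)
  if (length(start_idx) < window)
    stop("cross-section window undefined: curve does not extend beyond ",
         "the full-particle Guinier region (q_min = ", signif(q_min, 3), ")")
  best <- flattest <- NULL
  for (s in start_idx[seq_len(length(start_idx) - window + 1)]) {
    sel <- s:(s + window - 1)
    y <- q[sel] * I[sel]
    if (any(y <= 0)) next
    fit <- stats::lm(log(y) ~ I(q[sel]^2))
    slope <- stats::coef(fit)[[2]]
    r2 <- suppressWarnings(summary(fit)$r.squared)
    rc <- sqrt(max(0, -2 * slope))
    valid <- slope < 0 && q[sel[length(sel)]] * rc <= limit
    if (valid && (is.null(best) || r2 > best$r2))
      best <- list(sel = sel, slope = slope, r2 = r2)
    if (is.null(flattest) || abs(slope) < abs(flattest$slope))
      flattest <- list(sel = sel, slope = slope, r2 = r2)
  }
  if (is.null(best)) {
    # thin-rod limit: ln(qI) essentially flat, Rc indistinguishable
    # from zero at the grid resolution
    if (!is.null(flattest) && abs(flattest$slope) < 0.5 / 2)
      return(structure(list(rc = sqrt(max(0, -2 * flattest$slope)),
                            q_window = c(q[flattest$sel[1]],
                                         q[flattest$sel[length(flattest$sel)]]),
                            r_squared = flattest$r2),
                       class = "cross_section_fit"))
    stop("cross-section fit failed: no valid window with a negative slope ",
         "(particle may be globular)")
  }
  sel <- best$sel
  repeat {
    y <- q[sel] * I[sel]
    fit <- stats::lm(log(y) ~ I(q[sel]^2))
    slope <- stats::coef(fit)[[2]]
    rc <- sqrt(max(0, -2 * slope))
    if (rc == 0 || q[sel[length(sel)]] * rc <= limit || length(sel) <= 5)
      return(structure(list(rc = rc,
                            q_window = c(q[sel[1]], q[sel[length(sel)]]),
                            r_squared = suppressWarnings(summary(fit)$r.squared)),
                       class = "cross_section_fit"))
    sel <- sel[-length(sel)]
  }
}

#' @export
print.cross_section_fit <- function(x, ...) {
  cat(sprintf("Cross-section fit: Rc = %.2f A, q in [%.4f, %.4f] (R2 = %.4f)\n",
              x$rc, x$q_window[1], x$q_window[2], x$r_squared))
  invisible(x)
}

#' Pair-distance distribution from model coordinates
#'
#' Histogram of all pairwise inter-point distances, weighted by the
#' product of point form factors; `dmax` is the exact largest pairwise
#' distance (not a bin edge).
#'
#' @param model Model object or coordinate matrix.
#' @param bin_width Histogram bin width in Angstrom (default 1).
#' @param weights As in [debye_scattering()].
#' @return A `pair_distribution` list: `r` (bin centres), `density`
#'   (normalised to unit sum), `counts` (weighted), `dmax`.
#' @export
pr_from_model <- function(model, bin_width = 1, weights = "unit") {
  stopifnot(bin_width > 0)
  pts <- if (is.matrix(model)) model else model_coords(model)
  if (is.null(nrow(pts)) || nrow(pts) < 2)
    stop("model needs at least two points for a pair distribution")
  f <- if (identical(weights, "unit")) rep(1, nrow(pts)) else weights
  d <- as.vector(stats::dist(pts))
  w <- pair_weights(f)
  dmax <- max(d)
  edges <- seq(0, dmax + bin_width, by = bin_width)
  bins <- findInterval(d, edges, rightmost.closed = TRUE)
  counts <- vapply(seq_len(length(edges) - 1),
                   function(b) sum(w[bins == b]), 0)
  structure(
    list(r = edges[-length(edges)] + bin_width / 2,
         density = counts / sum(counts), counts = counts, dmax = dmax),
    class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("P(r): %d bins, Dmax = %.1f A\n", length(x$r), x$dmax))
  invisible(x)
}

#' Reduced chi-square between a model curve and a data curve
#'
#' The model intensity is interpolated onto the data q grid, scaled by
#' the analytically optimal scalar, and the reduced chi-square computed
#' against the data uncertainties: all shape parameters are invariant
#' under rescaling either curve.
#'
#' @param model_curve,data_curve `scattering_curve`s; `data_curve` must
#'   carry positive `sigma`.
#' @return A `chi_square_result` list: `chi2`, `scale`, `n_points`.
#' @export
chi_square <- function(model_curve, data_curve) {
  stopifnot(inherits(model_curve, "scattering_curve"),
            inherits(data_curve, "scattering_curve"))
  if (is.null(data_curve$sigma)) stop("data curve lacks sigma")
  if (any(data_curve$sigma <= 0)) stop("data sigma must be positive")
  m <- stats::approx(model_curve$q, model_curve$intensity,
                     xout = data_curve$q, rule = 2)$y
  d <- data_curve$intensity
  s2 <- data_curve$sigma^2
  scale <- sum(m * d / s2) / sum(m^2 / s2)
  n <- length(d)
  chi2 <- sum((scale * m - d)^2 / s2) / max(1, n - 1)
  structure(list(chi2 = chi2, scale = scale, n_points = n),
            class = "chi_square_result")
}

#' Add counting-like noise to a theoretical curve
#'
#' Multiplicative Gaussian noise whose relative width grows linearly in
#' q, sigma(q) = I(q) * (a + b * q / qmax), mimicking photon-counting
#' statistics worsening at high angle.  The returned curve carries the
#' true sigma used.
#'
#' @param curve A `scattering_curve`.
#' @param a,b Relative-noise coefficients (defaults 0.01, 0.04).
#' @param seed Optional integer seed for reproducibility.
#' @return A `scattering_curve` with noisy intensity and `sigma`.
#' @export
simulate_saxs_noise <- function(curve, a = 0.01, b = 0.04, seed = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (!is.null(seed)) set.seed(seed)
  sig <- curve$intensity * (a + b * curve$q / max(curve$q))
  scattering_curve(curve$q,
                   curve$intensity + stats::rnorm(length(sig), 0, sig),
                   sigma = sig)
}

#' Infer the hinge angle from a scattering curve by grid search
#'
#' Deterministic rigid-body stand-in for SAXS-directed flexible
#' modelling: for each candidate interdomain angle a hinged ideal dimer
#' is built with the standard rigid-domain partition (everything
#' N-terminal of the pivot fixed, everything C-terminal rotated as one
#' body), its Debye curve is computed on the data grid, and the reduced
#' chi-square against the data recorded.  The best angle is the arg-min
#' of the profile.
#'
#' @param data_curve A `scattering_curve` with `sigma`.
#' @param angle_grid Candidate interdomain angles in degrees, each in
#'   (60, 180].
#' @param first_residue,last_residue Model range (default 31--145).
#' @param pivot_residue Hinge pivot (default 91, the C89xxC92 midpoint).
#' @param params Crick parameters for the builder.
#' @param include_sidechains Passed to [build_ideal_dimer()].
#' @return A `hinge_fit_result` list: `best_angle_deg`, `chi2_profile`
#'   (data frame of angle and chi2), `best_chi2`.
#' @export
fit_hinge_angle <- function(data_curve, angle_grid = seq(90, 180, by = 5),
                            first_residue = 31, last_residue = 145,
                            pivot_residue = 91,
                            params = crick_parameters(),
                            include_sidechains = FALSE) {
  if (length(angle_grid) == 0) stop("angle_grid is empty")
  if (any(angle_grid <= 60 | angle_grid > 180))
    stop("angle_grid values must lie in (60, 180]")
  straight <- build_ideal_dimer(first_residue, last_residue, params,
                                include_sidechains = include_sidechains)
  chi2 <- vapply(angle_grid, function(a) {
    m <- if (a >= 180) straight else
      insert_hinge(straight, pivot_residue, a)
    mc <- debye_scattering(m, q = data_curve$q)
    chi_square(mc, data_curve)$chi2
  }, 0)
  best <- which.min(chi2)
  structure(
    list(best_angle_deg = angle_grid[best],
         best_chi2 = chi2[best],
         chi2_profile = data.frame(angle_deg = angle_grid, chi2 = chi2)),
    class = "hinge_fit_result")
}

#' @export
print.hinge_fit_result <- function(x, ...) {
  cat(sprintf("Hinge-angle grid search: best angle %.1f deg (chi2 = %.3f) over %d angles\n",
              x$best_angle_deg, x$best_chi2, nrow(x$chi2_profile)))
  invisible(x)
}

#' Read/write 3-column scattering text files (q, I, sigma)
#'
#' Whitespace-delimited text with an optional `#` header; sigma column
#' optional on read.
#' @param path File path.
#' @param curve A `scattering_curve` (for writing).
#' @return [read_saxs()] returns a `scattering_curve`; [write_saxs()]
#'   returns `path` invisibly.
#' @export
read_saxs <- function(path) {
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2) stop("expected at least 2 columns (q, I) in ", path)
  scattering_curve(tab[[1]], tab[[2]],
                   sigma = if (ncol(tab) >= 3) tab[[3]] else NULL)
}

#' @rdname read_saxs
#' @export
write_saxs <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  sig <- if (is.null(curve$sigma)) rep(0, nrow(curve)) else curve$sigma
  lines <- sprintf("%.6f %.8e %.8e", curve$q, curve$intensity, sig)
  writeLines(c("# q[1/A] I(q) sigma", lines), path)
  invisible(path)
}
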