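#' Hertzian contact force for a spherical indenter
#'
#' For a rigid sphere of radius R pressed a depth delta into an elastic
#' half-space of Young's modulus E and Poisson's ratio nu,
#' `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)`.
#'
#' @param delta Indentation depth (m, >= 0), vectorised.
#' @param E Young's modulus (Pa, > 0).
#' @param R Sphere radius (m, > 0).
#' @param nu Poisson's ratio (default 0.5, incompressible).
#' @return Force in newtons.
#' @export
hertz_force <- function(delta, E, R, nu = 0.5) {
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  stopifnot(E > 0, R > 0, nu >= 0, nu <= 0.5 + 1e-9)
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Plain least squares of `F = C delta^(3/2)` over `[0, delta_max]` with
#' the single free parameter E (through C = (4/3) E sqrt(R)/(1-nu^2)).
#' Because the model is linear in C the optimum is closed-form:
#' `C = sum(F d^(3/2)) / sum(d^3)`; a non-positive optimum (a curve with
#' no net positive force trend) is a fit error, which keeps E > 0
#' without constrained optimisation.
#'
#' @param curve An [fi_curve].
#' @param delta_max Upper end of the fit range (m). Default
#'   `min(800e-9, 0.1 * R)` — shallow enough to stay clear of the rigid
#'   dish and within the small-indentation regime (about 10 percent of
#'   the probe radius).
#' @param nu Poisson's ratio override; default from the curve metadata.
#' @return A list of class `hertz_fit`: `E` (Pa), `fit_range` (m),
#'   `residual_rms` (N), `n_points`.
#' @export
fit_hertz <- function(curve, delta_max = NULL, nu = NULL) {
  stopifnot(inherits(curve, "fi_curve"))
  R <- curve$metadata$probe_radius
  nu <- nu %||% curve$metadata$poisson_ratio
  delta_max <- delta_max %||% min(800e-9, 0.1 * R)
  sel <- curve$delta > 0 & curve$delta <= delta_max
  if (sum(sel) < 10L)
    stop("fit error: fewer than 10 points with 0 < delta <= delta_max",
         call. = FALSE)
  d <- curve$delta[sel]; f <- curve$force[sel]
  x <- d^1.5
  C <- sum(f * x) / sum(x * x)
  if (!is.finite(C) || C <= 0)
    stop("fit error: non-positive Hertz coefficient", call. = FALSE)
  E <- C * 3 * (1 - nu^2) / (4 * sqrt(R))
  structure(list(E = E,
                 fit_range = c(min(d), max(d)),
                 residual_rms = sqrt(mean((f - C * x)^2)),
                 n_points = sum(sel)),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz fit: E = %.4g kPa (%d points, depth %.0f-%.0f nm, residual RMS %.3g nN)\n",
              x$E * 1e-3, x$n_points, x$fit_range[1] * 1e9,
              x$fit_range[2] * 1e9, x$residual_rms * 1e9))
  invisible(x)
}

#' Population summary of per-curve Young's moduli
#'
#' Histograms the per-curve E values with Freedman-Diaconis binning and
#' fits a Gaussian to the bin counts; the population is summarised by
#' the peak position and its standard error from the fit covariance
#' (peak +/- SEM, not mean +/- SD), which is robust against the
#' long-tailed outliers typical of force-curve batches.
#'
#' @param E_values Numeric vector of moduli (Pa), length >= 10.
#' @return A list of class `hertz_population`: `E_values`, `peak` (Pa),
#'   `peak_sem` (Pa), `n_curves`.
#' @export
population_peak <- function(E_values) {
  E_values <- as.numeric(E_values)
  if (length(E_values) < 10L)
    stop("need at least 10 values", call. = FALSE)
  if (!all(is.finite(E_values))) stop("E_values must be finite", call. = FALSE)
  if (diff(range(E_values)) == 0) {
    warning("degenerate population: all values equal")
    return(structure(list(E_values = E_values, peak = E_values[1],
                          peak_sem = 0, n_curves = length(E_values)),
                     class = "hertz_population"))
  }
  h <- graphics::hist(E_values, breaks = "FD", plot = FALSE)
  mids <- h$mids; counts <- h$counts
  i0 <- which.max(counts)
  start <- list(A = max(counts), mu = mids[i0],
                s = max(stats::sd(E_values) / 2, diff(mids[1:2])))
  fit <- minpack.lm::nlsLM(
    counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
    start = start,
    lower = c(A = 0, mu = min(mids), s = diff(mids[1:2]) / 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["mu"]],
                 error = function(e) NA_real_)
  structure(list(E_values = E_values, peak = unname(co[["mu"]]),
                 peak_sem = se, n_curves = length(E_values)),
            class = "hertz_population")
}

#' @export
print.hertz_population <- function(x, ...) {
  cat(sprintf("Population of %d curves: E peak = %.4g +/- %.2g kPa (peak +/- SEM)\n",
              x$n_curves, x$peak * 1e-3, x$peak_sem * 1e-3))
  invisible(x)
}
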