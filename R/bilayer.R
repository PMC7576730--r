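#' Exponential bilayer elasticity profile
#'
#' Phenomenological depth dependence of the apparent modulus for a thin
#' surface layer (stiffness `E0`, thickness `d0`) on a half-space of
#' stiffness `Eb`, indented by a sphere of radius `R`:
#' `E(delta) = Eb + (E0 - Eb) exp(-lam sqrt(R delta) / d0)`.
#' The decay is governed by the contact radius `a = sqrt(R delta)`
#' relative to the layer thickness; `lam` is a dimensionless
#' phenomenological factor (default 1.74, calibrated against numerical
#' layered-contact data). Only the ratio `lam / d0` enters the model, so
#' rescaling `lam` rescales the fitted thickness by the same factor.
#'
#' @param delta Depth (m, >= 0), vectorised.
#' @param E0 Surface-layer modulus (Pa).
#' @param Eb Bulk modulus (Pa).
#' @param d0 Layer thickness (m).
#' @param R Probe radius (m).
#' @param lam Dimensionless decay factor.
#' @return Apparent modulus (Pa).
#' @export
bilayer_profile <- function(delta, E0, Eb, d0, R, lam = 1.74) {
  stopifnot(E0 > 0, Eb > 0, d0 > 0, R > 0, lam > 0)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  Eb + (E0 - Eb) * exp(-lam * sqrt(R * delta) / d0)
}

#' Fit the exponential bilayer model to a mean elasticity spectrum
#'
#' Nonlinear least squares of [bilayer_profile] to `E_mean(delta)` over
#' a depth range, with free parameters (E0, Eb, d0) and `lam` held fixed
#' (the decay factor must be known a priori; it trades off exactly
#' against d0). Positivity is enforced by fitting log-parameters; up to
#' five deterministically jittered restarts are attempted before
#' declaring non-convergence. A fit with E0 < Eb (soft layer on stiff
#' bulk) is allowed but flagged, as is a degenerate fit in which the
#' amplitude E0 - Eb is too small to identify d0.
#'
#' @param mean_spec A [mean_spectrum].
#' @param R Probe radius (m).
#' @param lam Decay factor; default 1.74.
#' @param range Depth range `c(delta_min, delta_max)` (m); default the
#'   full spectrum, typically from [select_working_range].
#' @param weights `"none"` (default; the averaged spectrum is fitted
#'   unweighted) or `"inverse_variance"` (1/SE^2 per point).
#' @return A list of class `bilayer_fit`: `E0_Pa`, `Eb_Pa`, `d0_m`,
#'   `lambda_used`, `param_se` (named E0, Eb, d0), `fit_rms_Pa`,
#'   `n_points`, `fit_range_m`, `inverted` (E0 < Eb), `degenerate`.
#' @export
fit_bilayer <- function(mean_spec, R, lam = 1.74, range = NULL,
                        weights = c("none", "inverse_variance")) {
  stopifnot(inherits(mean_spec, "mean_spectrum"), R > 0, lam > 0)
  weights <- match.arg(weights)
  d <- mean_spec$delta; e <- mean_spec$E_mean
  if (is.null(range)) range <- c(d[1], d[length(d)])
  sel <- d >= range[1] & d <= range[2] & is.finite(e)
  if (sum(sel) < 10L)
    stop("fit error: fewer than 10 spectrum points in range", call. = FALSE)
  d <- d[sel]; e <- e[sel]
  w <- rep(1, length(d))
  if (weights == "inverse_variance") {
    se <- mean_spec$E_std[sel] / sqrt(pmax(mean_spec$n[sel], 1L))
    w <- ifelse(se > 0, 1 / se^2, max(1 / se[se > 0]^2))
  }

  n10 <- max(3L, ceiling(length(d) * 0.10))
  n20 <- max(3L, ceiling(length(d) * 0.20))
  E0_init <- max(mean(e[seq_len(n10)]), 1e-3)
  Eb_init <- max(mean(e[seq(length(d) - n20 + 1L, length(d))]), 1e-3)
  d0_init <- R / 10
  # deterministic jitter schedule for restarts (no RNG involved)
  jit <- list(c(1, 1, 1), c(1, 1, 0.3), c(1, 1, 3), c(1.5, 0.7, 1),
              c(0.7, 1.5, 0.5))
  fit <- NULL
  for (jf in jit) {
    st <- list(lE0 = log(E0_init * jf[1]), lEb = log(Eb_init * jf[2]),
               ld0 = log(d0_init * jf[3]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        e ~ exp(lEb) + (exp(lE0) - exp(lEb)) *
          exp(-lam * sqrt(R * d) / exp(ld0)),
        start = st, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
      error = function(err) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("fit error: bilayer fit did not converge after restarts",
         call. = FALSE)
  co <- stats::coef(fit)
  E0 <- exp(co[["lE0"]]); Eb <- exp(co[["lEb"]]); d0 <- exp(co[["ld0"]])
  se_log <- tryCatch(sqrt(diag(stats::vcov(fit))),
                     error = function(err) rep(NA_real_, 3))
  # delta method: SE(exp(x)) = exp(x) SE(x)
  param_se <- c(E0 = E0 * se_log[["lE0"]], Eb = Eb * se_log[["lEb"]],
                d0 = d0 * se_log[["ld0"]])
  resid <- e - bilayer_profile(d, E0, Eb, d0, R, lam)
  # d0 is unidentifiable when the decay amplitude E0 - Eb vanishes: any
  # thickness then fits equally well
  degenerate <- is.na(param_se[["d0"]]) || param_se[["d0"]] > d0 ||
    abs(E0 - Eb) < 1e-3 * max(E0, Eb)
  structure(list(E0_Pa = E0, Eb_Pa = Eb, d0_m = d0, lambda_used = lam,
                 param_se = param_se, fit_rms_Pa = sqrt(mean(resid^2)),
                 n_points = length(d), fit_range_m = c(min(d), max(d)),
                 inverted = E0 < Eb, degenerate = degenerate),
            class = "bilayer_fit")
}

#' @export
print.bilayer_fit <- function(x, ...) {
  cat(sprintf(
    "Bilayer fit (lambda = %.3g): E0 = %.4g kPa, Eb = %.4g kPa, d0 = %.4g nm\n",
    x$lambda_used, x$E0_Pa * 1e-3, x$Eb_Pa * 1e-3, x$d0_m * 1e9))
  cat(sprintf("  SE: E0 %.2g kPa, Eb %.2g kPa, d0 %.2g nm; RMS %.3g kPa over %d points\n",
              x$param_se[["E0"]] * 1e-3, x$param_se[["Eb"]] * 1e-3,
              x$param_se[["d0"]] * 1e9, x$fit_rms_Pa * 1e-3, x$n_points))
  if (x$inverted) cat("  note: E0 < Eb (soft layer on stiff bulk)\n")
  if (x$degenerate) cat("  warning: amplitude too small, d0 not identifiable\n")
  invisible(x)
}

#' Calibrate the decay factor lambda against a reference layered curve
#'
#' Given a force-indentation curve generated by a layered-contact model
#' with known ground-truth parameters, computes its elasticity spectrum
#' and fits the exponential bilayer model with (E0, Eb, d0) fixed at the
#' truth and lambda as the single free parameter. The resulting lambda
#' transfers the model's depth scale onto real data, where only
#' lambda/d0 is identifiable.
#'
#' @param curve An [fi_curve] from a layered simulation (see
#'   [generate_fea_surrogate] / [generate_bilayer]).
#' @param truth Named list or vector with `E0`, `Eb` (Pa) and `d0` (m).
#' @param range Optional depth range for the fit (m).
#' @param derivative_step Passed to [pointwise_modulus].
#' @return A list of class `lambda_calibration`: `lambda`, `lambda_se`,
#'   `fit_rms_Pa`, `n_points`.
#' @export
calibrate_lambda <- function(curve, truth, range = NULL,
                             derivative_step = 25e-9) {
  stopifnot(inherits(curve, "fi_curve"))
  E0 <- truth[["E0"]]; Eb <- truth[["Eb"]]; d0 <- truth[["d0"]]
  stopifnot(E0 > 0, Eb > 0, d0 > 0)
  if (abs(E0 - Eb) < 1e-9 * max(E0, Eb))
    stop("calibration error: E0 = Eb leaves lambda unidentified",
         call. = FALSE)
  R <- curve$metadata$probe_radius
  sp <- pointwise_modulus(curve, derivative_step = derivative_step)
  d <- sp$delta; e <- sp$E
  if (!is.null(range)) {
    sel <- d >= range[1] & d <= range[2]
    d <- d[sel]; e <- e[sel]
  }
  fit <- minpack.lm::nlsLM(
    e ~ Eb + (E0 - Eb) * exp(-exp(llam) * sqrt(R * d) / d0),
    start = list(llam = log(1.74)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12))
  lam <- exp(stats::coef(fit)[["llam"]])
  se <- tryCatch(lam * sqrt(stats::vcov(fit)[1, 1]),
                 error = function(err) NA_real_)
  resid <- e - bilayer_profile(d, E0, Eb, d0, R, lam)
  structure(list(lambda = lam, lambda_se = se,
                 fit_rms_Pa = sqrt(mean(resid^2)), n_points = length(d)),
            class = "lambda_calibration")
}

#' @export
print.lambda_calibration <- function(x, ...) {
  cat(sprintf("Lambda calibration: lambda = %.4g +/- %.2g (%d points, RMS %.3g kPa)\n",
              x$lambda, x$lambda_se, x$n_points, x$fit_rms_Pa * 1e-3))
  invisible(x)
}

#' Aggregate bilayer fits from repeated sessions
#'
#' Combines per-session fits into a session-weighted summary: for each
#' parameter the weighted mean with weights proportional to the number
#' of cells per session, and the weighted variance of the repeats about
#' that mean (the error bar of the aggregate).
#'
#' @param fits List of `bilayer_fit` objects (>= 2).
#' @param n_cells Integer vector, cells measured per session.
#' @return A list of class `session_aggregate` with `weighted_mean` and
#'   `weighted_variance` (named E0_Pa, Eb_Pa, d0_m), `n_sessions`,
#'   `weights`.
#' @export
aggregate_sessions <- function(fits, n_cells) {
  if (length(fits) != length(n_cells))
    stop("validation error: fits and n_cells lengths differ", call. = FALSE)
  if (length(fits) < 2L) stop("need at least 2 sessions", call. = FALSE)
  stopifnot(all(vapply(fits, inherits, logical(1), "bilayer_fit")),
            all(n_cells > 0))
  w <- n_cells / sum(n_cells)
  params <- c(E0_Pa = "E0_Pa", Eb_Pa = "Eb_Pa", d0_m = "d0_m")
  wm <- vapply(params, function(p)
    sum(w * vapply(fits, `[[`, numeric(1), p)), numeric(1))
  wv <- vapply(names(params), function(p) {
    x <- vapply(fits, `[[`, numeric(1), params[[p]])
    sum(w * (x - wm[[p]])^2)
  }, numeric(1))
  structure(list(weighted_mean = wm, weighted_variance = wv,
                 n_sessions = length(fits), weights = w),
            class = "session_aggregate")
}

#' @export
print.session_aggregate <- function(x, ...) {
  cat(sprintf("Aggregate of %d sessions (weights by cell count):\n", x$n_sessions))
  cat(sprintf("  E0 = %.4g +/- %.2g kPa\n", x$weighted_mean[["E0_Pa"]] * 1e-3,
              sqrt(x$weighted_variance[["E0_Pa"]]) * 1e-3))
  cat(sprintf("  Eb = %.4g +/- %.2g kPa\n", x$weighted_mean[["Eb_Pa"]] * 1e-3,
              sqrt(x$weighted_variance[["Eb_Pa"]]) * 1e-3))
  cat(sprintf("  d0 = %.4g +/- %.2g nm\n", x$weighted_mean[["d0_m"]] * 1e9,
              sqrt(x$weighted_variance[["d0_m"]]) * 1e9))
  invisible(x)
}
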