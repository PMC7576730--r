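#' Pointwise apparent modulus: the elasticity spectrum of one curve
#'
#' Converts a force-indentation curve into an apparent Young's modulus
#' versus depth via the pointwise Oliver-Pharr relation
#' `dF/ddelta = 2 a E/(1-nu^2)` with the Sneddon contact radius
#' `a = sqrt(R delta)`, i.e.
#' `E(delta) = (1-nu^2) / (2 sqrt(R delta)) * dF/ddelta`
#' (the 3/(8 sqrt(R delta)) prefactor when nu = 0.5). The curve is first
#' resampled onto a uniform depth grid and the local slope dF/ddelta is
#' estimated by a Savitzky-Golay first-derivative filter whose window
#' spans `derivative_step`. For an ideal Hertzian curve the spectrum is
#' constant and equal to the generating modulus at every depth, which is
#' the internal consistency check of the method.
#'
#' @param curve An [fi_curve] (metadata supplies R and nu).
#' @param derivative_step Physical width of the derivative window (m).
#'   Default 25 nm.
#' @param resample_step Uniform grid spacing for resampling (m). Default
#'   `derivative_step / 5` (5 nm at the default step; must be
#'   <= derivative_step / 3).
#' @param sg_polyorder Polynomial order of the derivative filter.
#'   Default 3: the cubic/quartic filter pair cancels the O(h^2 F''')
#'   bias of the quadratic pair, which otherwise distorts the spectrum
#'   at shallow depths where F curves fastest, at the price of a larger
#'   noise variance (recovered by batch averaging).
#' @return An [elasticity_spectrum]; depths below `derivative_step` are
#'   not reported (the slope estimate is not yet supported there and the
#'   1/sqrt(delta) prefactor diverges).
#' @export
pointwise_modulus <- function(curve, derivative_step = 25e-9,
                              resample_step = derivative_step / 5,
                              sg_polyorder = 3L) {
  stopifnot(inherits(curve, "fi_curve"))
  R <- curve$metadata$probe_radius
  nu <- curve$metadata$poisson_ratio
  if (!is.finite(R) || R <= 0) stop("metadata error: invalid R", call. = FALSE)
  if (resample_step > derivative_step / 3 + 1e-15)
    stop("resample_step must be <= derivative_step / 3", call. = FALSE)
  dmax <- max(curve$delta)
  if (dmax <= 5 * derivative_step)
    stop("curve too shallow for the elasticity spectrum (max depth ",
         format(dmax * 1e9), " nm)", call. = FALSE)
  grid <- seq(resample_step, dmax, by = resample_step)
  f <- stats::approx(curve$delta, curve$force, xout = grid,
                     ties = mean, rule = 1)$y
  ok <- !is.na(f)
  grid <- grid[ok]; f <- f[ok]
  n_win <- .odd_window(derivative_step, resample_step,
                       minimum = sg_polyorder + 2L)
  if (length(grid) <= n_win)
    stop("curve too shallow after resampling", call. = FALSE)
  dFdd <- signal::sgolayfilt(f, p = sg_polyorder, n = n_win, m = 1L,
                             ts = resample_step)
  E <- (1 - nu^2) / (2 * sqrt(R * grid)) * dFdd
  keep <- grid >= derivative_step - 1e-15
  elasticity_spectrum(grid[keep], E[keep], id = curve$id)
}

#' Average elasticity spectra over a batch of curves
#'
#' Pointwise mean and standard deviation on the union of the individual
#' depth grids (all spectra must share the grid spacing; no
#' extrapolation past each curve's own depth, so the curve count n drops
#' with depth as shorter curves run out).
#'
#' @param spectra List of [elasticity_spectrum] objects.
#' @return A [mean_spectrum].
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop("validation error: empty spectrum list", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1), "elasticity_spectrum")))
  steps <- vapply(spectra, function(s) diff(s$delta[1:2]), numeric(1))
  if (any(abs(steps - steps[1]) > 1e-6 * steps[1]))
    stop("spectra must share the same grid spacing", call. = FALSE)
  step <- steps[1]
  lo <- min(vapply(spectra, function(s) s$delta[1], numeric(1)))
  hi <- max(vapply(spectra, function(s) s$delta[length(s$delta)], numeric(1)))
  grid <- seq(lo, hi + step / 2, by = step)
  acc_n <- integer(length(grid))
  acc_s <- numeric(length(grid))
  acc_s2 <- numeric(length(grid))
  for (s in spectra) {
    # snap onto the common grid (grids are aligned up to round-off)
    j <- round((s$delta - lo) / step) + 1L
    valid <- j >= 1L & j <= length(grid) &
      abs(grid[pmax(pmin(j, length(grid)), 1L)] - s$delta) < step / 4
    j <- j[valid]; e <- s$E[valid]
    acc_n[j] <- acc_n[j] + 1L
    acc_s[j] <- acc_s[j] + e
    acc_s2[j] <- acc_s2[j] + e * e
  }
  covered <- acc_n > 0L
  grid <- grid[covered]; nn <- acc_n[covered]
  m <- acc_s[covered] / nn
  v <- ifelse(nn > 1L, (acc_s2[covered] - nn * m^2) / (nn - 1L), 0)
  mean_spectrum(grid, m, sqrt(pmax(v, 0)), nn)
}

#' Select the trusted depth range of a mean spectrum
#'
#' The apparent modulus of a soft sample on a rigid dish eventually
#' rises with depth as the substrate is felt. The working range ends at
#' the onset of that rise: the first depth at which the slope of a
#' running linear fit of the mean spectrum (over a `slope_window` wide
#' window) turns persistently positive after having been non-positive.
#' When no rise is detected the full range (capped at `hard_cap`) is
#' returned.
#'
#' @param mean_spec A [mean_spectrum] (>= 10 grid points).
#' @param hard_cap Absolute maximum depth (m). Default 800 nm.
#' @param slope_window Window for the running linear fit (m). Default
#'   100 nm.
#' @return Numeric vector `c(delta_min, delta_max)` in metres.
#' @export
select_working_range <- function(mean_spec, hard_cap = 800e-9,
                                 slope_window = 100e-9) {
  stopifnot(inherits(mean_spec, "mean_spectrum"))
  d <- mean_spec$delta; e <- mean_spec$E_mean
  if (length(d) < 10L) stop("mean spectrum too short", call. = FALSE)
  step <- d[2] - d[1]
  w <- .odd_window(slope_window, step, minimum = 3L)
  full <- c(d[1], min(hard_cap, d[length(d)]))
  if (length(d) < w + 2L) return(full)
  # centred running slope via rolling first moments
  nwin <- length(d) - w + 1L
  slope <- vapply(seq_len(nwin), function(j) {
    xs <- d[j:(j + w - 1L)]; ys <- e[j:(j + w - 1L)]
    stats::cov(xs, ys) / stats::var(xs)
  }, numeric(1))
  centre <- seq_len(nwin) + (w - 1L) %/% 2L  # depth index of each window centre
  nonpos <- which(slope <= 0)
  if (!length(nonpos)) return(full)          # monotone rise from the start:
                                             # no decay phase to protect
  i0 <- nonpos[1]
  after <- slope[seq(i0, nwin)]
  # first window after i0 from which the slope stays positive to the end
  pos_run <- rev(cumprod(rev(after > 0))) == 1
  if (!any(pos_run) || all(after <= 0)) return(full)
  onset <- i0 + which(pos_run)[1] - 1L
  if (onset == i0) return(full)
  c(d[1], min(hard_cap, d[centre[onset]]))
}
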