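#' Preprocessing configuration
#'
#' Parameters for smoothing, contact-point detection and quality control.
#' Window lengths are physical lengths (m) so that the behaviour does not
#' depend on the sampling rate; they are converted to (odd) sample counts
#' internally.
#'
#' @param sg_window Savitzky-Golay smoothing window (m). Default 25 nm.
#' @param sg_polyorder Polynomial order of the smoother. Default 3.
#' @param rov_window Half-window of the ratio-of-variances detector (m);
#'   the sample-count equivalent is capped at `rov_max_samples`.
#'   Default 300 nm.
#' @param rov_max_samples Cap on the RoV window in samples. Default 150.
#' @param rov_min_prominence Peak prominence threshold as a fraction of
#'   the maximum of the RoV trace. Default 0.1.
#' @param rov_min_peak Absolute floor on the RoV maximum (default 3):
#'   below it the post-"contact" variance never rises convincingly above
#'   the baseline variance and the curve is declared contact-free.
#' @param refine_window Half-width (m) of the local piecewise-fit
#'   refinement around the RoV peak (see [find_contact_point]). Default
#'   100 nm: wide enough to average the noise, short enough that the
#'   sample still responds with its surface stiffness over the window.
#' @param qc_baseline_slope_max Maximum tolerated absolute baseline slope
#'   (N/m). `NULL` (default) uses the adaptive rule
#'   3 x baseline residual RMS / baseline length.
#' @param qc_noise_rms_max Maximum tolerated baseline residual RMS (N).
#'   `NULL` (default) means no absolute cap for a single curve;
#'   [qc_batch] replaces it by 5 x the batch median.
#' @param subtract_deflection If `TRUE` (default) the cantilever
#'   deflection F/k is subtracted from z - z0 when computing the
#'   indentation; if `FALSE` delta = z - z0.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 25e-9, sg_polyorder = 3L,
                              rov_window = 300e-9, rov_max_samples = 150L,
                              rov_min_prominence = 0.1, rov_min_peak = 3,
                              refine_window = 100e-9,
                              qc_baseline_slope_max = NULL,
                              qc_noise_rms_max = NULL,
                              subtract_deflection = TRUE) {
  stopifnot(sg_window > 0, rov_window > 0, rov_min_prominence > 0,
            sg_polyorder >= 1L, rov_max_samples >= 8L, refine_window > 0,
            rov_min_peak > 0)
  structure(list(sg_window = sg_window, sg_polyorder = as.integer(sg_polyorder),
                 rov_window = rov_window, refine_window = refine_window,
                 rov_max_samples = as.integer(rov_max_samples),
                 rov_min_prominence = rov_min_prominence,
                 rov_min_peak = rov_min_peak,
                 qc_baseline_slope_max = qc_baseline_slope_max,
                 qc_noise_rms_max = qc_noise_rms_max,
                 subtract_deflection = isTRUE(subtract_deflection)),
            class = "preprocess_config")
}

# odd sample count covering a physical length at grid spacing dz
.odd_window <- function(length_m, dz, minimum = 3L) {
  n <- max(minimum, round(length_m / dz))
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  n
}

#' Savitzky-Golay smoothing of a force-distance curve
#'
#' Replaces the force channel by a local-polynomial least-squares
#' estimate; z is left untouched. Endpoints are fitted with the
#' one-sided rows of the Savitzky-Golay projection matrix (a polynomial
#' fit over the window evaluated at the edge position), so there are no
#' padding artifacts. The curve must be uniformly sampled in z.
#'
#' @param curve An [fd_curve].
#' @param cfg A [preprocess_config].
#' @return The smoothed [fd_curve].
#' @export
smooth_curve <- function(curve, cfg = preprocess_config()) {
  stopifnot(inherits(curve, "fd_curve"))
  dz <- stats::median(diff(curve$z))
  n_win <- .odd_window(cfg$sg_window, dz, minimum = cfg$sg_polyorder + 2L)
  if (n_win %% 2L == 0L) n_win <- n_win + 1L
  if (n_win > length(curve$z))
    stop("config error: smoothing window (", n_win,
         " samples) exceeds curve length", call. = FALSE)
  sm <- signal::sgolayfilt(curve$force, p = cfg$sg_polyorder, n = n_win)
  fd_curve(curve$z, sm, curve$metadata, id = curve$id)
}

# sliding-window sample variance; out[j] = var(x[j:(j+w-1)])
.roll_var <- function(x, w) {
  n <- length(x)
  if (w < 2L || n < w) return(numeric(0))
  c1 <- cumsum(x); c2 <- cumsum(x * x)
  j <- seq_len(n - w + 1L)
  s1 <- c1[j + w - 1L] - c(0, c1)[j]
  s2 <- c2[j + w - 1L] - c(0, c2)[j]
  v <- (s2 - s1 * s1 / w) / (w - 1)
  pmax(v, 0) # guard tiny negative round-off
}

# peak prominence on a discrete trace: height above the higher of the two
# valley minima separating the peak from higher ground (or the trace ends)
.peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lmin <- if (length(higher_l)) min(left[(max(higher_l)):(p - 1L)])
            else min(c(left, h))
    right <- y[seq(p + 1L, length(y))]
    higher_r <- which(right > h)
    rmin <- if (length(higher_r)) min(right[seq_len(min(higher_r))])
            else min(c(right, h))
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Contact-point detection by the ratio of variances
#'
#' Computes, for every interior sample i, the ratio of the force variance
#' in a window after i to the variance in a window before i. Contact with
#' the sample changes the noise content of the signal, so the trace peaks
#' at the contact point; among all local maxima with sufficient
#' prominence, the last one (largest z) is returned as z0. No assumption
#' is made about the polynomial shape of the post-contact curve.
#'
#' Because the force grows only like delta^(3/2), the noise content
#' changes gradually across contact and the bare RoV peak sits a few
#' samples late (at the depth where the force first exceeds the noise
#' floor). The returned z0 is therefore refined around the RoV peak by a
#' local two-regime least-squares fit (flat baseline before contact,
#' baseline plus a 3/2-power onset after), which restores
#' sample-spacing accuracy; set `refine = FALSE` for the bare peak.
#'
#' @param curve An [fd_curve].
#' @param cfg A [preprocess_config]; `rov_window` / `rov_max_samples` set
#'   the window, `rov_min_prominence` the peak threshold (fraction of the
#'   trace maximum).
#' @param refine Refine the RoV peak by the local piecewise fit
#'   (default TRUE).
#' @return A list with `index` (sample index of z0), `z0` (m), `rov`
#'   (data.frame z, rov of the full trace), `rov_peak_index` (unrefined
#'   peak) and `zero_variance_floor` (TRUE when the pre-contact variance
#'   had to be floored).
#' @export
find_contact_point <- function(curve, cfg = preprocess_config(),
                               refine = TRUE) {
  stopifnot(inherits(curve, "fd_curve"))
  z <- curve$z; f <- curve$force; n <- length(f)
  dz <- stats::median(diff(z))
  w <- min(cfg$rov_max_samples, max(8L, as.integer(round(cfg$rov_window / dz))))
  if (n < 2L * w + 2L)
    stop("config error: curve too short for RoV window of ", w, " samples",
         call. = FALSE)
  V <- .roll_var(f, w)                  # V[j] = var(f[j:(j+w-1)])
  i <- seq(w + 1L, n - w)               # candidate contact samples
  v_after <- V[i + 1L]
  v_before <- V[i - w]
  floor_used <- any(v_before <= 0)
  eps <- max(V) * 1e-12 + .Machine$double.xmin
  rov <- v_after / pmax(v_before, eps)
  if (max(rov) < cfg$rov_min_peak)
    stop("contact-not-found: variance never rises above the baseline level",
         call. = FALSE)

  m <- length(rov)
  is_peak <- c(FALSE, rov[2:(m - 1)] > rov[1:(m - 2)] &
                      rov[2:(m - 1)] >= rov[3:m], FALSE)
  peaks <- which(is_peak)
  if (length(peaks)) {
    prom <- .peak_prominence(rov, peaks)
    peaks <- peaks[prom >= cfg$rov_min_prominence * max(rov)]
  }
  if (!length(peaks))
    stop("contact-not-found: no RoV peak above prominence threshold",
         call. = FALSE)
  idx <- i[max(peaks)]                  # the LAST qualifying peak
  peak_idx <- idx
  z0 <- z[idx]
  if (refine) {
    hw <- max(25L, as.integer(round(cfg$refine_window / dz)))
    ref <- .refine_contact(z, f, idx, half_width = hw,
                           k = curve$metadata$spring_constant)
    idx <- ref$index; z0 <- ref$z0
  }
  list(index = idx, z0 = z0,
       rov = data.frame(z = z[i], rov = rov),
       rov_peak_index = peak_idx,
       zero_variance_floor = floor_used)
}

# local two-regime refinement of a coarse contact index: over candidates c
# in a window, least squares of F = b0 (delta <= 0) and
# F = b0 + A delta^(3/2) (delta > 0) with the deflection-corrected
# indentation delta = (z - z_c) - F/k; returns the SSE-minimising sample.
# The F/k term matters: without it the fit leans on the compliance
# mismatch at the deep end of the window and lands several samples early.
.refine_contact <- function(z, f, i0, half_width, k) {
  n <- length(z)
  lo <- max(1L, i0 - half_width)
  hi <- min(n, i0 + half_width)
  cand <- seq(max(lo + 4L, lo), min(hi - 4L, hi))
  if (length(cand) < 3L) return(list(index = i0, z0 = z[i0]))
  zz <- z[lo:hi]; ff <- f[lo:hi]
  defl <- ff / k
  sse <- vapply(cand, function(cidx) {
    x <- pmax(zz - z[cidx] - defl, 0)^1.5
    fit <- stats::lm.fit(cbind(1, x), ff)
    sum(fit$residuals^2)
  }, numeric(1))
  j <- which.min(sse)
  idx <- cand[j]
  z0 <- z[idx]
  # sub-sample contact point by a parabola through the SSE minimum:
  # E(delta) ~ 1/sqrt(delta) amplifies even one-sample contact errors at
  # shallow depth, so sample resolution is not enough
  if (j > 1L && j < length(cand)) {
    denom <- sse[j - 1L] - 2 * sse[j] + sse[j + 1L]
    if (is.finite(denom) && denom > 0) {
      shift <- 0.5 * (sse[j - 1L] - sse[j + 1L]) / denom
      dz <- stats::median(diff(z))
      z0 <- z0 + max(-1, min(1, shift)) * dz
    }
  }
  list(index = idx, z0 = z0)
}

#' Convert a force-distance curve to a force-indentation curve
#'
#' Subtracts the contact point z0 and (by default) the cantilever
#' deflection x = F/k, so that `delta = (z - z0) - F/k`. Samples before
#' contact are dropped, small negative indentations are clipped to zero
#' and non-monotone back-steps (noise at very low force) are removed.
#' Force values are never modified, only re-indexed onto delta.
#'
#' @param curve An [fd_curve].
#' @param z0 Contact point (m), typically from [find_contact_point].
#' @param cfg A [preprocess_config]; `subtract_deflection` controls the
#'   F/k term.
#' @return An [fi_curve].
#' @export
to_force_indentation <- function(curve, z0, cfg = preprocess_config()) {
  stopifnot(inherits(curve, "fd_curve"))
  if (z0 < min(curve$z) || z0 > max(curve$z))
    stop("z0 outside the z range of the curve", call. = FALSE)
  k <- curve$metadata$spring_constant
  if (!is.finite(k) || k <= 0) stop("metadata error: invalid k", call. = FALSE)
  keep <- curve$z >= z0
  if (sum(keep) < 2L)
    stop("empty-curve error: all points pre-contact", call. = FALSE)
  z <- curve$z[keep]; f <- curve$force[keep]
  delta <- (z - z0) - if (cfg$subtract_deflection) f / k else 0
  delta <- pmax(delta, 0)
  # enforce monotone delta by dropping back-steps
  mono <- delta >= cummax(c(0, head(delta, -1L)))
  delta <- delta[mono]; f <- f[mono]
  fi_curve(delta, f, contact_point_z = z0, metadata = curve$metadata,
           id = curve$id)
}

#' Quality control for a single curve
#'
#' Applies the exclusion rules used for batch analysis: a curve is
#' rejected when no contact point was found (`no_contact_point`), when
#' its pre-contact baseline is not flat (`no_flat_region`: absolute
#' baseline slope above threshold) or when the baseline residuals are too
#' noisy (`high_noise`). Baseline slope and residual RMS come from a
#' least-squares line over the pre-contact segment.
#'
#' @param curve An [fd_curve].
#' @param z0 Contact point (m) or `NA` if detection failed.
#' @param cfg A [preprocess_config].
#' @param noise_rms_max Optional absolute RMS cap (N) overriding
#'   `cfg$qc_noise_rms_max`; [qc_batch] passes the batch-median rule here.
#' @return A list of class `qc_report`: `accepted`, `reasons`,
#'   `baseline_slope` (N/m), `baseline_noise_rms` (N).
#' @export
qc_filter <- function(curve, z0, cfg = preprocess_config(),
                      noise_rms_max = NULL) {
  stopifnot(inherits(curve, "fd_curve"))
  reasons <- character(0)
  slope <- NA_real_; rms <- NA_real_
  if (is.na(z0)) {
    reasons <- c(reasons, "no_contact_point")
  } else {
    base <- curve$z < z0
    if (sum(base) >= 8L) {
      zb <- curve$z[base]; fb <- curve$force[base]
      fit <- stats::lm.fit(cbind(1, zb), fb)
      slope <- fit$coefficients[[2]]
      rms <- sqrt(mean(fit$residuals^2))
      blen <- diff(range(zb))
      slope_max <- cfg$qc_baseline_slope_max %||% (3 * rms / blen)
      if (abs(slope) > slope_max) reasons <- c(reasons, "no_flat_region")
      rms_max <- noise_rms_max %||% cfg$qc_noise_rms_max
      if (!is.null(rms_max) && rms > rms_max)
        reasons <- c(reasons, "high_noise")
    } else {
      reasons <- c(reasons, "no_flat_region")
    }
  }
  structure(list(accepted = length(reasons) == 0L, reasons = reasons,
                 baseline_slope = slope, baseline_noise_rms = rms),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(if (x$accepted) "QC: accepted\n"
      else paste0("QC: rejected (", paste(x$reasons, collapse = ", "), ")\n"))
  invisible(x)
}

#' Quality control over a batch of curves
#'
#' Runs [qc_filter] on every curve; when no absolute noise cap is
#' configured, curves are compared against 5 x the batch median of the
#' baseline residual RMS, so a uniformly noisy instrument is not
#' penalised but individual outlier curves are.
#'
#' @param curves List of [fd_curve]s.
#' @param z0s Numeric vector of contact points (NA where not found).
#' @param cfg A [preprocess_config].
#' @return A data.frame with one row per curve: id, accepted, reasons
#'   (comma-joined), baseline_slope, baseline_noise_rms.
#' @export
qc_batch <- function(curves, z0s, cfg = preprocess_config()) {
  stopifnot(length(curves) == length(z0s))
  pre <- lapply(seq_along(curves), function(j)
    qc_filter(curves[[j]], z0s[j], cfg))
  rms_max <- cfg$qc_noise_rms_max
  if (is.null(rms_max)) {
    rms_all <- vapply(pre, function(r) r$baseline_noise_rms, numeric(1))
    if (any(is.finite(rms_all)))
      rms_max <- 5 * stats::median(rms_all, na.rm = TRUE)
  }
  reports <- lapply(seq_along(curves), function(j)
    qc_filter(curves[[j]], z0s[j], cfg, noise_rms_max = rms_max))
  data.frame(
    id = vapply(curves, function(cu) cu$id, character(1)),
    accepted = vapply(reports, function(r) r$accepted, logical(1)),
    reasons = vapply(reports, function(r) paste(r$reasons, collapse = ","),
                     character(1)),
    baseline_slope = vapply(reports, function(r) r$baseline_slope, numeric(1)),
    baseline_noise_rms = vapply(reports, function(r) r$baseline_noise_rms,
                                numeric(1)),
    stringsAsFactors = FALSE)
}
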