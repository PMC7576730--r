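#' Acquisition metadata for a nanoindentation curve
#'
#' Holds the probe and cantilever constants needed to turn a raw
#' force-distance record into elasticity estimates: probe radius `R`,
#' cantilever spring constant `k` and the Poisson's ratio of the sample.
#' All values are SI (m, N/m, dimensionless).
#'
#' @param probe_radius Sphere radius R in metres (> 0).
#' @param spring_constant Cantilever stiffness k in N/m (> 0).
#' @param poisson_ratio Sample Poisson's ratio; defaults to 0.5, the
#'   incompressible limit commonly assumed for living cells.
#' @param approach_speed Optional approach speed in m/s.
#' @param label Free-text identifier for the curve or session.
#' @return An object of class `acq_metadata`.
#' @export
acq_metadata <- function(probe_radius, spring_constant, poisson_ratio = 0.5,
                         approach_speed = NA_real_, label = "") {
  stopifnot(is.numeric(probe_radius), length(probe_radius) == 1L,
            is.numeric(spring_constant), length(spring_constant) == 1L)
  if (!is.finite(probe_radius) || probe_radius <= 0)
    stop("probe_radius must be a positive length in metres", call. = FALSE)
  if (!is.finite(spring_constant) || spring_constant <= 0)
    stop("spring_constant must be positive (N/m)", call. = FALSE)
  if (!is.finite(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5 + 1e-9)
    stop("poisson_ratio must lie in [0, 0.5]", call. = FALSE)
  structure(list(probe_radius = as.numeric(probe_radius),
                 spring_constant = as.numeric(spring_constant),
                 poisson_ratio = as.numeric(poisson_ratio),
                 approach_speed = as.numeric(approach_speed),
                 label = as.character(label)),
            class = "acq_metadata")
}

#' @export
print.acq_metadata <- function(x, ...) {
  cat(sprintf("Acquisition metadata: R = %.3g um, k = %.4g N/m, nu = %.2f%s\n",
              x$probe_radius * 1e6, x$spring_constant, x$poisson_ratio,
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Raw force-distance curve
#'
#' The atomic record of a nanoindentation experiment: piezo displacement
#' `z` (m, approach direction, non-decreasing) and cantilever force
#' `force` (N), plus acquisition metadata. Duplicate z samples are
#' averaged so that z is strictly increasing.
#'
#' @param z Displacement samples in metres.
#' @param force Force samples in newtons, same length as `z`.
#' @param metadata An [acq_metadata] object.
#' @param id Optional curve identifier.
#' @return An object of class `fd_curve`.
#' @export
fd_curve <- function(z, force, metadata, id = "") {
  if (!inherits(metadata, "acq_metadata"))
    stop("metadata must be an acq_metadata object", call. = FALSE)
  z <- as.numeric(z); force <- as.numeric(force)
  if (length(z) != length(force))
    stop("z and force must have the same length", call. = FALSE)
  if (!all(is.finite(z)) || !all(is.finite(force)))
    stop("z and force must be finite", call. = FALSE)
  if (is.unsorted(z))
    stop("z must be non-decreasing (approach segment)", call. = FALSE)
  # collapse duplicated z (piezo quantisation) by averaging the force
  if (anyDuplicated(z)) {
    force <- as.numeric(tapply(force, factor(z, levels = unique(z)), mean))
    z <- unique(z)
  }
  if (length(z) < 16L)
    stop("curve too short: need at least 16 distinct samples", call. = FALSE)
  structure(list(z = z, force = force, metadata = metadata,
                 id = as.character(id)),
            class = "fd_curve")
}

#' @export
print.fd_curve <- function(x, ...) {
  cat(sprintf("Force-distance curve%s: %d samples, z in [%.3g, %.3g] um, F max %.3g nN\n",
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              length(x$z), min(x$z) * 1e6, max(x$z) * 1e6,
              max(x$force) * 1e9))
  print(x$metadata)
  invisible(x)
}

#' Force-indentation curve
#'
#' A contact-point-corrected curve: indentation `delta` (m, >= 0,
#' non-decreasing) versus force (N). This is the input of all the
#' elasticity computations.
#'
#' @param delta Indentation samples in metres (>= 0, non-decreasing).
#' @param force Force samples in newtons.
#' @param contact_point_z Contact point z0 (m) on the original z axis.
#' @param metadata An [acq_metadata] object.
#' @param id Optional curve identifier.
#' @return An object of class `fi_curve`.
#' @export
fi_curve <- function(delta, force, contact_point_z, metadata, id = "") {
  if (!inherits(metadata, "acq_metadata"))
    stop("metadata must be an acq_metadata object", call. = FALSE)
  delta <- as.numeric(delta); force <- as.numeric(force)
  if (length(delta) != length(force))
    stop("delta and force must have the same length", call. = FALSE)
  if (length(delta) == 0L)
    stop("empty force-indentation curve", call. = FALSE)
  if (any(delta < 0)) stop("delta must be non-negative", call. = FALSE)
  if (is.unsorted(delta)) stop("delta must be non-decreasing", call. = FALSE)
  structure(list(delta = delta, force = force,
                 contact_point_z = as.numeric(contact_point_z),
                 metadata = metadata, id = as.character(id)),
            class = "fi_curve")
}

#' @export
print.fi_curve <- function(x, ...) {
  cat(sprintf("Force-indentation curve%s: %d samples, depth up to %.0f nm\n",
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              length(x$delta), max(x$delta) * 1e9))
  invisible(x)
}

#' Per-curve elasticity spectrum E(delta)
#'
#' Apparent Young's modulus as a function of indentation depth on a
#' uniform depth grid, obtained from the local slope of the
#' force-indentation curve.
#'
#' @param delta Uniformly spaced depth grid (m).
#' @param E Apparent modulus at each depth (Pa).
#' @param id Source curve identifier.
#' @return An object of class `elasticity_spectrum`.
#' @export
elasticity_spectrum <- function(delta, E, id = "") {
  delta <- as.numeric(delta); E <- as.numeric(E)
  if (length(delta) != length(E)) stop("delta and E lengths differ", call. = FALSE)
  if (length(delta) < 2L) stop("spectrum needs at least 2 points", call. = FALSE)
  dd <- diff(delta)
  if (any(abs(dd - dd[1]) > 1e-6 * dd[1]))
    stop("delta grid must be uniformly spaced", call. = FALSE)
  if (!all(is.finite(E))) stop("E must be finite", call. = FALSE)
  structure(list(delta = delta, E = E, id = as.character(id)),
            class = "elasticity_spectrum")
}

#' @export
print.elasticity_spectrum <- function(x, ...) {
  cat(sprintf("Elasticity spectrum%s: %d points, %.0f-%.0f nm, E %.3g-%.3g kPa\n",
              if (nzchar(x$id)) paste0(" '", x$id, "'") else "",
              length(x$delta), min(x$delta) * 1e9, max(x$delta) * 1e9,
              min(x$E) * 1e-3, max(x$E) * 1e-3))
  invisible(x)
}

#' Mean elasticity spectrum over a batch of curves
#'
#' Pointwise mean and standard deviation of per-curve spectra on a common
#' depth grid; `n` records how many curves cover each grid point (shorter
#' curves drop out at depth).
#'
#' @param delta Depth grid (m).
#' @param E_mean,E_std Pointwise mean and SD of the apparent modulus (Pa).
#' @param n Integer vector: number of curves contributing per point.
#' @return An object of class `mean_spectrum`.
#' @export
mean_spectrum <- function(delta, E_mean, E_std, n) {
  delta <- as.numeric(delta)
  stopifnot(length(delta) == length(E_mean), length(delta) == length(E_std),
            length(delta) == length(n))
  if (any(E_std < 0, na.rm = TRUE)) stop("E_std must be >= 0", call. = FALSE)
  structure(list(delta = delta, E_mean = as.numeric(E_mean),
                 E_std = as.numeric(E_std), n = as.integer(n)),
            class = "mean_spectrum")
}

#' @export
print.mean_spectrum <- function(x, ...) {
  cat(sprintf("Mean elasticity spectrum: %d points, %.0f-%.0f nm, %d curve(s) at the surface\n",
              length(x$delta), min(x$delta) * 1e9, max(x$delta) * 1e9,
              max(x$n)))
  invisible(x)
}

#' @export
as.data.frame.mean_spectrum <- function(x, ...) {
  data.frame(delta_m = x$delta, E_mean_Pa = x$E_mean,
             E_std_Pa = x$E_std, n = x$n)
}
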