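#' Closed-form force-indentation curve of the exponential bilayer
#'
#' Integrates the pointwise Oliver-Pharr relation
#' `dF/ddelta = 2 sqrt(R delta) E(delta) / (1 - nu^2)` over the
#' exponential bilayer profile [bilayer_profile]. With the substitution
#' `u = sqrt(t)` the integral has a closed form, so the generated curve
#' is exactly consistent with the spectrum computation: applying
#' [pointwise_modulus] to this force curve returns the generating
#' profile up to discretisation error. This makes it the reference
#' generator for round-trip validation.
#'
#' @param delta Depth (m, >= 0), vectorised.
#' @inheritParams bilayer_profile
#' @param nu Poisson's ratio (default 0.5).
#' @return Force (N).
#' @export
bilayer_force <- function(delta, E0, Eb, d0, R, lam = 1.74, nu = 0.5) {
  stopifnot(E0 > 0, Eb > 0, d0 > 0, R > 0, lam > 0)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  pref <- 2 * sqrt(R) / (1 - nu^2)
  cc <- lam * sqrt(R) / d0                       # exponent = cc * sqrt(delta)
  u <- sqrt(delta)
  # I(delta) = int_0^delta sqrt(t) exp(-cc sqrt(t)) dt
  #          = 2 [ 2/cc^3 - exp(-cc u) (u^2/cc + 2 u/cc^2 + 2/cc^3) ]
  I <- 2 * (2 / cc^3 - exp(-cc * u) * (u^2 / cc + 2 * u / cc^2 + 2 / cc^3))
  pref * (Eb * (2 / 3) * delta^1.5 + (E0 - Eb) * I)
}

#' Apparent-modulus profile of the stress-weighted layered surrogate
#'
#' A sharp-interface layered-contact model used as a numerical reference
#' that is NOT the exponential fit model (synthetic surrogate): the
#' apparent modulus at contact radius `a = sqrt(R delta)` is the average
#' of the true step profile (E0 above depth d0, Eb below) weighted by
#' the normalised Hertzian axial stress decay `1/(1 + (zeta/a)^2)`,
#' giving `E_eff = Eb + (E0 - Eb) (2/pi) atan(d0 / a)`. It reproduces
#' both film limits exactly (thick film -> E0, vanishing film -> Eb) and
#' decays algebraically rather than exponentially, providing a
#' model-mismatch test bed for the exponential bilayer fit.
#'
#' @inheritParams bilayer_profile
#' @return Apparent modulus (Pa).
#' @export
surrogate_profile <- function(delta, E0, Eb, d0, R) {
  stopifnot(E0 > 0, Eb > 0, d0 > 0, R > 0)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  a <- sqrt(R * delta)
  w <- ifelse(a > 0, (2 / pi) * atan(d0 / a), 1)
  Eb + (E0 - Eb) * w
}

#' Force curve of the stress-weighted layered surrogate
#'
#' Numerically integrates the Oliver-Pharr relation over
#' [surrogate_profile] (cumulative trapezoid on the supplied grid, which
#' should be fine enough for the requested accuracy; the integrand is
#' smooth and vanishes like sqrt(delta) at zero).
#'
#' @param delta Sorted depth grid starting at >= 0 (m).
#' @inheritParams surrogate_profile
#' @param nu Poisson's ratio (default 0.5).
#' @return Force (N) on the same grid.
#' @export
surrogate_force <- function(delta, E0, Eb, d0, R, nu = 0.5) {
  if (is.unsorted(delta, strictly = TRUE))
    stop("delta must be strictly increasing", call. = FALSE)
  g <- 2 * sqrt(R * delta) * surrogate_profile(delta, E0, Eb, d0, R) /
    (1 - nu^2)
  # cumulative trapezoid, starting from F = 0 at the first grid point
  n <- length(delta)
  F0 <- if (delta[1] > 0) {
    # close the gap [0, delta[1]] with a fine Hertz-like ramp at E ~ E0
    dd <- seq(0, delta[1], length.out = 33L)
    gg <- 2 * sqrt(R * dd) * surrogate_profile(dd, E0, Eb, d0, R) / (1 - nu^2)
    sum(diff(dd) * (head(gg, -1L) + tail(gg, -1L)) / 2)
  } else 0
  F0 + c(0, cumsum(diff(delta) * (g[-n] + g[-1L]) / 2))
}

#' Configuration of a synthetic nanoindentation experiment
#'
#' Fully describes a generative model for force-distance curves so that
#' every pipeline stage can be tested against known ground truth.
#' Defaults emulate a single-cell measurement with a bead probe:
#' R = 3.5 um, k = 0.3 N/m, nu = 0.5, 4 um displacement range sampled
#' every 2 nm, contact point uniform in 0.5-1.5 um, 20 pN RMS force
#' noise.
#'
#' @param model `"homogeneous"`, `"bilayer_exponential"` or
#'   `"bilayer_fea_surrogate"`.
#' @param E Young's modulus (Pa), homogeneous model.
#' @param E0,Eb,d0 Bilayer parameters (Pa, Pa, m).
#' @param lam Decay factor of the exponential bilayer (default 1.74).
#' @param R,k,nu Probe radius (m), spring constant (N/m), Poisson ratio.
#' @param z_range Total displacement range (m).
#' @param sampling_step z sampling interval (m).
#' @param contact_offset_z0 Contact point: a scalar (m) for a fixed z0 or
#'   a length-2 window for per-curve uniform draws.
#' @param noise_sigma_F Gaussian force noise SD (N).
#' @param baseline_tilt Pre-contact baseline slope (N/m), default 0.
#' @param n_curves Number of curves in the batch.
#' @param seed RNG seed; mandatory whenever the output is stochastic
#'   (noise > 0 or randomised contact point).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(model = c("homogeneous", "bilayer_exponential",
                                        "bilayer_fea_surrogate"),
                              E = 5200, E0 = 9800, Eb = 8400, d0 = 300e-9,
                              lam = 1.74, R = 3.5e-6, k = 0.3, nu = 0.5,
                              z_range = 4e-6, sampling_step = 2e-9,
                              contact_offset_z0 = c(0.5e-6, 1.5e-6),
                              noise_sigma_F = 20e-12, baseline_tilt = 0,
                              n_curves = 1L, seed = NULL) {
  model <- match.arg(model)
  stopifnot(R > 0, k > 0, nu >= 0, nu <= 0.5 + 1e-9, z_range > 0,
            sampling_step > 0, noise_sigma_F >= 0, n_curves >= 1L)
  if (any(contact_offset_z0 <= 0) || any(contact_offset_z0 >= z_range))
    stop("config error: contact offset must lie inside (0, z_range)",
         call. = FALSE)
  stochastic <- noise_sigma_F > 0 || length(contact_offset_z0) == 2L
  if (stochastic && is.null(seed))
    stop("seed is mandatory for stochastic output", call. = FALSE)
  structure(list(model = model, E = E, E0 = E0, Eb = Eb, d0 = d0, lam = lam,
                 R = R, k = k, nu = nu, z_range = z_range,
                 sampling_step = sampling_step,
                 contact_offset_z0 = contact_offset_z0,
                 noise_sigma_F = noise_sigma_F, baseline_tilt = baseline_tilt,
                 n_curves = as.integer(n_curves), seed = seed),
            class = "simulation_config")
}

# force model F(delta) selected by the config
.force_model <- function(cfg) {
  switch(cfg$model,
    homogeneous = function(delta)
      hertz_force(delta, cfg$E, cfg$R, cfg$nu),
    bilayer_exponential = function(delta)
      bilayer_force(delta, cfg$E0, cfg$Eb, cfg$d0, cfg$R, cfg$lam, cfg$nu),
    bilayer_fea_surrogate = function(delta)
      surrogate_force(delta, cfg$E0, cfg$Eb, cfg$d0, cfg$R, cfg$nu))
}

# one noiseless curve on the uniform z grid; z = z0 + delta + F/k
.generate_curve <- function(cfg, z0, id) {
  fmod <- .force_model(cfg)
  dmax <- cfg$z_range - z0
  if (dmax <= 0) stop("config error: z_range shorter than contact offset",
                      call. = FALSE)
  # parametric (delta, F, z) at 4x the target density, then resample in z
  dd <- seq(0, dmax, by = cfg$sampling_step / 4)
  ff <- fmod(dd)
  zz <- z0 + dd + ff / cfg$k
  zgrid <- seq(0, cfg$z_range, by = cfg$sampling_step)
  force <- numeric(length(zgrid))
  pre <- zgrid < z0
  force[pre] <- cfg$baseline_tilt * (zgrid[pre] - z0)
  post <- !pre & zgrid <= max(zz)
  force[post] <- stats::approx(zz, ff, xout = zgrid[post], ties = mean)$y
  keep <- pre | post
  list(z = zgrid[keep], force = force[keep])
}

.generate_batch <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  md <- acq_metadata(cfg$R, cfg$k, cfg$nu, label = cfg$model)
  z0s <- if (length(cfg$contact_offset_z0) == 2L)
    stats::runif(cfg$n_curves, cfg$contact_offset_z0[1],
                 cfg$contact_offset_z0[2])
  else rep(cfg$contact_offset_z0, cfg$n_curves)
  curves <- vector("list", cfg$n_curves)
  for (j in seq_len(cfg$n_curves)) {
    id <- sprintf("%s_%03d", cfg$model, j)
    cu <- .generate_curve(cfg, z0s[j], id)
    if (cfg$noise_sigma_F > 0)
      cu$force <- cu$force + stats::rnorm(length(cu$force), 0,
                                          cfg$noise_sigma_F)
    curves[[j]] <- fd_curve(cu$z, cu$force, md, id = id)
  }
  manifest <- data.frame(id = vapply(curves, `[[`, character(1), "id"),
                         z0 = z0s, stringsAsFactors = FALSE)
  if (cfg$model == "homogeneous") manifest$E <- cfg$E
  else { manifest$E0 <- cfg$E0; manifest$Eb <- cfg$Eb
         manifest$d0 <- cfg$d0
         if (cfg$model == "bilayer_exponential") manifest$lam <- cfg$lam }
  structure(list(curves = curves, manifest = manifest, config = cfg),
            class = "synth_batch")
}

#' @export
print.synth_batch <- function(x, ...) {
  cat(sprintf("Synthetic batch: %d %s curve(s), noise %.3g pN, seed %s\n",
              length(x$curves), x$config$model,
              x$config$noise_sigma_F * 1e12,
              if (is.null(x$config$seed)) "none" else x$config$seed))
  invisible(x)
}

#' Generate a batch of homogeneous (Hertzian) force-distance curves
#'
#' Forward model: `F(delta)` from the Hertz equation, mapped to the
#' displacement axis through the cantilever compliance
#' (`z = z0 + delta + F/k`), a flat (optionally tilted) pre-contact
#' baseline, and Gaussian force noise throughout. Deterministic for a
#' given seed.
#'
#' @param cfg A [simulation_config] with `model = "homogeneous"`.
#' @return A `synth_batch`: `curves` (list of [fd_curve]), `manifest`
#'   (per-curve ground truth: id, z0, parameters), `config`.
#' @export
generate_homogeneous <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$model != "homogeneous") stop("cfg$model must be 'homogeneous'",
                                       call. = FALSE)
  .generate_batch(cfg)
}

#' Generate a batch of exponential-bilayer force-distance curves
#'
#' Forward model: the closed-form [bilayer_force] (the integral of the
#' Oliver-Pharr relation over the exponential profile), then the same
#' displacement mapping and noise model as [generate_homogeneous]. With
#' `E0 = Eb` the output reduces exactly to the homogeneous generator.
#'
#' @param cfg A [simulation_config] with `model = "bilayer_exponential"`.
#' @return A `synth_batch` (see [generate_homogeneous]).
#' @export
generate_bilayer <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$model != "bilayer_exponential")
    stop("cfg$model must be 'bilayer_exponential'", call. = FALSE)
  .generate_batch(cfg)
}

#' Generate the synthetic layered-contact reference curve
#'
#' A single noiseless force-distance curve from the stress-weighted
#' sharp-interface layered model ([surrogate_force]). This is a
#' synthetic stand-in for finite-element layered-contact data: its decay
#' law differs from the exponential fit model, so fitting it exercises
#' genuine model mismatch (thick-film and thin-film limits reduce to
#' Hertz curves at E0 and Eb respectively).
#'
#' @param cfg A [simulation_config] with `model = "bilayer_fea_surrogate"`;
#'   noise and contact randomisation are ignored (the reference curve is
#'   noiseless, with a fixed contact point).
#' @return A `synth_batch` containing one noiseless [fd_curve].
#' @export
generate_fea_surrogate <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$model != "bilayer_fea_surrogate")
    stop("cfg$model must be 'bilayer_fea_surrogate'", call. = FALSE)
  if (cfg$d0 > 2 * cfg$R)
    stop("range error: surrogate assumes a thin film (d0 <= 2 R)",
         call. = FALSE)
  cfg$noise_sigma_F <- 0
  cfg$contact_offset_z0 <- mean(cfg$contact_offset_z0)
  cfg$n_curves <- 1L
  .generate_batch(cfg)
}

#' Exact force-indentation curve for a simulation config
#'
#' Bypasses the displacement mapping and noise model and evaluates the
#' configured force model directly on a depth grid — the ground-truth
#' F(delta) that the preprocessing stages are expected to recover.
#'
#' @param cfg A [simulation_config].
#' @param delta_max Maximum depth (m); default 1.2 um.
#' @param step Depth step (m); default `cfg$sampling_step`.
#' @return An [fi_curve].
#' @export
true_force_indentation <- function(cfg, delta_max = 1.2e-6, step = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  step <- step %||% cfg$sampling_step
  delta <- seq(0, delta_max, by = step)
  f <- .force_model(cfg)(delta)
  fi_curve(delta, f, contact_point_z = 0,
           metadata = acq_metadata(cfg$R, cfg$k, cfg$nu, label = cfg$model),
           id = paste0(cfg$model, "_truth"))
}
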