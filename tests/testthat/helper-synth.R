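# Shared fixtures: all synthetic, built in code at test time.

# reference sharp-probe bilayer geometry: the contact radius sqrt(R*delta)
# sweeps through d0 over the 25-800 nm working range
ref_truth <- list(E0 = 9800, Eb = 8400, d0 = 300e-9)
ref_R <- 300e-9

ref_bilayer_cfg <- function(model = "bilayer_exponential", ...) {
  args <- list(model = model, E0 = ref_truth$E0, Eb = ref_truth$Eb,
               d0 = ref_truth$d0, R = ref_R,
               contact_offset_z0 = 1e-6, noise_sigma_F = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

# gel-style homogeneous acquisition (ferrule-top probe constants)
gel_metadata <- function() acq_metadata(8e-6, 0.049, 0.5)

gel_cfg <- function(n_curves = 10L, seed = 1L, noise_sigma_F = 20e-12,
                    E = 5200, ...) {
  simulation_config("homogeneous", E = E, R = 8e-6, k = 0.049,
                    z_range = 4e-6, sampling_step = 2e-9,
                    contact_offset_z0 = c(0.8e-6, 2e-6),
                    noise_sigma_F = noise_sigma_F, n_curves = n_curves,
                    seed = seed, ...)
}

# noiseless ideal force-indentation curve for a given modulus profile
ideal_hertz_fi <- function(E = 5000, R = 8e-6, depth = 1e-6, step = 2e-9,
                           k = 0.049) {
  d <- seq(0, depth, by = step)
  fi_curve(d, hertz_force(d, E, R), 0, acq_metadata(R, k))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
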