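test_that("the closed-form bilayer force agrees with numerical quadrature", {
  E0 <- 9800; Eb <- 8400; d0 <- 300e-9; R <- ref_R; lam <- 1.74; nu <- 0.5
  for (dd in c(25e-9, 300e-9, 800e-9)) {
    oracle <- stats::integrate(function(t)
      2 * sqrt(R * t) * bilayer_profile(t, E0, Eb, d0, R, lam) / (1 - nu^2),
      0, dd, rel.tol = 1e-10)$value
    expect_equal(bilayer_force(dd, E0, Eb, d0, R, lam), oracle,
                 tolerance = 1e-8)
  }
})

test_that("generated batches are deterministic given the seed", {
  b1 <- generate_homogeneous(gel_cfg(n_curves = 3L, seed = 5L))
  b2 <- generate_homogeneous(gel_cfg(n_curves = 3L, seed = 5L))
  expect_identical(b1$manifest, b2$manifest)
  for (j in 1:3)
    expect_identical(b1$curves[[j]]$force, b2$curves[[j]]$force)
  b3 <- generate_homogeneous(gel_cfg(n_curves = 3L, seed = 6L))
  expect_false(identical(b1$curves[[1]]$force, b3$curves[[1]]$force))
})

test_that("a seed is demanded whenever the output is stochastic", {
  expect_error(simulation_config("homogeneous", noise_sigma_F = 1e-12,
                                 contact_offset_z0 = 1e-6),
               "seed is mandatory")
  expect_silent(simulation_config("homogeneous", noise_sigma_F = 0,
                                  contact_offset_z0 = 1e-6))
})

test_that("the bilayer generator reduces to Hertz when E0 = Eb", {
  cfg_b <- simulation_config("bilayer_exponential", E0 = 8400, Eb = 8400,
                             d0 = 300e-9, R = ref_R,
                             contact_offset_z0 = 1e-6, noise_sigma_F = 0)
  cfg_h <- simulation_config("homogeneous", E = 8400, R = ref_R,
                             contact_offset_z0 = 1e-6, noise_sigma_F = 0)
  bb <- generate_bilayer(cfg_b)
  bh <- generate_homogeneous(cfg_h)
  expect_equal(bb$curves[[1]]$force, bh$curves[[1]]$force, tolerance = 1e-12)
})

test_that("bilayer force curves are strictly increasing and superlinear", {
  d <- seq(1e-9, 1e-6, by = 1e-9)
  f <- bilayer_force(d, 9800, 8400, 300e-9, ref_R, 1.74)
  expect_true(all(diff(f) > 0))
  # steeper than linear at depth: local exponent d log F / d log delta > 1
  expo <- diff(log(f)) / diff(log(d))
  expect_true(all(expo > 1))
})

test_that("the layered surrogate reaches both film limits", {
  # thick film limit probed at shallow depth so the contact stays inside
  # the film (a << d0): force approaches the Hertz curve at E0
  d <- seq(1e-9, 1e-7, by = 1e-9)
  thick <- surrogate_force(d, 9800, 8400, 600e-9, ref_R)
  expect_lt(max(abs(thick - hertz_force(d, 9800, ref_R)) /
                hertz_force(d, 9800, ref_R)), 0.05)
  d <- seq(1e-9, 4e-7, by = 1e-9)
  thin <- surrogate_force(d, 9800, 8400, 1e-10, ref_R)
  expect_lt(max(abs(thin - hertz_force(d, 8400, ref_R)) /
                hertz_force(d, 8400, ref_R)), 0.02)
  # profile limits are exact
  expect_equal(surrogate_profile(0, 9800, 8400, 3e-7, ref_R), 9800)
  expect_lt(surrogate_profile(1, 9800, 8400, 3e-7, ref_R), 8420)
})

test_that("the surrogate spectrum decays from the layer to the bulk over a
           depth comparable with the thickness", {
  batch <- generate_fea_surrogate(ref_bilayer_cfg("bilayer_fea_surrogate"))
  fi <- to_force_indentation(batch$curves[[1]], batch$manifest$z0[1])
  sp <- pointwise_modulus(fi)
  sel <- sp$delta <= 800e-9
  expect_gt(sp$E[which.min(sp$delta)], 9000)    # near E0 at the surface
  expect_lt(min(sp$E[sel]), 8900)               # decays toward Eb
  expect_true(all(diff(sp$E[sel]) < 0))         # monotone decay
})

test_that("pre-contact noise honesty: baseline RMS matches the configured
           sigma over a batch", {
  cfg <- gel_cfg(n_curves = 100L, seed = 77L)
  batch <- generate_homogeneous(cfg)
  rms <- vapply(seq_along(batch$curves), function(j) {
    cu <- batch$curves[[j]]
    sd(cu$force[cu$z < batch$manifest$z0[j]])
  }, numeric(1))
  expect_rel_equal(mean(rms), cfg$noise_sigma_F, 0.05)
})

test_that("config validation guards impossible geometries", {
  expect_error(simulation_config("homogeneous", contact_offset_z0 = 5e-6,
                                 z_range = 4e-6), "config error")
  expect_error(generate_fea_surrogate(
    ref_bilayer_cfg("bilayer_fea_surrogate", d0 = 1e-6)), "range error")
  cfg <- gel_cfg(n_curves = 1L, seed = 1L)
  expect_error(generate_bilayer(cfg), "bilayer_exponential")
})
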