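test_that("Savitzky-Golay smoothing reproduces polynomials and matches a
           brute-force sliding fit", {
  md <- gel_metadata()
  z <- seq(0, 2e-6, by = 2e-9)
  # cubic signal is invariant under a cubic local fit, including endpoints
  f_cubic <- 1e-9 + 3e-3 * z + 2e3 * z^2 + 1e9 * z^3
  cu <- fd_curve(z, f_cubic, md)
  sm <- smooth_curve(cu, preprocess_config(sg_window = 25e-9, sg_polyorder = 3))
  expect_lt(max(abs(sm$force - f_cubic)) / max(abs(f_cubic)), 1e-12)

  # constant in, constant out
  cu0 <- fd_curve(z, rep(2e-12, length(z)), md)
  expect_equal(smooth_curve(cu0)$force, rep(2e-12, length(z)))

  # noisy line: interior samples must equal a brute-force local LS fit
  set.seed(4)
  f_noisy <- 5e-3 * z + rnorm(length(z), 0, 2e-12)
  cu2 <- fd_curve(z, f_noisy, md)
  cfg <- preprocess_config(sg_window = 25e-9, sg_polyorder = 3)
  sm2 <- smooth_curve(cu2, cfg)
  w <- 13L; h <- 6L # 25 nm / 2 nm -> 13-sample window
  idx <- seq(200L, 220L)
  brute <- vapply(idx, function(i) {
    zi <- z[(i - h):(i + h)]; fi <- f_noisy[(i - h):(i + h)]
    unname(stats::lm.fit(cbind(1, zi - z[i], (zi - z[i])^2,
                               (zi - z[i])^3), fi)$coefficients[1])
  }, numeric(1))
  expect_equal(sm2$force[idx], brute, tolerance = 1e-9)
  # and the analytic variance-reduction factor of the filter is realised
  resid_var <- var((sm2$force - 5e-3 * z)[idx[1]:(idx[1] + 500)])
  expect_lt(resid_var, var(f_noisy - 5e-3 * z)) # strictly smoother
})

test_that("smoothing window larger than the curve is a config error", {
  md <- gel_metadata()
  z <- seq(0, 3e-8, by = 1e-9)
  cu <- fd_curve(z, z * 1e-3, md)
  expect_error(smooth_curve(cu, preprocess_config(sg_window = 1e-6)),
               "config error")
})

test_that("contact point is recovered on synthetic Hertz curves", {
  cfg <- gel_cfg(n_curves = 60L, seed = 42L, E = 5000)
  batch <- generate_homogeneous(cfg)
  errs <- vapply(seq_along(batch$curves), function(j) {
    cp <- find_contact_point(batch$curves[[j]])
    (cp$z0 - batch$manifest$z0[j]) / cfg$sampling_step
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 2), 0.95)
  expect_lt(abs(median(errs)) * cfg$sampling_step, cfg$sampling_step)
})

test_that("contact detection is exactly translation-equivariant", {
  batch <- generate_homogeneous(gel_cfg(n_curves = 1L, seed = 7L))
  cu <- batch$curves[[1]]
  shift <- 3.3e-7
  cu2 <- fd_curve(cu$z + shift, cu$force, cu$metadata)
  cp1 <- find_contact_point(cu)
  cp2 <- find_contact_point(cu2)
  expect_equal(cp2$z0 - cp1$z0, shift, tolerance = 1e-12)
})

test_that("pure noise yields contact-not-found", {
  set.seed(10)
  md <- gel_metadata()
  cu <- fd_curve(seq(0, 2e-6, by = 2e-9),
                 rnorm(1001, 0, 20e-12), md)
  expect_error(find_contact_point(cu), "contact-not-found")
})

test_that("on a noiseless kink the RoV trace peaks at the contact and the
           last peak is the global peak", {
  md <- gel_metadata()
  z <- seq(0, 2e-6, by = 4e-9)
  z0 <- 1e-6
  set.seed(5)
  f <- hertz_force(pmax(z - z0, 0), 5000, 8e-6) +
    c(rnorm(sum(z < z0), 0, 5e-12), numeric(sum(z >= z0))) # noise floor only
  cu <- fd_curve(z, f, md)
  cp <- find_contact_point(cu, refine = FALSE)
  imax <- which.max(cp$rov$rov)
  # the global RoV maximum sits at the kink, and the selected last peak
  # coincides with it
  expect_lt(abs(cp$rov$z[imax] - z0), 60e-9)
  expect_equal(cu$z[cp$rov_peak_index], cp$rov$z[imax], tolerance = 1e-12)
})

test_that("force-indentation conversion respects the cantilever limits", {
  md_stiff <- acq_metadata(8e-6, 1e6) # essentially rigid cantilever
  z <- seq(0, 2e-6, by = 2e-9)
  z0 <- 5e-7
  f <- hertz_force(pmax(z - z0, 0), 5000, 8e-6)
  cu <- fd_curve(z, f, md_stiff)
  fi <- to_force_indentation(cu, z0)
  expect_equal(fi$delta, (z[z >= z0] - z0)[seq_along(fi$delta)],
               tolerance = 1e-6)

  # infinitely stiff sample: F = k (z - z0) puts all motion in deflection
  k <- 0.049
  md <- acq_metadata(8e-6, k)
  cu2 <- fd_curve(z, pmax(z - z0, 0) * k, md)
  fi2 <- to_force_indentation(cu2, z0)
  expect_lt(max(fi2$delta), 1e-15)

  # generator round trip: recovered F(delta) matches ground truth
  cfg <- ref_bilayer_cfg()
  batch <- generate_bilayer(cfg)
  fi3 <- to_force_indentation(batch$curves[[1]], batch$manifest$z0[1])
  truth <- bilayer_force(fi3$delta, ref_truth$E0, ref_truth$Eb, ref_truth$d0,
                         ref_R, 1.74)
  sel <- fi3$delta > 10e-9
  expect_lt(max(abs(fi3$force[sel] - truth[sel]) / truth[sel]), 0.01)

  expect_error(to_force_indentation(cu, 9e-6), "outside")
  expect_error(to_force_indentation(cu, max(z)), "pre-contact")
})

test_that("force values are preserved by conversion (only re-indexed)", {
  batch <- generate_homogeneous(gel_cfg(n_curves = 1L, seed = 2L))
  cu <- batch$curves[[1]]
  z0 <- batch$manifest$z0[1]
  fi <- to_force_indentation(cu, z0)
  expect_true(all(fi$force %in% cu$force))
})

test_that("QC rejects tilted baselines and gross noise, accepts clean curves", {
  cfg <- gel_cfg(n_curves = 6L, seed = 8L)
  batch <- generate_homogeneous(cfg)
  cu <- batch$curves[[1]]
  z0 <- batch$manifest$z0[1]

  clean <- qc_filter(cu, z0)
  expect_true(clean$accepted)
  expect_length(clean$reasons, 0L)

  tilt <- 1e-3 # N/m, strong baseline slope vs 20 pN noise
  f_tilt <- cu$force + ifelse(cu$z < z0, tilt * (cu$z - z0), 0)
  r_tilt <- qc_filter(fd_curve(cu$z, f_tilt, cu$metadata), z0)
  expect_false(r_tilt$accepted)
  expect_true("no_flat_region" %in% r_tilt$reasons)

  # 50x nominal noise on one curve of a batch -> high_noise
  noisy <- batch$curves
  set.seed(1)
  noisy[[6]] <- fd_curve(cu$z, cu$force + rnorm(length(cu$z), 0, 1e-9),
                         cu$metadata)
  tab <- qc_batch(noisy, batch$manifest$z0)
  expect_true(all(tab$accepted[1:5]))
  expect_false(tab$accepted[6])
  expect_match(tab$reasons[6], "high_noise")

  missing <- qc_filter(cu, NA)
  expect_false(missing$accepted)
  expect_identical(missing$reasons, "no_contact_point")
  # report invariant: accepted <=> no reasons
  for (r in list(clean, r_tilt, missing))
    expect_identical(r$accepted, length(r$reasons) == 0L)
})

test_that("a large homogeneous batch passes QC at a high rate", {
  cfg <- gel_cfg(n_curves = 100L, seed = 21L)
  batch <- generate_homogeneous(cfg)
  z0s <- vapply(batch$curves, function(cu) {
    cp <- tryCatch(find_contact_point(cu), error = function(e) NULL)
    if (is.null(cp)) NA_real_ else cp$z0
  }, numeric(1))
  tab <- qc_batch(batch$curves, z0s)
  expect_gte(mean(tab$accepted), 0.95)
})
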