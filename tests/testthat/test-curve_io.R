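test_that("canonical curve files round-trip through write/read", {
  cfg <- gel_cfg(n_curves = 2L, seed = 3L)
  batch <- generate_homogeneous(cfg)
  for (dialect in c("csv2col", "tsv2col")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_curve(batch$curves[[1]], path, dialect)
    back <- read_curve(path, dialect)
    expect_equal(back$z, batch$curves[[1]]$z, tolerance = 1e-8)
    expect_equal(back$force, batch$curves[[1]]$force, tolerance = 1e-8)
    expect_equal(back$metadata$probe_radius, 8e-6)
    expect_equal(back$metadata$spring_constant, 0.049)
  }
})

test_that("header metadata is parsed into SI acquisition constants", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049",
               paste(seq(0, 1.5e-6, length.out = 20),
                     seq(0, 1e-9, length.out = 20), sep = ",")), path)
  cu <- read_curve(path, "csv2col")
  expect_equal(cu$metadata$probe_radius, 8e-6)
  expect_equal(cu$metadata$spring_constant, 0.049)
  expect_equal(cu$metadata$poisson_ratio, 0.5) # default when nu missing
})

test_that("declared nm/nN units give the same curve as the SI file", {
  z <- seq(0, 2e-6, length.out = 32)
  f <- seq(0, 5e-9, length.out = 32)
  si <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049",
               paste(z, f, sep = ",")), si)
  scaled <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049",
               "# z_unit nm", "# F_unit nN",
               paste(z * 1e9, f * 1e9, sep = ",")), scaled)
  a <- read_curve(si, "csv2col"); b <- read_curve(scaled, "csv2col")
  expect_equal(a$z, b$z)
  expect_equal(a$force, b$force)
})

test_that("malformed files fail with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049"), p)
  expect_error(read_curve(p, "csv2col"), "no data rows")

  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049",
               "0,0", "1e-9,abc", "2e-9,0"), p)
  expect_error(read_curve(p, "csv2col"), "row 2")

  writeLines(c("# radius_m 8e-6",
               paste(seq(0, 1e-6, length.out = 20), 0, sep = ",")), p)
  expect_error(read_curve(p, "csv2col"), "metadata")

  expect_error(read_curve(file.path(tempdir(), "nope.csv"), "csv2col"),
               "not found")
})

test_that("approach segment is extracted from approach+retract records", {
  z_app <- seq(0, 2e-6, by = 5e-8)
  f_app <- pmax(z_app - 1e-6, 0)^1.5 * 1e4
  z_ret <- rev(z_app)[-1]
  f_ret <- pmax(z_ret - 1.05e-6, 0)^1.5 * 1e4
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# radius_m 8e-6", "# k_N_per_m 0.049",
               paste(c(z_app, z_ret), c(f_app, f_ret), sep = ",")), p)
  cu <- read_curve(p, "csv2col")
  expect_false(is.unsorted(cu$z))
  expect_equal(max(cu$force), max(f_app))
})

test_that("result records serialize losslessly and reject empty spectra", {
  # headline parameter set survives a JSON round trip bit-exactly
  spec <- mean_spectrum(seq(25e-9, 100e-9, by = 5e-9),
                        rep(9000, 16), rep(100, 16), rep(3L, 16))
  fake_fit <- structure(list(E0_Pa = 9770, Eb_Pa = 8390, d0_m = 302e-9,
                             lambda_used = 1.74,
                             param_se = c(E0 = 10, Eb = 5, d0 = 1e-9),
                             fit_rms_Pa = 12.3, n_points = 16L,
                             fit_range_m = c(25e-9, 100e-9),
                             inverted = FALSE, degenerate = FALSE),
                        class = "bilayer_fit")
  stem <- file.path(withr::local_tempdir(), "res")
  files <- write_results(fake_fit, spec, stem)
  rec <- read_results(files[["json"]])
  expect_equal(rec$bilayer$E0_Pa, 9770)
  expect_equal(rec$bilayer$Eb_Pa, 8390)
  expect_equal(rec$bilayer$d0_m, 302e-9)
  csv <- read.csv(files[["spectrum"]])
  expect_equal(csv$E_mean_Pa, spec$E_mean)

  empty <- mean_spectrum(seq(25e-9, 100e-9, by = 5e-9),
                         rep(NA_real_, 16), rep(0, 16), rep(0L, 16))
  expect_error(write_results(fake_fit, empty, stem), "0 curves")
})

test_that("curve validation rejects inconsistent inputs", {
  md <- gel_metadata()
  expect_error(fd_curve(1:10 * 1e-9, 1:9 * 1e-12, md), "same length")
  expect_error(fd_curve(rev(1:20) * 1e-9, 1:20 * 1e-12, md), "non-decreasing")
  expect_error(fd_curve(1:20 * 1e-9, c(NA, 2:20) * 1e-12, md), "finite")
  expect_error(acq_metadata(-1e-6, 0.05), "probe_radius")
  expect_error(acq_metadata(8e-6, 0.05, poisson_ratio = 0.7), "poisson")
})
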