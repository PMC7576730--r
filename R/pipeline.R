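#' Run the full elasticity-spectra pipeline on a batch of curves
#'
#' Orchestrates the standard analysis chain on in-memory curves:
#' smoothing, ratio-of-variances contact-point detection, conversion to
#' force-indentation, quality control, per-curve Hertz fits, per-curve
#' elasticity spectra, spectrum averaging, working-range selection and
#' the exponential bilayer fit. Individual curve failures are recorded
#' and skipped; the run continues with the remaining curves.
#'
#' @param curves List of [fd_curve] objects.
#' @param cfg A [preprocess_config].
#' @param lam Bilayer decay factor (default 1.74).
#' @param hard_cap Maximum trusted depth (m) for the working range
#'   (default 800 nm).
#' @param hertz_delta_max Fit range cap for the per-curve Hertz fits;
#'   default `min(800e-9, 0.1 * R)`.
#' @param do_hertz,do_spectra,do_bilayer Stage toggles.
#' @param derivative_step Depth step of the spectrum derivative (m).
#' @return A list of class `es_analysis`: `qc` (data.frame), `hertz`
#'   ([population_peak] result or NULL), `hertz_fits`, `spectrum`
#'   ([mean_spectrum]), `working_range`, `bilayer` (`bilayer_fit`),
#'   `n_total`, `n_accepted`, `errors` (per-curve messages).
#' @export
analyze_curves <- function(curves, cfg = preprocess_config(), lam = 1.74,
                           hard_cap = 800e-9, hertz_delta_max = NULL,
                           do_hertz = TRUE, do_spectra = TRUE,
                           do_bilayer = TRUE, derivative_step = 25e-9) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "fd_curve")))
  n <- length(curves)
  errors <- character(0)
  smoothed <- vector("list", n)
  z0s <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    res <- tryCatch({
      sm <- smooth_curve(curves[[j]], cfg)
      # contact detection runs on the raw force: the refinement step is a
      # least-squares fit (its own noise handling) and pre-smoothing would
      # correlate the residuals it relies on
      cp <- find_contact_point(curves[[j]], cfg)
      list(sm = sm, z0 = cp$z0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      smoothed[[j]] <- curves[[j]]
      errors <- c(errors, paste0(curves[[j]]$id, ": ", conditionMessage(res)))
    } else {
      smoothed[[j]] <- res$sm
      z0s[j] <- res$z0
    }
  }
  qc <- qc_batch(smoothed, z0s, cfg)
  acc <- which(qc$accepted)
  if (!length(acc))
    stop("all curves rejected by QC", call. = FALSE)

  fis <- vector("list", length(acc))
  keep <- logical(length(acc))
  for (u in seq_along(acc)) {
    j <- acc[u]
    res <- tryCatch(to_force_indentation(smoothed[[j]], z0s[j], cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(smoothed[[j]]$id, ": ",
                                 conditionMessage(res)))
    } else { fis[[u]] <- res; keep[u] <- TRUE }
  }
  fis <- fis[keep]
  if (!length(fis)) stop("no curve survived conversion", call. = FALSE)

  hertz_fits <- NULL; hertz_pop <- NULL
  if (do_hertz) {
    hertz_fits <- list()
    for (fi in fis) {
      hf <- tryCatch(fit_hertz(fi, delta_max = hertz_delta_max),
                     error = function(e) e)
      if (inherits(hf, "error"))
        errors <- c(errors, paste0(fi$id, ": ", conditionMessage(hf)))
      else hertz_fits[[length(hertz_fits) + 1L]] <- hf
    }
    if (length(hertz_fits) >= 10L)
      hertz_pop <- population_peak(vapply(hertz_fits, `[[`, numeric(1), "E"))
  }

  spectrum <- NULL; wr <- NULL; bl <- NULL
  if (do_spectra) {
    spectra <- list()
    for (fi in fis) {
      sp <- tryCatch(pointwise_modulus(fi, derivative_step = derivative_step),
                     error = function(e) e)
      if (inherits(sp, "error"))
        errors <- c(errors, paste0(fi$id, ": ", conditionMessage(sp)))
      else spectra[[length(spectra) + 1L]] <- sp
    }
    if (length(spectra)) {
      spectrum <- average_spectra(spectra)
      wr <- select_working_range(spectrum, hard_cap = hard_cap)
      if (do_bilayer) {
        R <- fis[[1]]$metadata$probe_radius
        bl <- tryCatch(fit_bilayer(spectrum, R = R, lam = lam, range = wr),
                       error = function(e) {
                         errors <<- c(errors,
                                      paste0("bilayer: ", conditionMessage(e)))
                         NULL
                       })
      }
    }
  }

  structure(list(qc = qc, hertz = hertz_pop, hertz_fits = hertz_fits,
                 spectrum = spectrum, working_range = wr, bilayer = bl,
                 n_total = n, n_accepted = length(fis), errors = errors),
            class = "es_analysis")
}

#' @export
print.es_analysis <- function(x, ...) {
  cat(sprintf("Elasticity-spectra analysis: %d/%d curves accepted\n",
              x$n_accepted, x$n_total))
  if (!is.null(x$hertz)) print(x$hertz)
  if (!is.null(x$working_range))
    cat(sprintf("Working range: %.0f-%.0f nm\n", x$working_range[1] * 1e9,
                x$working_range[2] * 1e9))
  if (!is.null(x$bilayer)) print(x$bilayer)
  if (length(x$errors)) cat(length(x$errors), "per-curve issue(s) logged\n")
  invisible(x)
}

#' Analyze a directory (or explicit set) of curve files
#'
#' File-level front end of [analyze_curves]: reads every curve, runs the
#' pipeline and writes `results.json`, `results_spectrum.csv`,
#' `per_curve.csv`, `qc.csv` and `run.log` to `out_dir`.
#'
#' @param input Directory containing curve files, or a character vector
#'   of file paths.
#' @param out_dir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @param dialect Curve file dialect (see [read_curve]).
#' @param metadata Optional [acq_metadata] applied to all files.
#' @param ... Passed to [analyze_curves].
#' @return The `es_analysis` result, invisibly.
#' @export
es_analyze <- function(input, out_dir = NULL, dialect = "csv2col",
                       metadata = NULL, ...) {
  files <- if (length(input) == 1L && dir.exists(input))
    list.files(input, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
  else input
  if (!length(files)) stop("no curves found", call. = FALSE)
  curves <- list(); read_errors <- character(0)
  for (f in files) {
    cu <- tryCatch(read_curve(f, dialect, metadata = metadata),
                   error = function(e) e)
    if (inherits(cu, "error"))
      read_errors <- c(read_errors, paste0(f, ": ", conditionMessage(cu)))
    else curves[[length(curves) + 1L]] <- cu
  }
  if (!length(curves))
    stop("no curves found: all files failed to parse", call. = FALSE)
  res <- analyze_curves(curves, ...)
  res$errors <- c(read_errors, res$errors)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    blocks <- Filter(Negate(is.null), list(res$bilayer, res$hertz))
    write_results(blocks, res$spectrum, file.path(out_dir, "results"),
                  config = list(n_total = res$n_total,
                                n_accepted = res$n_accepted,
                                working_range_m = res$working_range))
    utils::write.csv(res$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    if (length(res$hertz_fits)) {
      pc <- data.frame(E_Pa = vapply(res$hertz_fits, `[[`, numeric(1), "E"),
                       residual_rms_N = vapply(res$hertz_fits, `[[`,
                                               numeric(1), "residual_rms"))
      utils::write.csv(pc, file.path(out_dir, "per_curve.csv"),
                       row.names = FALSE)
    }
    writeLines(c(sprintf("elastispec %s",
                         utils::packageVersion("elastispec")),
                 sprintf("curves in: %d, accepted: %d, rejected: %d",
                         res$n_total, res$n_accepted,
                         res$n_total - res$n_accepted),
                 res$errors),
               file.path(out_dir, "run.log"))
  }
  invisible(res)
}

#' Simulate a batch of curves and write them to disk
#'
#' Generates curves from a [simulation_config] and writes one file per
#' curve in the canonical dialect plus a ground-truth manifest
#' (`manifest.json`) holding the per-curve contact point and generating
#' parameters.
#'
#' @param cfg A [simulation_config].
#' @param out_dir Output directory.
#' @param dialect Output dialect (see [write_curve]).
#' @return The `synth_batch`, invisibly.
#' @export
es_simulate <- function(cfg, out_dir, dialect = "csv2col") {
  stopifnot(inherits(cfg, "simulation_config"))
  batch <- switch(cfg$model,
                  homogeneous = generate_homogeneous(cfg),
                  bilayer_exponential = generate_bilayer(cfg),
                  bilayer_fea_surrogate = generate_fea_surrogate(cfg))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "csv2col") ".csv" else ".tsv"
  for (cu in batch$curves)
    write_curve(cu, file.path(out_dir, paste0(cu$id, ext)), dialect)
  jsonlite::write_json(
    c(as.list(batch$manifest),
      list(model = cfg$model, seed = cfg$seed)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(batch)
}

#' Calibrate lambda on the synthetic layered reference curve
#'
#' Generates the layered-contact reference curve (the stress-weighted
#' synthetic surrogate by default, or the self-consistent exponential
#' generator when `cfg$model = "bilayer_exponential"`), converts it to a
#' force-indentation curve using the known contact point, and runs
#' [calibrate_lambda] with the generating (E0, Eb, d0) held fixed.
#' Optionally repeats the calibration over a physiological parameter
#' sweep to quantify how stable the calibrated value is.
#'
#' @param cfg A [simulation_config] for a bilayer model; default: the
#'   surrogate at E0 = 9.8 kPa, Eb = 8.4 kPa, d0 = 300 nm.
#' @param sweep If `TRUE`, re-calibrate over a grid of stiffness ratios
#'   (E0/Eb in 1.05-2) and thicknesses (d0 in 200-500 nm).
#' @param range Depth range for the calibration fit (m); default
#'   c(25e-9, 800e-9).
#' @return A list of class `lambda_report`: `calibration`
#'   (the [calibrate_lambda] result), `sweep` (data.frame or NULL),
#'   `spread` (max relative deviation across the sweep, or NA).
#' @export
es_calibrate_lambda <- function(cfg = NULL, sweep = FALSE,
                                range = c(25e-9, 800e-9)) {
  if (is.null(cfg))
    cfg <- simulation_config(model = "bilayer_fea_surrogate",
                             E0 = 9800, Eb = 8400, d0 = 300e-9, R = 300e-9,
                             contact_offset_z0 = 1e-6, noise_sigma_F = 0)
  run_one <- function(cfg) {
    batch <- if (cfg$model == "bilayer_fea_surrogate")
      generate_fea_surrogate(cfg) else generate_bilayer(cfg)
    cu <- batch$curves[[1]]
    fi <- to_force_indentation(cu, batch$manifest$z0[1])
    calibrate_lambda(fi, truth = list(E0 = cfg$E0, Eb = cfg$Eb, d0 = cfg$d0),
                     range = range)
  }
  cal <- run_one(cfg)
  sw <- NULL; spread <- NA_real_
  if (sweep) {
    grid <- expand.grid(ratio = c(1.05, 1.17, 1.5, 2),
                        d0 = c(200e-9, 300e-9, 400e-9, 500e-9))
    lam_hat <- vapply(seq_len(nrow(grid)), function(i) {
      ci <- cfg
      ci$E0 <- ci$Eb * grid$ratio[i]
      ci$d0 <- grid$d0[i]
      run_one(ci)$lambda
    }, numeric(1))
    sw <- cbind(grid, lambda = lam_hat)
    spread <- (max(lam_hat) - min(lam_hat)) / stats::median(lam_hat)
  }
  structure(list(calibration = cal, sweep = sw, spread = spread),
            class = "lambda_report")
}

#' @export
print.lambda_report <- function(x, ...) {
  print(x$calibration)
  if (!is.null(x$sweep))
    cat(sprintf("Sweep over %d parameter sets: lambda %.3g-%.3g (spread %.1f%%)\n",
                nrow(x$sweep), min(x$sweep$lambda), max(x$sweep$lambda),
                100 * x$spread))
  invisible(x)
}
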