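#' @importFrom utils read.table write.csv packageVersion head tail
NULL

.unit_factors <- list(
  z = c(m = 1, mm = 1e-3, um = 1e-6, nm = 1e-9),
  F = c(N = 1, mN = 1e-3, uN = 1e-6, nN = 1e-9, pN = 1e-12)
)

.parse_header <- function(lines) {
  hdr <- grep("^\\s*#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    body <- sub("^\\s*#\\s*", "", h)
    parts <- strsplit(trimws(body), "\\s+")[[1]]
    if (length(parts) >= 2) out[[parts[1]]] <- parts[2]
  }
  out
}

#' Read a force-distance curve from a delimited text file
#'
#' The canonical on-disk format is a two-column numeric table (z, F) with
#' `#`-prefixed metadata header lines. Recognised header keys:
#' `radius_m`, `k_N_per_m`, `nu`, `speed_m_per_s`, `label`, and optional
#' `z_unit` / `F_unit` (one of m/mm/um/nm and N/mN/uN/nN/pN) when the
#' columns are not already SI. If a file holds an approach and a retract
#' segment, the approach segment (increasing z up to the force maximum)
#' is used.
#'
#' @param path File to read.
#' @param dialect `"csv2col"` (comma) or `"tsv2col"` (tab/whitespace).
#' @param metadata Optional [acq_metadata] overriding the file header.
#' @return An [fd_curve] in SI units.
#' @export
read_curve <- function(path, dialect = c("csv2col", "tsv2col"),
                       metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- .parse_header(lines)
  data_lines <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  if (length(data_lines) == 0L)
    stop("parse error: no data rows in ", path, call. = FALSE)
  sep <- if (dialect == "csv2col") "," else ""
  tab <- tryCatch(
    read.table(text = data_lines, sep = sep, header = FALSE,
               colClasses = "numeric", fill = FALSE),
    error = function(e) NULL)
  if (is.null(tab) || ncol(tab) < 2L) {
    # locate the first offending row for the error message
    for (i in seq_along(data_lines)) {
      flds <- strsplit(trimws(data_lines[i]),
                       if (dialect == "csv2col") "," else "\\s+")[[1]]
      if (length(flds) < 2L || anyNA(suppressWarnings(as.numeric(flds[1:2]))))
        stop(sprintf("parse error at data row %d of %s", i, path), call. = FALSE)
    }
    stop("format error: expected 2 numeric columns in ", path, call. = FALSE)
  }
  z <- tab[[1]]; force <- tab[[2]]
  if (anyNA(z) || anyNA(force)) {
    bad <- which(is.na(z) | is.na(force))[1]
    stop(sprintf("parse error at data row %d of %s", bad, path), call. = FALSE)
  }
  zf <- .unit_factors$z[hdr$z_unit %||% "m"]
  ff <- .unit_factors$F[hdr$F_unit %||% "N"]
  if (is.na(zf)) stop("unknown z_unit: ", hdr$z_unit, call. = FALSE)
  if (is.na(ff)) stop("unknown F_unit: ", hdr$F_unit, call. = FALSE)
  z <- z * unname(zf); force <- force * unname(ff)

  if (is.null(metadata)) {
    if (is.null(hdr$radius_m) || is.null(hdr$k_N_per_m))
      stop("metadata error: header must provide radius_m and k_N_per_m ",
           "(or pass metadata=)", call. = FALSE)
    metadata <- acq_metadata(
      probe_radius   = as.numeric(hdr$radius_m),
      spring_constant = as.numeric(hdr$k_N_per_m),
      poisson_ratio  = as.numeric(hdr$nu %||% 0.5),
      approach_speed = as.numeric(hdr$speed_m_per_s %||% NA),
      label          = hdr$label %||% "")
  }

  seg <- .approach_segment(z, force)
  fd_curve(z[seg], force[seg], metadata,
           id = sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# approach segment: the run of non-decreasing z ending at the force maximum
.approach_segment <- function(z, force) {
  imax <- which.max(force)
  start <- 1L
  if (imax > 1L) {
    dz <- diff(z[1:imax])
    drops <- which(dz < 0)
    if (length(drops)) start <- max(drops) + 1L
  }
  start:imax
}

#' Write a synthetic or measured curve in the canonical dialect
#'
#' @param curve An [fd_curve].
#' @param path Output file.
#' @param dialect `"csv2col"` or `"tsv2col"`.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, dialect = c("csv2col", "tsv2col")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(curve, "fd_curve"))
  md <- curve$metadata
  hdr <- c(sprintf("# radius_m %.9g", md$probe_radius),
           sprintf("# k_N_per_m %.9g", md$spring_constant),
           sprintf("# nu %.9g", md$poisson_ratio))
  if (is.finite(md$approach_speed))
    hdr <- c(hdr, sprintf("# speed_m_per_s %.9g", md$approach_speed))
  if (nzchar(md$label)) hdr <- c(hdr, paste("# label", md$label))
  sep <- if (dialect == "csv2col") "," else "\t"
  body <- paste(sprintf("%.9e", curve$z), sprintf("%.9e", curve$force),
                sep = sep)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write analysis results (JSON) and the mean spectrum (CSV)
#'
#' Emits a JSON record with the fitted parameters, their uncertainties,
#' curve counts and a configuration echo, plus a CSV table of the mean
#' elasticity spectrum (`delta_m, E_mean_Pa, E_std_Pa, n`). All numbers
#' are serialized at full double precision so a round trip through disk
#' is lossless.
#'
#' @param fit A [fit_bilayer] result, a [population_peak] result, or a
#'   named list containing either/both under `bilayer` / `hertz`.
#' @param spectrum A [mean_spectrum] (or NULL to skip the CSV).
#' @param path Output stem: `<path>.json` and `<path>_spectrum.csv`.
#' @param config Optional list echoed verbatim into the JSON.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(fit, spectrum = NULL, path, config = NULL) {
  rec <- list(software = "elastispec",
              version = as.character(utils::packageVersion("elastispec")))
  add_block <- function(rec, x) {
    if (inherits(x, "bilayer_fit")) rec$bilayer <- unclass(x)
    else if (inherits(x, "hertz_population")) rec$hertz <- unclass(x)
    else if (inherits(x, "session_aggregate")) rec$sessions <- unclass(x)
    else if (is.list(x)) for (nm in names(x)) rec <- add_block(rec, x[[nm]])
    else stop("unsupported result object", call. = FALSE)
    rec
  }
  rec <- add_block(rec, fit)
  if (!is.null(config)) rec$config <- config
  if (!is.null(spectrum)) {
    stopifnot(inherits(spectrum, "mean_spectrum"))
    if (all(spectrum$n == 0L))
      stop("validation error: mean spectrum built from 0 curves", call. = FALSE)
    rec$n_spectrum_points <- length(spectrum$delta)
  }
  json_path <- paste0(path, ".json")
  jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  written <- c(json = json_path)
  if (!is.null(spectrum)) {
    csv_path <- paste0(path, "_spectrum.csv")
    write.csv(as.data.frame(spectrum), csv_path, row.names = FALSE)
    written <- c(written, spectrum = csv_path)
  }
  invisible(written)
}

#' Read back a JSON result record written by [write_results]
#' @param path JSON file path.
#' @return The parsed record as a list.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
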