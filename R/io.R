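#' @title Tabular readers and writers
#' @description CSV schemas shared by the analysis drivers. All files are
#'   comma-separated UTF-8; metadata travel in `#`-prefixed header lines of
#'   the form `# key=value`.
#' @name io
NULL

read_metadata_header <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*)$", meta_lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3L) out[[m[2L]]] <- type.convert(trimws(m[3L]), as.is = TRUE)
  }
  out
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       check.names = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  }
  for (cn in required) {
    v <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(v) & !is.na(d[[cn]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column `%s`, row %d of %s",
                   cn, bad[1L], basename(path)))
    }
  }
  d
}

#' Read a titration series from a wide CSV
#'
#' First column: denaturant concentration (M); remaining columns: one
#' wavelength each, header row giving the wavelengths. Columns may appear in
#' any order as long as the denaturant column is named `denaturant`.
#'
#' @param path CSV path.
#' @param probe Probe label for the resulting series.
#' @return A [titration_series()].
#' @export
read_titration_csv <- function(path, probe = "fluorescence") {
  d <- read_checked_csv(path, "denaturant")
  ord <- order(d$denaturant)
  d <- d[ord, , drop = FALSE]
  wl_cols <- setdiff(names(d), "denaturant")
  m <- t(as.matrix(d[, wl_cols, drop = FALSE]))
  titration_series(d$denaturant, m, channels = wl_cols, probe = probe)
}

#' Write a titration series to the wide CSV schema
#' @param series A [titration_series()].
#' @param path Output path.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  d <- data.frame(denaturant = series$denaturant_concs,
                  t(series$signal_matrix), check.names = FALSE)
  names(d) <- c("denaturant", series$channels)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a kinetic trace CSV
#'
#' Columns `time`, `signal`; optional metadata lines `# denaturant=` and
#' `# dead_time=`.
#'
#' @param path CSV path.
#' @return A [kinetic_trace()].
#' @export
read_trace_csv <- function(path) {
  meta <- read_metadata_header(path)
  d <- read_checked_csv(path, c("time", "signal"))
  kinetic_trace(d$time, d$signal,
                final_denaturant = if (!is.null(meta$denaturant)) meta$denaturant else NA_real_,
                dead_time = if (!is.null(meta$dead_time)) meta$dead_time else 0.002)
}

#' Write a kinetic trace CSV
#' @param trace A [kinetic_trace()].
#' @param path Output path.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# denaturant=%g", trace$final_denaturant),
               sprintf("# dead_time=%g", trace$dead_time)), con)
  utils::write.csv(data.frame(time = trace$times, signal = trace$signal),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a chevron dataset CSV
#'
#' Columns `phase`, `branch`, `denaturant`, `k_obs` (one row per observed
#' rate).
#'
#' @param path CSV path.
#' @return Data frame, split-ready by `phase`.
#' @export
read_chevron_csv <- function(path) {
  read_checked_csv(path, c("denaturant", "k_obs"))
}

#' Read a melting curve CSV (`temperature_C`, `signal`)
#' @param path CSV path.
#' @param wavelength Monitoring wavelength stored in the object.
#' @return A [melt_curve()].
#' @export
read_melt_csv <- function(path, wavelength = 215) {
  d <- read_checked_csv(path, c("temperature_C", "signal"))
  meta <- read_metadata_header(path)
  melt_curve(d$temperature_C + 273.15, d$signal, wavelength = wavelength,
             ligand = meta$ligand)
}

#' Read an ITC isotherm CSV
#'
#' Columns `injection_volume_uL`, `heat_ucal`; metadata lines
#' `# cell_concentration_uM=`, `# syringe_concentration_uM=`,
#' `# cell_volume_uL=`, `# temperature_K=`.
#'
#' @param path CSV path.
#' @return An [itc_isotherm()].
#' @export
read_itc_csv <- function(path) {
  meta <- read_metadata_header(path)
  need <- c("cell_concentration_uM", "syringe_concentration_uM")
  if (!all(need %in% names(meta))) {
    stop("ITC CSV must carry metadata lines: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  d <- read_checked_csv(path, c("injection_volume_uL", "heat_ucal"))
  itc_isotherm(meta$cell_concentration_uM, meta$syringe_concentration_uM,
               cell_volume = if (!is.null(meta$cell_volume_uL)) meta$cell_volume_uL else 200,
               injection_volumes = d$injection_volume_uL,
               heats = d$heat_ucal,
               temperature = if (!is.null(meta$temperature_K)) meta$temperature_K else 298.15)
}

#' Read a per-residue HDX intensity table (`residue`, `time`, `intensity`)
#' @param path CSV path.
#' @return Long data frame, ingestible by [hdx_protection_factors()].
#' @export
read_hdx_csv <- function(path) {
  read_checked_csv(path, c("residue", "time", "intensity"))
}

#' Read a single protein sequence from a FASTA file
#' @param path FASTA path.
#' @return One-letter amino-acid string.
#' @export
read_fasta_sequence <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(s) != 1L) stop("expected exactly one sequence, found ", length(s))
  toupper(as.character(s[[1L]]))
}

#' Serialize a fit result as a flat JSON record
#'
#' Scalars and short numeric vectors of the fit object are flattened to a
#' JSON record (full numeric precision) with a provenance block (package
#' version, timestamp-free content hash of the inputs when supplied). Failed
#' fits may be reported by passing a `status` attribute.
#'
#' @param result A fit object (any of the package's fit classes) or a named
#'   list.
#' @param path Output path.
#' @param status Status string stored in the record (default "converged").
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(result, path, status = "converged") {
  flat <- flatten_fit(result)
  rec <- c(list(status = status,
                package = "uchfold",
                version = as.character(utils::packageVersion("uchfold"))),
           if (status == "converged") flat else NULL)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

flatten_fit <- function(x) {
  if (inherits(x, "data.frame")) return(as.list(x))
  keep <- Filter(function(v) is.numeric(v) && length(v) <= 12 && !is.matrix(v),
                 unclass(x))
  keep
}

#' Read back a fit report written by [write_fit_report()]
#' @param path JSON path.
#' @return Named list.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
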