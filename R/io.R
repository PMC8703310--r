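#' Read and write spectra
#'
#' Two plain-text containers are supported. The jMRUI-style dialect has
#' `Key: value` header lines — `PointsInDataset`, `SamplingInterval` (ms),
#' `TransmitterFrequency` (Hz), optional `ReferencePpm` — followed by two
#' whitespace-separated columns of real and imaginary FID samples. The
#' package JSON container stores the axis parameters and the FID as
#' real/imaginary arrays under a versioned schema. Both round-trip to
#' within 1e-12.
#'
#' Parsing is strict: malformed headers or a truncated body raise an error
#' naming the offending line rather than returning partial data.
#'
#' @param spectrum A `phos_spectrum`.
#' @param path File path.
#' @param format `"jmrui_text"` or `"package_json"` (inferred from the file
#'   extension `.json` when omitted).
#' @return `read_spectrum` returns a `phos_spectrum`; `write_spectrum`
#'   returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = NULL) {
  stopifnot(inherits(spectrum, "phos_spectrum"))
  format <- infer_format(path, format)
  ax <- spectrum$axis
  if (format == "jmrui_text") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c(
      sprintf("PointsInDataset: %d", ax$n_points),
      sprintf("SamplingInterval: %.17g", ax$dwell_s * 1000),
      sprintf("TransmitterFrequency: %.17g", ax$larmor_mhz * 1e6),
      sprintf("ReferencePpm: %.17g", ax$reference_ppm),
      ""), con)
    writeLines(sprintf("%.17g %.17g", Re(spectrum$fid), Im(spectrum$fid)),
               con)
  } else {
    doc <- list(schema = "phosfit-spectrum", schema_version = 1L,
                axis = list(n_points = ax$n_points,
                            bandwidth_hz = ax$bandwidth_hz,
                            larmor_mhz = ax$larmor_mhz,
                            reference_ppm = ax$reference_ppm,
                            acquisition_delay_ms = ax$acquisition_delay_ms),
                fid_re = Re(spectrum$fid), fid_im = Im(spectrum$fid),
                provenance = spectrum$provenance)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    return(match.arg(format, c("jmrui_text", "package_json")))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) "package_json"
  else "jmrui_text"
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  format <- infer_format(path, format)
  if (format == "package_json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(doc$schema, "phosfit-spectrum"))
      stop("not a phosfit spectrum document: ", path)
    ax <- doc$axis
    axis <- make_axis(ax$n_points, ax$bandwidth_hz, ax$larmor_mhz,
                      reference_ppm = ax$reference_ppm,
                      acquisition_delay_ms = ax$acquisition_delay_ms)
    if (length(doc$fid_re) != axis$n_points)
      stop("FID length ", length(doc$fid_re), " does not match n_points ",
           axis$n_points)
    prov <- if (is.null(doc$provenance)) list() else as.list(doc$provenance)
    return(as_spectrum(complex(real = doc$fid_re, imaginary = doc$fid_im),
                       axis, prov))
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1L; break }
    m <- regmatches(ln, regexec("^([A-Za-z]+):\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("parse error at line ", i, ": expected 'Key: value', got '",
           ln, "'")
    hdr[[m[2]]] <- m[3]
    i <- i + 1L
  }
  need <- c("PointsInDataset", "SamplingInterval", "TransmitterFrequency")
  for (k in need) if (is.null(hdr[[k]]))
    stop("parse error: missing header field '", k, "'")
  n <- as.integer(hdr$PointsInDataset)
  dwell_ms <- as.numeric(hdr$SamplingInterval)
  tf_hz <- as.numeric(hdr$TransmitterFrequency)
  if (is.na(n) || is.na(dwell_ms) || is.na(tf_hz) || dwell_ms <= 0 ||
      tf_hz <= 0)
    stop("parse error: non-numeric or non-positive header value")
  refppm <- if (is.null(hdr$ReferencePpm)) 0 else as.numeric(hdr$ReferencePpm)
  axis <- make_axis(n, 1000 / dwell_ms, tf_hz / 1e6, reference_ppm = refppm)
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("parse error: body has ", length(body), " samples, header promises ",
         n, " (line ", i + length(body), ")")
  if (length(body) > n)
    stop("parse error: body has ", length(body), " samples, header promises ",
         n)
  vals <- lapply(seq_along(body), function(j) {
    parts <- strsplit(trimws(body[j]), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) != 2L || anyNA(v))
      stop("parse error at line ", i + j - 1L,
           ": expected two numeric columns")
    v
  })
  vm <- do.call(rbind, vals)
  as_spectrum(complex(real = vm[, 1], imaginary = vm[, 2]), axis,
              list(source = path))
}

#' Export and import a basis set
#'
#' `write_basis_lcmodel` writes a namelist-like container: a `$BASIS1`
#' header with points-per-ppm (`HZPPPM`), dwell (`BADELT`, seconds) and
#' point count (`NDATAB`), then one `$NMUSED`/`$BASIS` block per member
#' carrying the label and its frequency-domain points as real/imaginary
#' pairs. The structure is parseable by [read_basis_lcmodel()];
#' bit-compatibility with vendor software is not promised.
#' `write_basis_jmrui` writes each member's FID in the jMRUI-style text
#' dialect into a directory.
#'
#' @param basis A `phos_basis`.
#' @param path Output file (lcmodel) or directory (jmrui).
#' @return `path` invisibly; `read_basis_lcmodel` returns a list with
#'   `hzpppm`, `badelt`, `ndatab` and `members` (named list of complex
#'   frequency-domain vectors).
#' @export
write_basis_lcmodel <- function(basis, path) {
  stopifnot(inherits(basis, "phos_basis"))
  ax <- basis$axis
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(" $BASIS1",
               sprintf(" HZPPPM = %.6f,", ax$larmor_mhz),
               sprintf(" BADELT = %.9e,", ax$dwell_s),
               sprintf(" NDATAB = %d,", ax$n_points),
               " $END"), con)
  for (i in seq_along(basis$members)) {
    m <- basis$members[[i]]
    writeLines(c(" $NMUSED",
                 sprintf(" METABO = '%s',", basis$labels[i]),
                 sprintf(" PPMAPP = %.4f,", basis$shifts_ppm[i]),
                 sprintf(" FWHM = %.4f,", basis$fwhm_hz[i]),
                 " $END",
                 " $BASIS",
                 " $END"), con)
    writeLines(sprintf(" %.9e %.9e", Re(m$freq), Im(m$freq)), con)
  }
  invisible(path)
}

#' @rdname write_basis_lcmodel
#' @export
read_basis_lcmodel <- function(path) {
  lines <- readLines(path)
  getval <- function(key, block) {
    ln <- grep(sprintf("^\\s*%s\\s*=", key), block, value = TRUE)
    if (!length(ln)) stop("basis parse error: missing ", key)
    gsub(",\\s*$", "", sub(".*=\\s*", "", ln[1]))
  }
  h_end <- grep("\\$END", lines)[1]
  header <- lines[1:h_end]
  out <- list(hzpppm = as.numeric(getval("HZPPPM", header)),
              badelt = as.numeric(getval("BADELT", header)),
              ndatab = as.integer(getval("NDATAB", header)),
              members = list())
  starts <- grep("\\$NMUSED", lines)
  for (s in starts) {
    ends <- grep("\\$END", lines)
    meta_end <- min(ends[ends > s])
    lab <- gsub("'", "", getval("METABO", lines[s:meta_end]))
    data_end <- min(ends[ends > meta_end])
    body_start <- data_end + 1L
    body <- lines[body_start:(body_start + out$ndatab - 1L)]
    vm <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
    if (nrow(vm) != out$ndatab || anyNA(vm))
      stop("basis parse error: bad data block for ", lab)
    out$members[[lab]] <- complex(real = vm[, 1], imaginary = vm[, 2])
  }
  out
}

#' @rdname write_basis_lcmodel
#' @export
write_basis_jmrui <- function(basis, path) {
  stopifnot(inherits(basis, "phos_basis"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (i in seq_along(basis$members)) {
    f <- file.path(path, paste0(gsub("[^A-Za-z0-9_+-]", "_",
                                     basis$labels[i]), ".txt"))
    write_spectrum(basis$members[[i]], f, format = "jmrui_text")
  }
  invisible(path)
}

#' Write a fit report
#'
#' Serializes a `phos_fit` as a versioned JSON report and, optionally, a
#' delimited summary table (label, amplitude, relative intensity, relative
#' CRLB, shift).
#'
#' @param fit A `phos_fit`.
#' @param path JSON output path.
#' @param table_path Optional TSV output path.
#' @return `path` invisibly.
#' @export
write_fit_report <- function(fit, path, table_path = NULL) {
  stopifnot(inherits(fit, "phos_fit"))
  rel <- fit$relative_intensities
  doc <- list(schema = "phosfit-fit-report", schema_version = 1L,
              labels = fit$labels,
              amplitudes = unname(fit$amplitudes),
              shifts_ppm = unname(fit$shifts_ppm),
              broadening_hz = fit$broadening_hz,
              phase0_deg = fit$phase0_deg,
              phase1_deg_ppm = fit$phase1_deg_ppm,
              noise_sd = fit$noise_sd,
              relative_intensities = as.list(rel),
              relative_crlb = as.list(fit$relative_crlb),
              converged = fit$diagnostics$converged)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(table_path)) {
    df <- data.frame(label = fit$labels,
                     amplitude = unname(fit$amplitudes),
                     relative_intensity_pct =
                       unname(rel[match(fit$labels, names(rel))]),
                     relative_crlb_pct = unname(fit$relative_crlb),
                     shift_ppm = unname(fit$shifts_ppm))
    utils::write.table(df, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
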