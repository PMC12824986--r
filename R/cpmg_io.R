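#' Construct acquisition metadata for a CPMG measurement
#'
#' Bundles the per-measurement acquisition parameters of a CPMG echo train:
#' the interpulse delay tau (half the echo spacing; echo k is refocused at
#' t = 2*tau*k), the number of co-added scans, the sample temperature, and
#' whether the record came from a time-domain or frequency-domain CPMG
#' experiment.
#'
#' @param lab_id Character label identifying the laboratory/instrument.
#' @param tau Interpulse delay in seconds; must be positive.
#' @param n_scans Number of scans (transients) co-added; at least 1.
#' @param temperature Sample temperature in degrees Celsius; sanity-checked
#'   to lie in \[0, 60\].
#' @param mode Either `"time_domain"` (echo-intensity decay) or
#'   `"frequency_domain"` (sparse points derived from spectral processing).
#' @param sample_code Blinded alphanumeric vial code, or `NA`.
#' @return An object of class `acquisition_meta` (a named list).
#' @export
acquisition_meta <- function(lab_id = NA_character_, tau = NA_real_,
                             n_scans = 1L, temperature = 25,
                             mode = c("time_domain", "frequency_domain"),
                             sample_code = NA_character_) {
  mode <- match.arg(mode)
  if (!is.na(tau)) {
    stopifnot(is.numeric(tau), length(tau) == 1L)
    if (tau <= 0) stop("acquisition_meta: tau must be > 0 (seconds)")
  }
  n_scans <- as.integer(n_scans)
  if (n_scans < 1L) stop("acquisition_meta: n_scans must be >= 1")
  if (!is.na(temperature) && (temperature < 0 || temperature > 60)) {
    stop("acquisition_meta: temperature outside sanity window [0, 60] degC")
  }
  structure(
    list(lab_id = as.character(lab_id), tau = as.numeric(tau),
         n_scans = n_scans, temperature = as.numeric(temperature),
         mode = mode, sample_code = as.character(sample_code)),
    class = "acquisition_meta"
  )
}

#' Construct a CPMG decay trace
#'
#' A `decay_trace` holds a sampled CPMG echo decay: a strictly increasing,
#' positive time grid (seconds) and the complex echo signal on that grid.
#' Real-only records are stored with the imaginary channel set exactly to
#' zero and `is_quadrature = FALSE`.
#'
#' @param time Numeric vector of echo times in seconds, strictly increasing
#'   and positive, length >= 3.  Out-of-order input is sorted (signal
#'   reordered along with it) and the trace flagged via the `"reordered"`
#'   attribute.
#' @param signal Complex (or numeric, taken as real) vector of echo
#'   intensities, same length as `time`, arbitrary units.
#' @param is_quadrature Logical; `TRUE` when an imaginary channel was
#'   actually acquired.  Defaults to whether any imaginary component is
#'   nonzero.
#' @param meta An [acquisition_meta()] object (optional).
#' @return An object of class `decay_trace`.
#' @export
decay_trace <- function(time, signal, is_quadrature = NULL, meta = NULL) {
  time <- as.numeric(time)
  if (is.numeric(signal)) signal <- complex(real = signal, imaginary = 0)
  if (!is.complex(signal)) stop("decay_trace: signal must be numeric or complex")
  if (length(time) != length(signal)) {
    stop("decay_trace: time and signal lengths differ (",
         length(time), " vs ", length(signal), ")")
  }
  if (length(time) < 3L) {
    stop("decay_trace: insufficient data, need at least 3 points")
  }
  if (anyNA(time) || anyNA(signal)) stop("decay_trace: NA values not allowed")
  if (any(time <= 0)) stop("decay_trace: time values must be positive")
  reordered <- FALSE
  if (is.unsorted(time, strictly = TRUE)) {
    o <- order(time)
    if (any(duplicated(time))) stop("decay_trace: duplicated time values")
    time <- time[o]
    signal <- signal[o]
    reordered <- TRUE
    warning("decay_trace: time values were out of order and have been sorted")
  }
  if (is.null(is_quadrature)) is_quadrature <- any(Im(signal) != 0)
  if (!is_quadrature && any(Im(signal) != 0)) {
    stop("decay_trace: is_quadrature = FALSE but imaginary components nonzero")
  }
  if (is.null(meta)) meta <- acquisition_meta()
  structure(
    list(time = time, signal = signal, is_quadrature = isTRUE(is_quadrature),
         meta = meta),
    class = "decay_trace", reordered = reordered
  )
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> %d points, t in [%g, %g] s, %s\n",
              length(x$time), min(x$time), max(x$time),
              if (x$is_quadrature) "quadrature" else "real-only"))
  if (!is.na(x$meta$lab_id)) {
    cat(sprintf("  lab %s, sample %s, tau = %g s, %d scans, %s\n",
                x$meta$lab_id, x$meta$sample_code, x$meta$tau,
                x$meta$n_scans, x$meta$mode))
  }
  invisible(x)
}

#' @export
length.decay_trace <- function(x) length(x$time)

.detect_delim <- function(line) {
  for (d in c(",", ";", "\t")) {
    if (grepl(d, line, fixed = TRUE)) return(d)
  }
  # whitespace-separated fallback
  if (grepl("[ \t]", trimws(line))) return("[[:space:]]+")
  stop("read_decay: could not detect a delimiter (',', ';' or tab) in: ",
       substr(line, 1, 40))
}

#' Read a CPMG decay record from CSV
#'
#' Reads the two CSV dialects used for submitted benchtop CPMG data: two
#' columns (time in seconds, echo intensity in arbitrary units) or three
#' columns (time, real, imaginary quadrature components).  The delimiter is
#' auto-detected among comma, semicolon and tab; a single optional header
#' row is detected by its first row being non-numeric.  Two-column records
#' are stored with the imaginary channel zero-filled.  Times are taken as
#' seconds since the 90-degree excitation pulse; `time_unit` rescales on
#' read for files exported in ms or us.
#'
#' @param path Path to the CSV file.
#' @param dialect `"auto"` (detect from the column count), `"two_col"` or
#'   `"three_col"`.  A mismatch between a requested dialect and the file's
#'   column count is an error.
#' @param time_unit Unit of the file's time column: `"s"` (default), `"ms"`
#'   or `"us"`; values are converted to seconds.
#' @param meta Optional [acquisition_meta()] attached to the trace.
#' @return A [decay_trace()].
#' @export
read_decay <- function(path, dialect = c("auto", "two_col", "three_col"),
                       time_unit = c("s", "ms", "us"), meta = NULL) {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("read_decay: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("read_decay: empty file: ", path)
  delim <- .detect_delim(lines[[1]])
  fields <- strsplit(lines, delim)
  fields <- lapply(fields, trimws)
  # optional single header row: first row has a non-numeric cell
  first_num <- suppressWarnings(as.numeric(fields[[1]]))
  start_row <- if (anyNA(first_num)) 2L else 1L
  if (start_row > length(fields)) stop("read_decay: no data rows in ", path)
  fields <- fields[start_row:length(fields)]
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[[1]])[1]
    stop("read_decay: mixed column counts (row ", bad + start_row - 1L,
         " has ", ncols[bad], " columns, expected ", ncols[1], ")")
  }
  nc <- ncols[[1]]
  if (!nc %in% c(2L, 3L)) {
    stop("read_decay: expected 2 or 3 columns, found ", nc)
  }
  detected <- if (nc == 2L) "two_col" else "three_col"
  if (dialect != "auto" && dialect != detected) {
    stop("read_decay: dialect '", dialect, "' requested but file has ",
         nc, " columns")
  }
  mat <- matrix(NA_real_, nrow = length(fields), ncol = nc)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v)) {
      stop("read_decay: non-numeric cell in data row ", i + start_row - 1L,
           ": '", paste(fields[[i]], collapse = delim), "'")
    }
    mat[i, ] <- v
  }
  if (nrow(mat) < 3L) {
    stop("read_decay: insufficient data (", nrow(mat), " rows, need >= 3)")
  }
  scale <- switch(time_unit, s = 1, ms = 1e-3, us = 1e-6)
  tt <- mat[, 1] * scale
  sig <- if (nc == 2L) complex(real = mat[, 2], imaginary = 0)
         else complex(real = mat[, 2], imaginary = mat[, 3])
  decay_trace(tt, sig, is_quadrature = (nc == 3L), meta = meta)
}

#' Write a CPMG decay record to CSV
#'
#' Writes a [decay_trace()] in one of the two study CSV dialects at full
#' floating-point precision, so that `read_decay(write_decay(x))` reproduces
#' the trace exactly.  Writing a quadrature trace in the two-column dialect
#' discards information and is refused unless a reduction `policy` is given.
#'
#' @param trace A [decay_trace()].
#' @param path Output file path.
#' @param dialect `"two_col"` or `"three_col"`.
#' @param policy How to reduce a quadrature signal to one column when
#'   `dialect = "two_col"`: `"refuse"` (default; error if any imaginary
#'   component is nonzero), `"real"` (write the real channel) or
#'   `"magnitude"`.
#' @param header Logical; write a header row (default `TRUE`).
#' @return Invisibly, `path`.
#' @export
write_decay <- function(trace, path, dialect = c("two_col", "three_col"),
                        policy = c("refuse", "real", "magnitude"),
                        header = TRUE) {
  stopifnot(inherits(trace, "decay_trace"))
  dialect <- match.arg(dialect)
  policy <- match.arg(policy)
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "two_col") {
    if (any(Im(trace$signal) != 0) && policy == "refuse") {
      stop("write_decay: quadrature trace cannot be written as two columns; ",
           "set policy = 'real' or 'magnitude'")
    }
    y <- switch(policy,
                refuse = Re(trace$signal),
                real = Re(trace$signal),
                magnitude = Mod(trace$signal))
    rows <- paste(fmt(trace$time), fmt(y), sep = ",")
    if (header) rows <- c("time,intensity", rows)
  } else {
    rows <- paste(fmt(trace$time), fmt(Re(trace$signal)),
                  fmt(Im(trace$signal)), sep = ",")
    if (header) rows <- c("time,real,imaginary", rows)
  }
  writeLines(rows, path)
  invisible(path)
}

.sample_classes <- c("mAb", "AH", "AP", "ETFE", "buffer", "reference")

#' Load a blinded-study manifest
#'
#' The manifest maps each blinded vial code to its contents: sample class
#' (`mAb`, `AH`, `AP`, `ETFE`, `buffer`, `reference`), concentration
#' (mg/mL, or particle count for ETFE) and whether the vial was
#' freeze/thaw stressed.  Accepts JSON (an array of entry objects) or CSV
#' with header `sample_code,sample_class,concentration,stressed`.
#'
#' @param path Path to a `.json` or `.csv` manifest file.
#' @return A `study_manifest`: a data frame with columns `sample_code`,
#'   `sample_class`, `concentration`, `stressed`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("load_manifest: file not found: ", path)
  if (file.size(path) == 0) stop("load_manifest: empty file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_study_manifest(df)
}

#' Validate a data frame as a study manifest
#'
#' @param df Data frame with columns `sample_code`, `sample_class`,
#'   `concentration`, `stressed`.
#' @return A validated `study_manifest`.
#' @export
as_study_manifest <- function(df) {
  need <- c("sample_code", "sample_class", "concentration", "stressed")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("manifest: missing required field(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("manifest: no entries")
  df$sample_code <- as.character(df$sample_code)
  df$sample_class <- as.character(df$sample_class)
  df$concentration <- as.numeric(df$concentration)
  df$stressed <- as.logical(df$stressed)
  dup <- df$sample_code[duplicated(df$sample_code)]
  if (length(dup)) {
    stop("manifest: duplicated sample_code(s): ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(df$sample_class), .sample_classes)
  if (length(bad)) {
    stop("manifest: unknown sample_class(es): ", paste(bad, collapse = ", "),
         " (known: ", paste(.sample_classes, collapse = ", "), ")")
  }
  if (anyNA(df$concentration) || any(df$concentration < 0)) {
    stop("manifest: concentrations must be numeric and >= 0")
  }
  if (anyNA(df$stressed)) stop("manifest: stressed must be TRUE/FALSE")
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' Default 24-vial study manifest
#'
#' Builds the blinded sample kit used for a multi-laboratory comparison:
#' 6 aluminum-hydroxide (AH) concentrations (0.31--10 mg/mL of Al(III)),
#' 5 aluminum-phosphate (AP) concentrations (0.31--5 mg/mL), one
#' freeze/thaw-stressed AH and one stressed AP vial at 1.25 mg/mL,
#' 5 NISTmAb concentrations (1--100 mg/mL) plus a buffer blank, and
#' 5 ETFE particle-count levels (6250--100000) as the negative control:
#' 24 vials in total.
#'
#' @return A `study_manifest` with 24 entries.
#' @export
default_manifest <- function() {
  entries <- rbind(
    data.frame(sample_code = sprintf("AH%d", 1:6), sample_class = "AH",
               concentration = c(0.31, 0.63, 1.25, 2.5, 5.0, 10.0),
               stressed = FALSE),
    data.frame(sample_code = sprintf("AP%d", 1:5), sample_class = "AP",
               concentration = c(0.31, 0.63, 1.25, 2.5, 5.0),
               stressed = FALSE),
    data.frame(sample_code = "AHFT", sample_class = "AH",
               concentration = 1.25, stressed = TRUE),
    data.frame(sample_code = "APFT", sample_class = "AP",
               concentration = 1.25, stressed = TRUE),
    data.frame(sample_code = sprintf("MAB%d", 1:5), sample_class = "mAb",
               concentration = c(1, 10, 25, 50, 100), stressed = FALSE),
    data.frame(sample_code = "BUF1", sample_class = "buffer",
               concentration = 0, stressed = FALSE),
    data.frame(sample_code = sprintf("ETFE%d", 1:5), sample_class = "ETFE",
               concentration = c(6250, 12500, 25000, 50000, 100000),
               stressed = FALSE)
  )
  as_study_manifest(entries)
}

#' Write a study manifest to CSV or JSON
#'
#' @param manifest A `study_manifest`.
#' @param path Output path ending in `.csv` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "study_manifest"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(as.data.frame(unclass(manifest)), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(unclass(manifest)), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
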