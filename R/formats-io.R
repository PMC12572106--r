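# I/O for every external representation the pipeline touches: Raven Pro
# selection tables, detection tables with class probabilities, WAV audio,
# and tri-axial acceleration tables.

RAVEN_BEGIN <- "Begin Time (s)"
RAVEN_END <- "End Time (s)"

#' Read a Raven Pro selection table
#'
#' Parses the tab-delimited selection table dialect exported by Raven Pro.
#' Columns `Begin Time (s)` and `End Time (s)` are required; frequency
#' columns, if present, are ignored (annotations here carry no frequency
#' information). The annotation label column is configurable because Raven
#' exports vary between setups.
#'
#' @param path Path to a tab-delimited selection table.
#' @param label_column Name of the column carrying the class label
#'   (default `"Annotation"`).
#' @param individual_id,file_id Optional identifiers attached to every row;
#'   `file_id` defaults to the file's base name.
#' @return A selection table tibble sorted by `start_s` (see
#'   [validate_selection_table()]).
#' @export
read_selection_table <- function(path, label_column = "Annotation",
                                 individual_id = NA_character_,
                                 file_id = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  for (col in c(RAVEN_BEGIN, RAVEN_END, label_column)) {
    if (!col %in% names(raw)) {
      abort(sprintf("selection table '%s': missing required column \"%s\"", path, col))
    }
  }
  start_s <- suppressWarnings(as.numeric(raw[[RAVEN_BEGIN]]))
  stop_s <- suppressWarnings(as.numeric(raw[[RAVEN_END]]))
  bad <- which(is.na(start_s) | is.na(stop_s))
  if (length(bad) > 0) {
    abort(sprintf("selection table '%s': non-numeric time on row %d", path, bad[1]))
  }
  out <- tibble(
    start_s = start_s,
    stop_s = stop_s,
    label = raw[[label_column]],
    detection_prob = 1,
    individual_id = individual_id,
    file_id = file_id %||% basename(path)
  )
  validate_selection_table(out, where = sprintf("selection table '%s'", path))
}

#' Write a selection table in Raven dialect
#'
#' Writes a tab-delimited table with columns `Selection`, `View`, `Channel`,
#' `Begin Time (s)`, `End Time (s)` and the annotation column, ordered by
#' start time with times printed to six decimals, so that
#' read-then-write round trips are stable.
#'
#' @param table A selection table tibble.
#' @param path Output path.
#' @param label_column Name for the annotation column (default `"Annotation"`).
#' @param channel Channel number written to every row.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(table, path, label_column = "Annotation",
                                  channel = 1L) {
  table <- validate_selection_table(table)
  out <- tibble(
    Selection = seq_len(nrow(table)),
    View = rep("Spectrogram 1", nrow(table)),
    Channel = rep(as.integer(channel), nrow(table)),
    begin = sprintf("%.6f", table$start_s),
    end = sprintf("%.6f", table$stop_s),
    label = table$label
  )
  names(out)[4:6] <- c(RAVEN_BEGIN, RAVEN_END, label_column)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read/write a detection table
#'
#' Detections are exchanged as TSV with columns `start_s`, `stop_s`, `label`,
#' `detection_prob` and the four class-probability columns `p_focal`,
#' `p_nonfocal`, `p_chick`, `p_cuckoo` (plus optional `individual_id`,
#' `file_id`).
#'
#' @param path Path to a detections TSV.
#' @return A selection table tibble with probability columns.
#' @export
read_detections <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_selection_table(x, where = sprintf("detections '%s'", path))
}

#' @rdname read_detections
#' @param detections Selection table tibble to write.
#' @export
write_detections <- function(detections, path) {
  detections <- validate_selection_table(detections)
  readr::write_tsv(detections, path, progress = FALSE)
  invisible(path)
}

# ---- WAV ------------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer (PCM 16/24-bit and IEEE float32).
# Integer samples are scaled by 1/2^(bits-1) so full scale is [-1, 1]; this
# fixes the dBFS reference used throughout the package.

#' Read a WAV file
#'
#' Reads mono (or the first channel of) PCM 16/24-bit or IEEE float32 WAV.
#' Integer samples are scaled by `1/2^(bits-1)` to floating point in
#' `[-1, 1]`, the full-scale reference for all dBFS measurements.
#'
#' @param path Path to a WAV file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(sprintf("'%s' is not a RIFF/WAVE file", path))
  readBin(con, "integer", 1, 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(sprintf("'%s' is not a RIFF/WAVE file", path))
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) abort(sprintf("'%s': data chunk before fmt chunk", path))
      samples <- read_wav_data(con, size, fmt, path)
      break
    } else {
      seek(con, size + size %% 2, origin = "current")
    }
  }
  if (is.null(samples)) abort(sprintf("'%s': no data chunk found", path))
  list(samples = samples, sample_rate = fmt$sample_rate)
}

read_wav_data <- function(con, size, fmt, path) {
  bytes_per <- fmt$bits %/% 8
  n_total <- size %/% bytes_per
  if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(con, "integer", n_total, 2, signed = TRUE, endian = "little")
    x <- x / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    b <- readBin(con, "raw", size)
    b <- matrix(as.integer(b), nrow = 3)
    x <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    x <- ifelse(x >= 8388608, x - 16777216, x) / 8388608
  } else if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(con, "numeric", n_total, 4, endian = "little")
  } else {
    abort(sprintf("'%s': unsupported WAV encoding (format %d, %d-bit)",
                  path, fmt$format, fmt$bits))
  }
  if (fmt$channels > 1) x <- x[seq(1, length(x), by = fmt$channels)]
  x
}

#' Write a WAV file
#'
#' Writes mono audio as PCM 16/24-bit or IEEE float32. For integer formats,
#' floating samples in `[-1, 1]` are scaled by `2^(bits-1)` and clamped to
#' the representable range.
#'
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits One of 16, 24 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16) {
  if (!bits %in% c(16, 24, 32)) abort("`bits` must be 16, 24 or 32")
  n <- length(samples)
  bytes_per <- bits %/% 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16) {
    x <- pmin(pmax(round(samples * 32768), -32768), 32767)
    writeBin(as.integer(x), con, 2, endian = "little")
  } else if (bits == 24) {
    x <- pmin(pmax(round(samples * 8388608), -8388608), 8388607)
    x <- ifelse(x < 0, x + 16777216, x)
    b <- rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}

# ---- Acceleration tables --------------------------------------------------

#' Construct a tri-axial acceleration table
#'
#' An acceleration table is a tibble with columns `t` (seconds, uniform
#' step), `ax`, `ay`, `az` (acceleration in g; x rightward, y forward,
#' z upward) and an `fs` attribute giving the sampling rate in Hz.
#'
#' @param ax,ay,az Numeric vectors of equal length, acceleration in g.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return A tibble of class `accel_tbl`.
#' @export
accel_table <- function(ax, ay, az, fs, t0 = 0) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n) abort("ax, ay, az must have equal length")
  stopifnot_scalar_number(fs, "fs")
  out <- tibble(t = t0 + (seq_len(n) - 1) / fs, ax = ax, ay = ay, az = az)
  attr(out, "fs") <- fs
  class(out) <- c("accel_tbl", class(out))
  out
}

#' @rdname accel_table
#' @param x An acceleration table.
#' @export
accel_fs <- function(x) {
  fs <- attr(x, "fs", exact = TRUE)
  if (is.null(fs)) {
    if (!"t" %in% names(x) || nrow(x) < 2) abort("cannot infer sampling rate")
    fs <- 1 / stats::median(diff(x$t))
  }
  fs
}

check_uniform_time <- function(t, fs, tol = 1e-6, where = "acceleration table") {
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > tol)) {
      abort(sprintf("%s: non-uniform timestamps (expected step %g s)", where, 1 / fs))
    }
  }
  invisible(NULL)
}

#' Read a tri-axial acceleration table from CSV
#'
#' Accepts either a 4-column file with header `t,ax,ay,az` (rate inferred
#' from timestamps, which must be uniform to 1e-6 s) or a 3-column
#' `ax,ay,az` file with the rate passed as `fs`.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz; required when the file has no `t` column.
#' @return An [accel_table()].
#' @export
read_accel_table <- function(path, fs = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (all(c("t", "ax", "ay", "az") %in% names(x))) {
    if (anyDuplicated(x$t)) abort(sprintf("'%s': duplicated timestamp", path))
    if (is.null(fs)) fs <- 1 / stats::median(diff(x$t))
    check_uniform_time(x$t, fs, where = sprintf("'%s'", path))
    out <- accel_table(x$ax, x$ay, x$az, fs = fs, t0 = x$t[1])
  } else if (all(c("ax", "ay", "az") %in% names(x))) {
    if (is.null(fs)) abort(sprintf("'%s' has no t column; pass `fs`", path))
    out <- accel_table(x$ax, x$ay, x$az, fs = fs)
  } else {
    abort(sprintf("'%s': expected columns t,ax,ay,az or ax,ay,az", path))
  }
  out
}

#' @rdname read_accel_table
#' @param accel An acceleration table to write.
#' @export
write_accel_table <- function(accel, path) {
  readr::write_csv(as_tibble(accel)[, c("t", "ax", "ay", "az")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write a metrics table as JSON or TSV
#'
#' @param metrics A metrics tibble from [compute_metrics()].
#' @param path Output path; format chosen by extension (`.json` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(metrics, path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  } else {
    readr::write_tsv(metrics, path, progress = FALSE)
  }
  invisible(path)
}
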