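#' Uniformly sampled pressure recording
#'
#' Container for a uniformly sampled pressure time series, either calibrated
#' gauge pressure in mmHg or raw transmitter frequency units before
#' calibration. Sample `i` (1-based) is taken at
#' `start_time + (i - 1) / sampling_rate_hz`; all analysis windows in the
#' package are half-open `[start, end)`.
#'
#' @param samples Numeric vector of pressure samples. `NA` values are treated
#'   as gaps.
#' @param sampling_rate_hz Sampling rate in samples per second (default 500,
#'   the usual telemetry acquisition rate).
#' @param start_time ISO-8601 timestamp string for the first sample.
#' @param units Unit label, `"mmHg"` for calibrated pressure or `"raw_freq"`
#'   for uncalibrated transmitter output.
#' @param gap_mask Logical vector marking missing/invalid samples; defaults to
#'   `is.na(samples)`.
#' @return An object of class `pressure_recording`: a list with elements
#'   `samples`, `sampling_rate_hz`, `start_time`, `units`, `gap_mask`.
#' @examples
#' rec <- pressure_recording(sin(seq(0, 2 * pi, length.out = 500)), 500)
#' rec_duration(rec)
#' @export
pressure_recording <- function(samples, sampling_rate_hz = 500,
                               start_time = "1970-01-01T00:00:00Z",
                               units = "mmHg", gap_mask = NULL) {
  if (!is.numeric(samples)) stop("`samples` must be numeric")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number")
  }
  if (is.null(gap_mask)) gap_mask <- is.na(samples)
  if (length(gap_mask) != length(samples)) {
    stop("`gap_mask` must have the same length as `samples`")
  }
  samples <- as.double(samples)
  samples[gap_mask] <- NA_real_
  structure(
    list(samples = samples,
         sampling_rate_hz = as.double(sampling_rate_hz),
         start_time = as.character(start_time),
         units = as.character(units),
         gap_mask = as.logical(gap_mask)),
    class = "pressure_recording")
}

#' @export
print.pressure_recording <- function(x, ...) {
  cat(sprintf("<pressure_recording> %d samples @ %g Hz (%.3f s), units %s, %d gaps\n",
              length(x$samples), x$sampling_rate_hz, rec_duration(x),
              x$units, sum(x$gap_mask)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [pressure_recording()].
#' @return Duration in seconds (`n / rate`; the half-open convention counts
#'   each sample as covering `1/rate` seconds).
#' @export
rec_duration <- function(rec) length(rec$samples) / rec$sampling_rate_hz

#' Sample times relative to the recording start
#' @param rec A [pressure_recording()].
#' @return Numeric vector of times in seconds, starting at 0.
#' @export
rec_times <- function(rec) {
  (seq_along(rec$samples) - 1) / rec$sampling_rate_hz
}

parse_start_time <- function(x) {
  out <- as.POSIXct(sub("T", " ", sub("Z$", "", x)), tz = "UTC")
  if (is.na(out)) stop("unparseable start_time: ", x)
  out
}

#' Read a waveform text file
#'
#' The format is UTF-8 text with `#`-prefixed header lines
#' (`# sampling_rate_hz: 500`, `# units: mmHg`, `# start_time: ...`) followed
#' by one sample per line; `NA` or blank lines mark gaps.
#'
#' @param path Path to the file.
#' @return A [pressure_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    if (!startsWith(ln, "#")) break
    head_lines <- c(head_lines, ln)
  }
  close(con); on.exit(NULL)
  hdr <- list()
  for (ln in head_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3L) hdr[[m[2]]] <- m[3]
  }
  for (key in c("sampling_rate_hz", "units", "start_time")) {
    if (is.null(hdr[[key]])) {
      stop("waveform header is missing required field '", key, "' in ", path)
    }
  }
  rate <- suppressWarnings(as.numeric(hdr$sampling_rate_hz))
  if (is.na(rate) || rate <= 0) {
    stop("nonpositive or non-numeric sampling_rate_hz in header of ", path)
  }
  n_skip <- length(head_lines)
  body <- data.table::fread(path, skip = n_skip, header = FALSE, sep = "\n",
                            colClasses = "character", blank.lines.skip = FALSE,
                            strip.white = TRUE)
  vals <- if (nrow(body)) body[[1L]] else character()
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(!is.na(vals) & vals != "NA" & is.na(num))
  if (length(bad)) {
    stop(sprintf("non-numeric sample value '%s' at line %d of %s",
                 vals[bad[1]], n_skip + bad[1], path))
  }
  pressure_recording(num, sampling_rate_hz = rate,
                     start_time = hdr$start_time, units = hdr$units)
}

#' Write a waveform text file
#'
#' Writes the header/sample format read by [read_recording()]. Samples are
#' formatted with five decimal places (0.00001 mmHg), so write-read round
#' trips are lossless at that precision and write-read-write is a fixed point
#' on the text representation.
#'
#' @param rec A [pressure_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pressure_recording"))
  hdr <- c(sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate_hz),
           sprintf("# units: %s", rec$units),
           sprintf("# start_time: %s", rec$start_time))
  body <- sprintf("%.5f", rec$samples)
  body[rec$gap_mask | is.na(rec$samples)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(body, con)
  invisible(path)
}

#' Write a metrics/epoch/trend table to CSV
#'
#' One row per beat, epoch, or trend point, with units embedded in the column
#' names (e.g. `tau66_ms`). Values are written at full double precision so a
#' read-back reproduces them well beyond 6 significant digits.
#'
#' @param x A data.frame (beat metrics, epoch summaries, trend points, or
#'   daily summaries).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(x, path) {
  if (!is.data.frame(x)) {
    stop("`x` must be a data.frame; mixed or non-tabular collections are not supported")
  }
  if (nrow(x) == 0L) stop("refusing to write an empty table")
  if (!all(vapply(x, function(col) is.atomic(col) || is.factor(col), TRUE))) {
    stop("all columns must be atomic (mixed-type collections rejected)")
  }
  data.table::fwrite(x, path)
  invisible(path)
}

#' Read back a metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return A data.frame.
#' @export
read_metrics_table <- function(path) {
  as.data.frame(data.table::fread(path))
}
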