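#' Quality-control policy
#'
#' Thresholds controlling beat- and recording-level quality control. The
#' irregularity rule follows the arrhythmia-exclusion practice for telemetry
#' baselines: a recording dominated by irregular RR intervals (e.g. from a
#' post-surgical arrhythmia) is excluded from analysis rather than averaged.
#'
#' @param rr_dev_frac A beat is irregular when its RR deviates from the
#'   median RR of the surrounding window by more than this fraction
#'   (default 0.25).
#' @param rr_window_s Width of the surrounding window for the local median
#'   RR (default 30 s).
#' @param irregular_max Recording excluded when the irregular-beat fraction
#'   exceeds this (default 0.05).
#' @param pressure_range Physiological gauge-pressure bounds in mmHg
#'   (default `c(0, 250)`); samples outside count as artifact.
#' @param spike_mmHg_per_s Absolute derivative above this flags wall-contact
#'   style spike artifact (default 6000 mmHg/s).
#' @param artifact_max Recording excluded when the artifact-time fraction
#'   exceeds this (default 0.10).
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(rr_dev_frac = 0.25, rr_window_s = 30,
                      irregular_max = 0.05, pressure_range = c(0, 250),
                      spike_mmHg_per_s = 6000, artifact_max = 0.10) {
  structure(list(rr_dev_frac = rr_dev_frac, rr_window_s = rr_window_s,
                 irregular_max = irregular_max,
                 pressure_range = pressure_range,
                 spike_mmHg_per_s = spike_mmHg_per_s,
                 artifact_max = artifact_max),
            class = "qc_policy")
}

# Indices of beats whose [onset, end) window contains any flagged sample.
beats_hitting <- function(beats, flagged_idx) {
  if (length(flagged_idx) == 0L || nrow(beats) == 0L) return(integer())
  cum <- cumsum(seq_len(max(beats$end_idx)) %in% flagged_idx)
  which(cum[beats$end_idx - 1L] - cum[pmax(beats$onset_idx - 1L, 1L)] > 0)
}

#' Quality control of a beat-annotated recording
#'
#' Flags irregular beats (RR deviating more than `rr_dev_frac` from the
#' median RR of the surrounding `rr_window_s`), pressure excursions outside
#' physiological bounds, derivative spikes (wall-contact artifact) and gap
#' samples. The recording is excluded when the irregular fraction exceeds
#' `irregular_max`, when the artifact-time fraction exceeds `artifact_max`,
#' or when no beats were detected.
#'
#' @param beats A `beat_annotation` from [detect_beats()].
#' @param recording The annotated [pressure_recording()].
#' @param policy A [qc_policy()].
#' @param derivative Optional derivative series (recomputed by central
#'   difference if omitted) used for spike detection.
#' @return A list of class `qc_report`: `n_beats`, `n_irregular`,
#'   `irregular_fraction`, `artifact_fraction` (fraction of recording time
#'   flagged as artifact), `artifact_intervals` (data.frame start_s/end_s),
#'   `excluded` (logical), `reasons` (character), `beat_flags` (per-beat
#'   semicolon-joined flag strings aligned with `beats`), and the policy.
#' @export
qc_recording <- function(beats, recording, policy = qc_policy(),
                         derivative = NULL) {
  stopifnot(inherits(recording, "pressure_recording"))
  p <- recording$samples
  rate <- recording$sampling_rate_hz
  n <- length(p)
  if (is.null(derivative)) derivative <- estimate_derivative(recording)
  d <- as.numeric(derivative)

  reasons <- character()
  if (nrow(beats) == 0L) {
    rep0 <- structure(list(n_beats = 0L, n_irregular = 0L,
                           irregular_fraction = 0,
                           artifact_fraction = 1,
                           artifact_intervals = data.frame(start_s = 0,
                                                           end_s = rec_duration(recording)),
                           excluded = TRUE, reasons = "no beats",
                           beat_flags = character(), policy = policy),
                      class = "qc_report")
    return(rep0)
  }

  flags <- beats$flag
  flags[is.na(flags)] <- ""

  # irregular RR vs local median over +/- rr_window_s/2
  t <- beats$onset_time_s
  half <- policy$rr_window_s / 2
  lo <- findInterval(t - half, t) + 1L
  hi <- findInterval(t + half, t)
  med <- vapply(seq_len(nrow(beats)),
                function(k) stats::median(beats$rr_s[lo[k]:hi[k]]), 0)
  irregular <- abs(beats$rr_s - med) > policy$rr_dev_frac * med
  # a beat truncated by the recording edge has an artifactual RR, not an
  # arrhythmic one
  irregular <- irregular & !grepl("edge", flags)
  flags[irregular] <- paste0(flags[irregular],
                             ifelse(nzchar(flags[irregular]), ";", ""), "irregular")

  # sample-level artifact mask
  obb <- !is.na(p) & (p < policy$pressure_range[1] | p > policy$pressure_range[2])
  spk <- !is.na(d) & abs(d) > policy$spike_mmHg_per_s
  gap <- is.na(p)
  art <- obb | spk | gap
  art_frac <- mean(art)

  hit <- beats_hitting(beats, which(obb | spk))
  flags[hit] <- paste0(flags[hit], ifelse(nzchar(flags[hit]), ";", ""), "artifact")

  # contiguous artifact runs as intervals
  runs <- rle(art)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ai <- data.frame(start_s = (starts[runs$values] - 1L) / rate,
                   end_s = ends[runs$values] / rate)

  n_irr <- sum(irregular)
  irr_frac <- n_irr / nrow(beats)
  if (irr_frac > policy$irregular_max) {
    reasons <- c(reasons, sprintf("irregular fraction %.3f > %.3f (cardiac arrhythmia)",
                                  irr_frac, policy$irregular_max))
  }
  if (art_frac > policy$artifact_max) {
    reasons <- c(reasons, sprintf("artifact time fraction %.3f > %.3f",
                                  art_frac, policy$artifact_max))
  }

  structure(list(n_beats = nrow(beats), n_irregular = n_irr,
                 irregular_fraction = irr_frac,
                 artifact_fraction = art_frac,
                 artifact_intervals = ai,
                 excluded = length(reasons) > 0L,
                 reasons = reasons,
                 beat_flags = flags,
                 policy = policy),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d beats, irregular %.1f%%, artifact time %.1f%%: %s\n",
              x$n_beats, 100 * x$irregular_fraction, 100 * x$artifact_fraction,
              if (x$excluded) paste("EXCLUDED -", paste(x$reasons, collapse = "; "))
              else "retained"))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  x <- unclass(report)
  x$policy <- unclass(x$policy)
  x$beat_flags <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
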