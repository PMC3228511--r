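#' Transmitter calibration record
#'
#' Pairs of applied chamber pressure and raw transmitter frequency output.
#' The usual bench protocol applies three absolute pressures (750, 850 and
#' 950 mmHg) to the sealed chamber and records the transmitter's raw
#' frequency at each.
#'
#' @param pressure_mmHg Applied absolute pressures, strictly increasing,
#'   at least two distinct values.
#' @param raw Raw frequency output at each pressure.
#' @return An object of class `calibration_record`.
#' @examples
#' calibration_record(c(750, 850, 950), c(750, 850, 950))
#' @export
calibration_record <- function(pressure_mmHg, raw) {
  if (length(pressure_mmHg) != length(raw)) {
    stop("pressure and raw vectors must have equal length")
  }
  if (length(unique(pressure_mmHg)) < 2L) {
    stop("insufficient calibration: need at least 2 distinct pressure points")
  }
  if (any(diff(pressure_mmHg) <= 0)) {
    stop("calibration pressures must be strictly increasing")
  }
  if (anyNA(pressure_mmHg) || anyNA(raw)) stop("calibration points must be finite")
  structure(list(pressure_mmHg = as.double(pressure_mmHg),
                 raw = as.double(raw)),
            class = "calibration_record")
}

#' Fit an affine raw-frequency to pressure calibration map
#'
#' Least-squares affine fit of applied pressure on raw frequency output.
#' With exactly two points the fit is exact; with three (the standard
#' 750/850/950 mmHg protocol) the line is over-determined and the residuals
#' act as a transducer-linearity health check. The affine form is an
#' assumption (the vendor's raw-frequency model is not published) and the
#' residuals are always reported rather than dropped.
#'
#' @param record A [calibration_record()].
#' @return An object of class `calibration_map` with elements `slope`,
#'   `intercept` (pressure = slope * raw + intercept), `residuals`
#'   (observed - fitted pressure per calibration point) and `points`.
#' @examples
#' fit_calibration(calibration_record(c(750, 850, 950), c(1510, 1710, 1910)))
#' @export
fit_calibration <- function(record) {
  stopifnot(inherits(record, "calibration_record"))
  raw <- record$raw
  p <- record$pressure_mmHg
  if (diff(range(raw)) == 0) {
    stop("degenerate calibration: zero spread in raw frequency output")
  }
  fit <- stats::lm(p ~ raw)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope == 0) {
    stop("degenerate calibration: slope is zero or non-finite")
  }
  structure(list(slope = slope, intercept = intercept,
                 residuals = unname(stats::resid(fit)),
                 points = record),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> pressure = %.6g * raw + %.6g; max |residual| %.3g mmHg\n",
              x$slope, x$intercept, max(abs(x$residuals))))
  invisible(x)
}

#' Apply a calibration map and ambient-pressure reference
#'
#' Converts a raw-frequency recording to gauge pressure:
#' `gauge = slope * raw + intercept - ambient`, per sample. The ambient
#' reference (an ambient pressure reference monitor channel) may be a scalar
#' in mmHg or a [pressure_recording()]; a recording is linearly interpolated
#' onto the target sample times (constant extrapolation at the ends), so
#' slow barometric series sampled at low rates align without resampling by
#' hand.
#'
#' @param rec Raw [pressure_recording()] (units are not required to be
#'   `"mmHg"`; the output is labelled mmHg gauge).
#' @param map A [calibration_map()].
#' @param ambient Scalar ambient pressure in mmHg, or a
#'   [pressure_recording()] of ambient pressure.
#' @return A gauge-pressure [pressure_recording()] in mmHg.
#' @export
apply_calibration <- function(rec, map, ambient = 0) {
  stopifnot(inherits(rec, "pressure_recording"), inherits(map, "calibration_map"))
  absolute <- map$slope * rec$samples + map$intercept
  if (inherits(ambient, "pressure_recording")) {
    if (length(ambient$samples) == length(rec$samples) &&
        ambient$sampling_rate_hz == rec$sampling_rate_hz) {
      amb <- ambient$samples
    } else {
      if (sum(!is.na(ambient$samples)) < 2L) {
        stop("ambient recording misaligned: need at least 2 finite ambient samples to resample")
      }
      offset <- as.double(difftime(parse_start_time(ambient$start_time),
                                   parse_start_time(rec$start_time),
                                   units = "secs"))
      t_amb <- rec_times(ambient) + offset
      ok <- !is.na(ambient$samples)
      amb <- stats::approx(t_amb[ok], ambient$samples[ok], xout = rec_times(rec),
                           rule = 2)$y
    }
  } else if (is.numeric(ambient) && length(ambient) == 1L) {
    amb <- ambient
  } else {
    stop("`ambient` must be a scalar or a pressure_recording (alignment error otherwise)")
  }
  pressure_recording(absolute - amb,
                     sampling_rate_hz = rec$sampling_rate_hz,
                     start_time = rec$start_time,
                     units = "mmHg",
                     gap_mask = rec$gap_mask)
}
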