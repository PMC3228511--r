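#' Detect beats and annotate fiducial points
#'
#' Candidate beats are local maxima of dP/dt exceeding an adaptive threshold
#' (a fraction of the rolling 10-s derivative maximum), separated by a
#' refractory period. For each candidate the fiducials are: the systolic
#' peak (maximum pressure before the next candidate, earliest sample on
#' ties), the -dP/dt_max point (most negative derivative after the peak in
#' the same interval), and the onset (end-diastole), taken as the last
#' sample below 10% of the beat's own dP/dt_max before the upstroke crosses
#' that level. A beat's end is the next beat's onset; windows are half-open
#' `[onset, end)`. Detection depends on the signal only through its
#' derivative and through within-interval pressure maxima, so it is
#' invariant to constant pressure offsets.
#'
#' @param recording A [pressure_recording()].
#' @param derivative Derivative series from [estimate_derivative()] (aligned
#'   to the recording).
#' @param threshold_frac Fraction of the rolling derivative maximum used as
#'   the candidate threshold (default 0.3).
#' @param threshold_window_s Width of the rolling-maximum window in seconds
#'   (default 10).
#' @param refractory_s Minimum spacing between candidates (default 0.15 s,
#'   a ~400 bpm ceiling).
#' @param onset_frac Fraction of the beat's dP/dt_max defining the onset
#'   crossing (default 0.05; low enough that the onset sample still sits on
#'   the end-diastolic baseline rather than one sample into the upstroke).
#' @return A data.frame of class `beat_annotation` with one row per beat:
#'   `onset_idx`, `dpdt_max_idx`, `systolic_peak_idx`, `neg_dpdt_max_idx`,
#'   `end_idx` (1-based sample indices), `onset_time_s`, `rr_s`, and `flag`
#'   (`""`, or `"edge"` for the trailing beat truncated by the recording
#'   end). Beats spanning gaps or violating fiducial ordering are dropped;
#'   the number dropped is available as `attr(x, "n_dropped")`. An empty
#'   recording yields zero rows with a warning.
#' @export
detect_beats <- function(recording, derivative,
                         threshold_frac = 0.3, threshold_window_s = 10,
                         refractory_s = 0.15, onset_frac = 0.05) {
  stopifnot(inherits(recording, "pressure_recording"))
  p <- recording$samples
  d <- as.numeric(derivative)
  n <- length(p)
  if (length(d) != n) stop("derivative must be aligned to the recording")
  rate <- recording$sampling_rate_hz

  empty <- function(msg) {
    warning(msg)
    out <- data.frame(onset_idx = integer(), dpdt_max_idx = integer(),
                      systolic_peak_idx = integer(), neg_dpdt_max_idx = integer(),
                      end_idx = integer(), onset_time_s = numeric(),
                      rr_s = numeric(), flag = character())
    class(out) <- c("beat_annotation", "data.frame")
    attr(out, "n_dropped") <- 0L
    out
  }
  if (n < 3L) return(empty("recording too short for beat detection"))

  thr <- threshold_frac * rolling_max(d, half_w = round(threshold_window_s * rate / 2))
  dd <- d
  dd[is.na(dd)] <- -Inf
  is_max <- c(FALSE, dd[2:(n - 1)] >= dd[1:(n - 2)] & dd[2:(n - 1)] > dd[3:n], FALSE)
  cand <- which(is_max & dd > thr & dd > 0)
  if (length(cand) == 0L) return(empty("no beat candidates found"))

  # refractory: greedy in time order
  refr <- refractory_s * rate
  keep <- logical(length(cand))
  last <- -Inf
  for (j in seq_along(cand)) {
    if (cand[j] - last >= refr) {
      keep[j] <- TRUE
      last <- cand[j]
    }
  }
  cand <- cand[keep]
  K <- length(cand)

  # systolic peak and -dP/dt_max within [cand[k], cand[k+1]) (last interval
  # runs to the end of the recording)
  i_all <- cand[1]:n
  g <- findInterval(i_all, cand)
  dt <- data.table::data.table(i = i_all, p = p[i_all], d = dd[i_all], g = g)
  fid <- dt[, {
    ipk <- which.max(p)
    ing <- if (ipk < .N) ipk + which.min(d[(ipk + 1L):.N]) else NA_integer_
    list(peak = i[ipk], neg = if (is.na(ing)) NA_integer_ else i[ing])
  }, by = g]

  # onset: last sample below onset_frac * d[cand[k]] before the upstroke
  # crossing, searched in (cand[k-1], cand[k]] (up to 2 s back)
  back <- as.integer(round(2 * rate))
  i0 <- max(2L, cand[1] - back)
  i_on <- i0:cand[K]
  h <- findInterval(i_on, cand + 0.5) + 1L   # beat whose onset window holds sample i
  thr10 <- onset_frac * dd[cand]
  crossed <- dd[i_on] >= thr10[h] & dd[i_on - 1L] < thr10[h]
  dt_on <- data.table::data.table(i = i_on[crossed], h = h[crossed])
  ons <- dt_on[, list(onset = max(i) - 1L), by = h]

  onset_idx <- rep(NA_integer_, K)
  onset_idx[ons$h] <- ons$onset
  peak_idx <- rep(NA_integer_, K)
  peak_idx[fid$g] <- fid$peak
  neg_idx <- rep(NA_integer_, K)
  neg_idx[fid$g] <- fid$neg

  end_idx <- c(onset_idx[-1L], n)
  flag <- c(rep("", max(K - 1L, 0L)), "edge")
  out <- data.frame(onset_idx = onset_idx, dpdt_max_idx = cand,
                    systolic_peak_idx = peak_idx, neg_dpdt_max_idx = neg_idx,
                    end_idx = end_idx, flag = flag,
                    stringsAsFactors = FALSE)

  # validity: fiducial ordering, onset within reach, no gaps inside the beat
  ok <- !is.na(out$onset_idx) & !is.na(out$systolic_peak_idx) &
    !is.na(out$neg_dpdt_max_idx) & !is.na(out$end_idx) &
    out$onset_idx < out$dpdt_max_idx &
    out$dpdt_max_idx < out$systolic_peak_idx &
    out$systolic_peak_idx < out$neg_dpdt_max_idx &
    out$neg_dpdt_max_idx < out$end_idx &
    (out$dpdt_max_idx - out$onset_idx) <= back
  if (any(ok)) {
    gap_cum <- cumsum(is.na(p))
    has_gap <- gap_cum[out$end_idx] - gap_cum[pmax(out$onset_idx, 1L)] > 0
    has_gap[is.na(has_gap)] <- TRUE
    ok <- ok & !has_gap
  }
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  out$onset_time_s <- (out$onset_idx - 1L) / rate
  out$rr_s <- (out$end_idx - out$onset_idx) / rate
  rownames(out) <- NULL
  out <- out[, c("onset_idx", "dpdt_max_idx", "systolic_peak_idx",
                 "neg_dpdt_max_idx", "end_idx", "onset_time_s", "rr_s", "flag")]
  class(out) <- c("beat_annotation", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  out
}
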