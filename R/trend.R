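#' Summarize per-beat metrics into fixed epochs
#'
#' Beats are assigned to contiguous half-open epochs `[k*epoch_s,
#' (k+1)*epoch_s)` by onset time (20 s by default, the standard telemetry
#' storage epoch). QC-flagged beats are excluded from the means and counted
#' in `artifact_fraction`; epochs with no valid beat carry missing means.
#' Epochs tile the full recording duration without overlap.
#'
#' @param beats Data.frame of per-beat metrics (from
#'   [compute_beat_metrics()]) with `onset_time_s`, the metric columns and
#'   optionally `flag`.
#' @param epoch_s Epoch length in seconds (default 20; must be positive).
#' @param duration_s Recording duration; defaults to the end of the last
#'   beat, rounded up to a whole epoch.
#' @return Data.frame with one row per epoch: `epoch` (0-based), `start_s`,
#'   `end_s`, `n_beats` (valid beats), `artifact_fraction`, and the per-
#'   parameter epoch means under the metric column names.
#' @export
epoch_summarize <- function(beats, epoch_s = 20, duration_s = NULL) {
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch length must be positive")
  params <- intersect(metric_columns(), names(beats))
  if (!length(params)) stop("no metric columns found in `beats`")
  if (is.null(duration_s)) {
    duration_s <- if (nrow(beats)) max(beats$onset_time_s + beats$rr_s) else 0
  }
  n_epochs <- max(1L, as.integer(ceiling(duration_s / epoch_s - 1e-9)))
  flag <- beats$flag
  if (is.null(flag)) flag <- rep("", nrow(beats))
  flag[is.na(flag)] <- ""
  valid <- !nzchar(flag)
  ep <- as.integer(floor(beats$onset_time_s / epoch_s))
  dt <- data.table::as.data.table(beats[, c("onset_time_s", params)])
  dt[, `:=`(epoch = ep, valid = valid)]
  counts <- dt[, list(n_total = .N, n_beats = sum(valid)), by = "epoch"]
  means <- dt[valid == TRUE,
              lapply(.SD, mean), by = "epoch", .SDcols = params]
  out <- data.table::data.table(epoch = 0:(n_epochs - 1L))
  out <- merge(out, counts, by = "epoch", all.x = TRUE)
  out <- merge(out, means, by = "epoch", all.x = TRUE)
  out[is.na(n_total), n_total := 0L]
  out[is.na(n_beats), n_beats := 0L]
  out[, artifact_fraction := ifelse(n_total > 0, 1 - n_beats / n_total, 0)]
  out[, `:=`(start_s = epoch * epoch_s, end_s = (epoch + 1) * epoch_s)]
  data.table::setcolorder(out, c("epoch", "start_s", "end_s", "n_beats",
                                 "artifact_fraction"))
  out[, n_total := NULL]
  as.data.frame(out)
}

#' Moving-average trend over epoch summaries
#'
#' Trailing (right-aligned) moving average of the epoch means, emitted only
#' for complete windows. The SEM is taken over the non-missing epoch means
#' inside the window (`sd/sqrt(n)`), matching the convention of plotting
#' 1-h averages of 20-s epochs with standard-error bars. Missing epochs are
#' excluded from the window mean rather than zero-filled.
#'
#' @param epochs Output of [epoch_summarize()].
#' @param window_s Moving-average window in seconds (default 3600).
#' @return Long-format data.frame of trend points: `center_s` (window
#'   center time), `parameter`, `mean`, `sem`, `n_epochs` (non-missing
#'   epochs in the window).
#' @export
moving_average <- function(epochs, window_s = 3600) {
  epoch_s <- epochs$end_s[1] - epochs$start_s[1]
  k <- window_s / epoch_s
  if (k < 1 || abs(k - round(k)) > 1e-9) {
    stop("window must be a positive whole multiple of the epoch length")
  }
  k <- as.integer(round(k))
  params <- intersect(metric_columns(), names(epochs))
  n <- nrow(epochs)
  if (n < k) {
    return(data.frame(center_s = numeric(), parameter = character(),
                      mean = numeric(), sem = numeric(), n_epochs = integer()))
  }
  pieces <- lapply(params, function(pp) {
    x <- epochs[[pp]]
    ok <- as.numeric(!is.na(x))
    x0 <- ifelse(is.na(x), 0, x)
    s1 <- data.table::frollsum(x0, k)
    s2 <- data.table::frollsum(x0^2, k)
    nn <- data.table::frollsum(ok, k)
    full <- k:n
    s1 <- s1[full]; s2 <- s2[full]; nn <- nn[full]
    m <- ifelse(nn > 0, s1 / nn, NA_real_)
    v <- ifelse(nn > 1, pmax(s2 - s1^2 / pmax(nn, 1), 0) / (nn - 1), NA_real_)
    data.frame(center_s = epochs$end_s[full] - window_s / 2,
               parameter = pp, mean = m,
               sem = ifelse(nn > 1, sqrt(v / nn), NA_real_),
               n_epochs = as.integer(nn))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Daily summaries of epoch means
#'
#' Mean and SEM per parameter over each 24-h block from the recording
#' start, the shape of a per-day baseline table. A partial trailing day is
#' reported with its actual epoch count and flagged.
#'
#' @param epochs Output of [epoch_summarize()].
#' @return Long-format data.frame: `day` (1-based), `parameter`, `mean`,
#'   `sem`, `n_epochs` (non-missing epochs), `partial` (logical), and
#'   `mean_sem` (formatted `"mean +/- sem"` string).
#' @export
daily_summary <- function(epochs) {
  params <- intersect(metric_columns(), names(epochs))
  epoch_s <- epochs$end_s[1] - epochs$start_s[1]
  expected <- 86400 / epoch_s
  day <- floor(epochs$start_s / 86400)
  dt <- data.table::as.data.table(epochs[, params, drop = FALSE])
  dt[, day := day]
  pieces <- lapply(params, function(pp) {
    agg <- dt[, {
      x <- .SD[[pp]]
      x <- x[!is.na(x)]
      nn <- length(x)
      list(mean = if (nn) mean(x) else NA_real_,
           sem = if (nn > 1) stats::sd(x) / sqrt(nn) else NA_real_,
           n_epochs = nn, n_windows = .N)
    }, by = "day", .SDcols = pp]
    data.frame(day = agg$day + 1L, parameter = pp, mean = agg$mean,
               sem = agg$sem, n_epochs = agg$n_epochs,
               partial = agg$n_windows < expected)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$parameter, out$day), ]
  out$mean_sem <- sprintf("%.4g ± %.3g", out$mean, out$sem)
  rownames(out) <- NULL
  out
}
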