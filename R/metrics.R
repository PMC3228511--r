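#' Per-beat hemodynamic indices
#'
#' Computes the eight monitored parameters for every annotated beat: heart
#' rate, mean LVP, LVSP, LVEDP, dP/dt_max, Vmax, -dP/dt_max (as a positive
#' magnitude) and Tau66. Definitions:
#' \itemize{
#'   \item LVSP: maximum pressure between the dP/dt_max and -dP/dt_max
#'     fiducials (earliest sample on ties).
#'   \item LVEDP: pressure at the onset (end-diastole) sample.
#'   \item dP/dt extrema: the derivative value at the respective fiducials.
#'   \item Vmax: maximum of `(dP/dt) / max(P, pressure_floor)` over the
#'     isovolumic contraction window `[onset, dpdt_max]` (1/s). The floor
#'     guards the ratio against division blow-up near zero pressure. Note
#'     that with absolute chamber pressure in the denominator this index is
#'     bounded by `dP/dt_max / LVEDP`; vendor analysis programs print much
#'     larger magnitudes under the same name, so Vmax values are comparable
#'     within, not across, analysis packages.
#'   \item Tau66: time from the -dP/dt_max fiducial to the first downward
#'     crossing of `P_tgt = LVSP - 0.66 * (LVSP - LVEDP)`, with linear
#'     interpolation between the bracketing samples (ms). "Diastolic" in the
#'     66% rule is the same beat's LVEDP.
#'   \item mean LVP: mean pressure over the half-open beat window
#'     `[onset, end)`.
#'   \item heart rate: `60 / rr_s`.
#' }
#' All computations are invariant to time-shifting the recording.
#'
#' @param beats A `beat_annotation` from [detect_beats()].
#' @param recording The [pressure_recording()] the annotations refer to
#'   (optionally pre-smoothed for noisy data; see [analyze_recording()]).
#' @param derivative Aligned derivative series from [estimate_derivative()].
#' @param vmax_floor Pressure floor for the Vmax denominator (default 1 mmHg).
#' @return A data.frame with one row per beat: the fiducial columns of
#'   `beats` plus `heart_rate_bpm`, `mean_lvp_mmHg`, `lvsp_mmHg`,
#'   `lvedp_mmHg`, `dpdt_max_mmHg_per_s`, `vmax_per_s`,
#'   `neg_dpdt_max_mmHg_per_s`, `tau66_ms` and `flag` (detection flags plus
#'   `vmax_undefined` / `tau_unmeasurable` where those indices could not be
#'   computed; the affected value is `NA`).
#' @export
compute_beat_metrics <- function(beats, recording, derivative, vmax_floor = 1) {
  stopifnot(inherits(recording, "pressure_recording"))
  p <- recording$samples
  d <- as.numeric(derivative)
  rate <- recording$sampling_rate_hz
  nb <- nrow(beats)
  out <- as.data.frame(beats)
  if (nb == 0L) {
    for (col in metric_columns()) out[[col]] <- numeric()
    return(out)
  }
  on <- beats$onset_idx; dm <- beats$dpdt_max_idx
  ng <- beats$neg_dpdt_max_idx; en <- beats$end_idx
  flag <- beats$flag
  if (is.null(flag)) flag <- rep("", nb)

  grouped <- function(from, to, fun_expr) {
    lens <- to - from + 1L
    idx <- sequence(lens, from = from)
    g <- rep.int(seq_len(nb), lens)
    dt <- data.table::data.table(g = g, i = idx, p = p[idx], d = d[idx])
    dt[, fun_expr(.SD), by = g]
  }

  lvsp <- grouped(dm, ng, function(s) list(v = max(s$p)))$v
  lvedp <- p[on]
  dpdt_max <- d[dm]
  neg_dpdt <- abs(d[ng])
  mean_lvp <- grouped(on, en - 1L, function(s) list(v = mean(s$p)))$v

  # align the Vmax denominator with the derivative's footprint: a backward
  # difference at sample i estimates the slope at i - 1/2, so divide by the
  # midpoint pressure there
  p_v <- if (identical(attr(derivative, "method"), "backward")) {
    c(p[1], (p[-1] + p[-length(p)]) / 2)
  } else {
    p
  }
  vmax <- grouped_vmax(on, dm, p_v, d, nb, vmax_floor)

  p_tgt <- lvsp - 0.66 * (lvsp - lvedp)
  tau_dt <- {
    lens <- en - ng
    idx <- sequence(lens, from = ng)
    g <- rep.int(seq_len(nb), lens)
    dt <- data.table::data.table(g = g, p = p[idx], tgt = p_tgt[g])
    dt[, {
      below <- p <= tgt[1L]
      jj <- which(below)[1L]
      if (is.na(jj) || jj == 1L || anyNA(p[1:jj])) {
        list(tau = NA_real_)
      } else {
        frac <- (p[jj - 1L] - tgt[1L]) / (p[jj - 1L] - p[jj])
        list(tau = (jj - 2L + frac) / rate * 1000)
      }
    }, by = g]
  }
  tau66 <- rep(NA_real_, nb)
  tau66[tau_dt$g] <- tau_dt$tau

  add_flag <- function(flag, which_beats, label) {
    flag[which_beats] <- paste0(flag[which_beats],
                                ifelse(nzchar(flag[which_beats]), ";", ""), label)
    flag
  }
  flag <- add_flag(flag, which(is.na(vmax)), "vmax_undefined")
  flag <- add_flag(flag, which(is.na(tau66)), "tau_unmeasurable")

  out$heart_rate_bpm <- 60 / beats$rr_s
  out$mean_lvp_mmHg <- mean_lvp
  out$lvsp_mmHg <- lvsp
  out$lvedp_mmHg <- lvedp
  out$dpdt_max_mmHg_per_s <- dpdt_max
  out$vmax_per_s <- vmax
  out$neg_dpdt_max_mmHg_per_s <- neg_dpdt
  out$tau66_ms <- tau66
  out$flag <- flag
  out
}

grouped_vmax <- function(from, to, p, d, nb, vmax_floor) {
  lens <- to - from + 1L
  idx <- sequence(lens, from = from)
  g <- rep.int(seq_len(nb), lens)
  dt <- data.table::data.table(g = g, p = p[idx], d = d[idx])
  dt[, {
    if (all(is.na(p)) || all(p <= 0, na.rm = TRUE)) list(v = NA_real_)
    else list(v = max(d / pmax(p, vmax_floor), na.rm = TRUE))
  }, by = g]$v
}

metric_columns <- function() {
  c("heart_rate_bpm", "mean_lvp_mmHg", "lvsp_mmHg", "lvedp_mmHg",
    "dpdt_max_mmHg_per_s", "vmax_per_s", "neg_dpdt_max_mmHg_per_s",
    "tau66_ms")
}

one_beat <- function(beat) {
  if (is.data.frame(beat) && nrow(beat) == 1L) return(beat)
  if (is.list(beat)) return(as.data.frame(beat))
  stop("`beat` must be a one-row beat annotation")
}

#' Left ventricular systolic pressure of one beat
#' @param beat One-row beat annotation (or list with the fiducial indices).
#' @param recording A [pressure_recording()].
#' @return Peak pressure (mmHg) over `[dpdt_max_idx, neg_dpdt_max_idx]`.
#' @export
compute_lvsp <- function(beat, recording) {
  b <- one_beat(beat)
  win <- b$dpdt_max_idx:b$neg_dpdt_max_idx
  if (length(win) == 0L || all(is.na(recording$samples[win]))) {
    stop("invalid beat: empty or all-gap systolic window")
  }
  max(recording$samples[win], na.rm = TRUE)
}

#' Left ventricular end-diastolic pressure of one beat
#' @inheritParams compute_lvsp
#' @return Pressure (mmHg) at the onset sample.
#' @export
compute_lvedp <- function(beat, recording) {
  b <- one_beat(beat)
  v <- recording$samples[b$onset_idx]
  if (is.na(v)) stop("invalid beat: onset sample falls in a gap")
  v
}

#' dP/dt extrema of one beat
#' @param beat One-row beat annotation.
#' @param derivative Aligned derivative series.
#' @return Named vector `c(dpdt_max =, neg_dpdt_max =)`; the latter is a
#'   positive magnitude.
#' @export
compute_dpdt_extrema <- function(beat, derivative) {
  b <- one_beat(beat)
  d <- as.numeric(derivative)
  c(dpdt_max = d[b$dpdt_max_idx], neg_dpdt_max = abs(d[b$neg_dpdt_max_idx]))
}

#' Vmax (pressure-normalized contractility) of one beat
#' @inheritParams compute_dpdt_extrema
#' @param recording A [pressure_recording()].
#' @param pressure_floor Denominator floor in mmHg (default 1).
#' @return Peak of `(dP/dt)/max(P, pressure_floor)` over
#'   `[onset_idx, dpdt_max_idx]`, in 1/s; `NA` with attribute
#'   `flag = "vmax_undefined"` when pressure is nonpositive throughout.
#' @export
compute_vmax <- function(beat, recording, derivative, pressure_floor = 1) {
  b <- one_beat(beat)
  win <- b$onset_idx:b$dpdt_max_idx
  p <- recording$samples[win]
  if (identical(attr(derivative, "method"), "backward")) {
    prev <- recording$samples[pmax(win - 1L, 1L)]
    p <- (p + prev) / 2
  }
  d <- as.numeric(derivative)[win]
  if (all(is.na(p)) || all(p <= 0, na.rm = TRUE)) {
    return(structure(NA_real_, flag = "vmax_undefined"))
  }
  max(d / pmax(p, pressure_floor), na.rm = TRUE)
}

#' Tau66 relaxation time of one beat
#'
#' Time from the -dP/dt_max fiducial to the first downward crossing of the
#' 66% target pressure, linearly interpolated between the bracketing
#' samples.
#'
#' @inheritParams compute_lvsp
#' @param lvsp,lvedp Systolic and end-diastolic pressure of the beat;
#'   computed from the beat if omitted.
#' @return Tau66 in ms; `NA` with attribute `flag = "tau_unmeasurable"`
#'   when the target is not crossed before the beat end.
#' @export
compute_tau66 <- function(beat, recording, lvsp = NULL, lvedp = NULL) {
  b <- one_beat(beat)
  if (is.null(lvsp)) lvsp <- compute_lvsp(b, recording)
  if (is.null(lvedp)) lvedp <- compute_lvedp(b, recording)
  p_tgt <- lvsp - 0.66 * (lvsp - lvedp)
  win <- b$neg_dpdt_max_idx:(b$end_idx - 1L)
  p <- recording$samples[win]
  below <- p <= p_tgt
  jj <- which(below)[1L]
  if (is.na(jj) || jj == 1L || anyNA(p[1:jj])) {
    return(structure(NA_real_, flag = "tau_unmeasurable"))
  }
  frac <- (p[jj - 1L] - p_tgt) / (p[jj - 1L] - p[jj])
  (jj - 2L + frac) / recording$sampling_rate_hz * 1000
}
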