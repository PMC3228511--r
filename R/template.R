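#' Exponential time constant from a 66%-decay time
#'
#' The relaxation index Tau used here is operational: the time for pressure
#' to drop 66% of the systolic-to-diastolic distance, measured from the
#' -dP/dt_max point. For a monoexponential decay toward an asymptote
#' `floor_mmHg`, `P(t) = floor + (start - floor) * exp(-t / tau_exp)`, the
#' decay reaches the target pressure
#' `P_tgt = lvsp - 0.66 * (lvsp - diastolic)` at
#' `t = tau_exp * log((start - floor) / (P_tgt - floor))`; inverting gives
#' the closed form implemented here.
#'
#' @param tau66_ms Time to the 66% crossing, in milliseconds.
#' @param start_pressure_mmHg Pressure at the start of the decay (the
#'   -dP/dt_max point).
#' @param lvsp_mmHg Systolic pressure of the beat.
#' @param diastolic_mmHg Diastolic pressure used in the 66% rule (same-beat
#'   LVEDP by package convention).
#' @param floor_mmHg Asymptote of the decay, strictly below the target
#'   pressure.
#' @return The exponential time constant `tau_exp` in milliseconds.
#' @examples
#' solve_tau_exp(29, 110, 110, 20, 20)  # 29 / log(1 / 0.34)
#' @export
solve_tau_exp <- function(tau66_ms, start_pressure_mmHg, lvsp_mmHg,
                          diastolic_mmHg, floor_mmHg) {
  if (!is.finite(tau66_ms) || tau66_ms <= 0) stop("tau66_ms must be positive")
  p_tgt <- lvsp_mmHg - 0.66 * (lvsp_mmHg - diastolic_mmHg)
  if (!(floor_mmHg < p_tgt && p_tgt < start_pressure_mmHg)) {
    stop("invalid geometry: need floor < target pressure < start pressure ",
         sprintf("(floor=%.3g, target=%.3g, start=%.3g)",
                 floor_mmHg, p_tgt, start_pressure_mmHg))
  }
  tau66_ms / log((start_pressure_mmHg - floor_mmHg) / (p_tgt - floor_mmHg))
}

# Solve (1 - exp(-x)) / x = rho for x > 0 (rho in (0, 1)). Used to pick the
# time constant of the slope-matched relaxation segment.
solve_decay_shape <- function(rho) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    stop("decay shape ratio must be in (0, 1), got ", rho)
  }
  g <- function(x) (1 - exp(-x)) / x - rho
  upper <- max(10, 4 / rho)
  stats::uniroot(g, c(1e-9, upper), tol = 1e-12)$root
}

# Per-beat template geometry. All pressure arguments in mmHg, slopes in
# mmHg/s, times in seconds. Vectorized over beats; returns a data.frame of
# per-beat segment boundaries and decay constants.
#
# Segments (phase u measured from beat onset, beat length rr):
#   [0, t1)      end-diastolic hold at lvedp
#   [t1, t2)     raised-cosine upstroke lvedp -> lvsp, peak slope = dpdt
#   [t2, t3)     systolic plateau at lvsp
#   [t3, t4)     first half of a raised-cosine fall; slope at t4 = -negdpdt
#   [t4, t5)     slope-matched offset exponential, crosses the Tau target
#                P_tgt exactly at t4 + tau66
#   [t5, t6)     exponential toward the diastolic floor, slope-matched at t5
#   [t6, rr)     raised-cosine refill to lvedp (zero slope at both ends)
beat_geometry <- function(lvsp, lvedp, floor_p, dpdt, negdpdt, tau66_s, rr_s) {
  n <- max(length(lvsp), length(lvedp), length(floor_p), length(dpdt),
           length(negdpdt), length(tau66_s), length(rr_s))
  lvsp <- rep_len(lvsp, n); lvedp <- rep_len(lvedp, n)
  floor_p <- rep_len(floor_p, n); dpdt <- rep_len(dpdt, n)
  negdpdt <- rep_len(negdpdt, n); tau66_s <- rep_len(tau66_s, n)
  rr_s <- rep_len(rr_s, n)

  dp <- lvsp - lvedp
  if (any(dp <= 0)) stop("invalid geometry: lvsp must exceed lvedp")
  p_tgt <- lvsp - 0.66 * dp
  if (any(floor_p >= p_tgt)) {
    stop("invalid geometry: diastolic floor must lie below the Tau target pressure")
  }
  # Pressure drop from the -dP/dt_max point to the Tau target, balancing
  # three constraints: (i) the slope at the 66% crossing must stay above
  # ~20 mmHg/s, else Tau becomes hypersensitive to tiny pressure errors
  # (the decay slope there is negdpdt*exp(-x), so x <= log(negdpdt/20),
  # which the shape function maps to a minimum drop ratio); (ii) the drop
  # must stay below negdpdt*tau66 for the slope-matched segment to be
  # solvable; (iii) the cosine fall above the corner must keep a gentle
  # (>~24 ms) approach so sampled derivatives read the corner faithfully.
  x_max <- log(pmax(negdpdt / 20, 3))
  rho_min <- (1 - exp(-x_max)) / x_max
  d1 <- pmin(pmax(0.33 * dp, rho_min * negdpdt * tau66_s),
             0.7 * negdpdt * tau66_s,
             0.66 * dp - 0.0075 * negdpdt)
  if (any(d1 <= 0.05 * dp)) {
    stop("invalid geometry: -dP/dt_max too large for the available ",
         "systolic-diastolic pressure span")
  }
  p_sw <- p_tgt + d1
  t_rise <- pi * dp / (2 * dpdt)
  t_fall_half <- pi * (lvsp - p_sw) / (2 * negdpdt)   # half of a full cosine fall
  t_plat <- pmin(0.025, 0.10 * rr_s)
  t_hold <- pmin(0.010, 0.04 * rr_s)

  rho <- d1 / (negdpdt * tau66_s)
  x <- vapply(unique(rho), solve_decay_shape, 0)
  names(x) <- as.character(unique(rho))
  x <- unname(x[as.character(rho)])
  tau_a <- tau66_s / x            # slope-matched segment time constant
  b_a <- negdpdt * tau_a          # amplitude; initial slope = -negdpdt exactly
  c_a <- p_sw - b_a               # offset (may lie above or below the floor)
  tau_b <- (p_tgt - floor_p) / (negdpdt * exp(-x))

  t1 <- t_hold
  t2 <- t1 + t_rise
  t3 <- t2 + t_plat
  t4 <- t3 + t_fall_half
  t5 <- t4 + tau66_s
  if (any(t5 > 0.85 * rr_s)) {
    k <- which(t5 > 0.85 * rr_s)[1]
    stop(sprintf(paste0("infeasible beat: systole + relaxation (%.1f ms) does not fit ",
                        "in the RR interval (%.1f ms)"),
                 1000 * t5[k], 1000 * rr_s[k]))
  }
  t6 <- pmax(t5, 0.75 * rr_s)
  p_refill <- floor_p + (p_tgt - floor_p) * exp(-(t6 - t5) / tau_b)

  data.frame(lvsp = lvsp, lvedp = lvedp, floor_p = floor_p, dpdt = dpdt,
             negdpdt = negdpdt, tau66_s = tau66_s, rr_s = rr_s,
             dp = dp, p_tgt = p_tgt, p_sw = p_sw, d1 = d1,
             t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5, t6 = t6,
             t_rise = t_rise, t_fall_half = t_fall_half,
             x = x, tau_a = tau_a, b_a = b_a, c_a = c_a, tau_b = tau_b,
             p_refill = p_refill)
}

# Evaluate the template pressure at phases u (seconds from each sample's beat
# onset) for beats indexed by k into the geometry table. Vectorized over
# samples.
eval_beats <- function(u, k, geo) {
  g <- function(col) geo[[col]][k]
  p <- numeric(length(u))
  t1 <- g("t1"); t2 <- g("t2"); t3 <- g("t3"); t4 <- g("t4")
  t5 <- g("t5"); t6 <- g("t6"); rr <- g("rr_s")

  m <- u < t1
  p[m] <- g("lvedp")[m]

  m <- u >= t1 & u < t2
  p[m] <- g("lvedp")[m] + g("dp")[m] / 2 *
    (1 - cos(pi * (u[m] - t1[m]) / g("t_rise")[m]))

  m <- u >= t2 & u < t3
  p[m] <- g("lvsp")[m]

  m <- u >= t3 & u < t4
  p[m] <- g("lvsp")[m] - (g("lvsp")[m] - g("p_sw")[m]) *
    (1 - cos(pi * (u[m] - t3[m]) / (2 * g("t_fall_half")[m])))

  m <- u >= t4 & u < t5
  p[m] <- g("c_a")[m] + g("b_a")[m] * exp(-(u[m] - t4[m]) / g("tau_a")[m])

  m <- u >= t5 & u < t6
  p[m] <- g("floor_p")[m] + (g("p_tgt")[m] - g("floor_p")[m]) *
    exp(-(u[m] - t5[m]) / g("tau_b")[m])

  m <- u >= t6
  tre <- pmax(rr - t6, 1e-9)
  p[m] <- g("p_refill")[m] + (g("lvedp")[m] - g("p_refill")[m]) / 2 *
    (1 - cos(pi * pmin((u[m] - t6[m]) / tre[m], 1)))
  p
}

# Analytic per-beat ground-truth metrics for a geometry table.
geometry_truth <- function(geo, vmax_floor = 1) {
  with(geo, {
    # mean pressure: closed-form piecewise integrals
    int_hold <- lvedp * t1
    int_rise <- t_rise * (lvedp + dp / 2)
    int_plat <- (t3 - t2) * lvsp
    df <- lvsp - p_sw
    tf <- 2 * t_fall_half
    int_fall <- lvsp * t_fall_half - df * (t_fall_half - tf / pi)
    int_a <- c_a * tau66_s + b_a * tau_a * (1 - exp(-x))
    len_b <- t6 - t5
    int_b <- floor_p * len_b + (p_tgt - floor_p) * tau_b * (1 - exp(-len_b / tau_b))
    int_re <- (p_refill + lvedp) / 2 * (rr_s - t6)
    mean_lvp <- (int_hold + int_rise + int_plat + int_fall + int_a + int_b + int_re) / rr_s

    # Vmax: peak of (dP/dt)/max(P, floor) on the upstroke; interior critical
    # point of the raised cosine at cos(theta*) = 1 / (1 + 2*lvedp/dp)
    cth <- 1 / (1 + 2 * lvedp / dp)
    p_at <- lvedp + dp * (1 - cth) / 2
    vmax <- dpdt * sqrt(1 - cth^2) / pmax(p_at, vmax_floor)

    data.frame(heart_rate_bpm = 60 / rr_s,
               mean_lvp_mmHg = mean_lvp,
               lvsp_mmHg = lvsp,
               lvedp_mmHg = lvedp,
               dpdt_max_mmHg_per_s = dpdt,
               vmax_per_s = vmax,
               neg_dpdt_max_mmHg_per_s = negdpdt,
               tau66_ms = 1000 * tau66_s)
  })
}

#' Continuous-time pressure template for one beat
#'
#' Builds the piecewise-smooth single-beat pressure waveform used by the
#' simulator: an end-diastolic hold, a raised-cosine upstroke whose maximum
#' slope equals the configured dP/dt_max exactly, a brief systolic plateau at
#' LVSP, a cosine fall whose maximum negative slope equals the configured
#' -dP/dt_max, a slope-matched exponential relaxation that crosses the Tau
#' target pressure exactly `tau66_ms` after the -dP/dt_max point, a decay
#' toward the diastolic floor, and a smooth refill to LVEDP at the next
#' onset. Every monitored index therefore has a closed-form location and
#' value on the template.
#'
#' @param config A [sim_config()].
#' @param rr_s Beat length (RR interval) in seconds; must be long enough to
#'   hold all segments, otherwise an infeasible-beat error is raised.
#' @return A list with `f` (vectorized pressure function of time in
#'   `[0, rr_s)` seconds), `geometry` (one-row data.frame of segment
#'   boundaries), and `truth` (one-row data.frame of the beat's analytic
#'   index values).
#' @examples
#' tpl <- beat_template(sim_config(duration_s = 10), 0.25)
#' tpl$truth$lvsp_mmHg
#' @export
beat_template <- function(config, rr_s) {
  stopifnot(inherits(config, "sim_config"))
  geo <- beat_geometry(config$lvsp_mmHg, config$lvedp_mmHg,
                       config$diastolic_floor_mmHg,
                       config$dpdt_max_mmHg_per_s,
                       config$neg_dpdt_max_mmHg_per_s,
                       config$tau66_ms / 1000, rr_s)
  list(f = function(t) eval_beats(t, rep(1L, length(t)), geo),
       geometry = geo,
       truth = geometry_truth(geo))
}
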