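#' Synthetic telemetry simulation configuration
#'
#' Ground-truth physiological parameters driving the synthetic LVP generator.
#' Defaults describe a resting, conscious rabbit at baseline: heart rate in
#' the normal 200-300 bpm band, LVSP ~107 mmHg, LVEDP ~20 mmHg, dP/dt_max
#' ~3000 mmHg/s, -dP/dt_max ~2500 mmHg/s, Tau ~29 ms, sampled at 500 Hz.
#'
#' @param heart_rate_bpm Mean heart rate, beats per minute (must be in
#'   (0, 600)).
#' @param rr_cv Coefficient of variation of the beat-to-beat (RR) interval;
#'   RR intervals are drawn lognormal with this cv.
#' @param lvsp_mmHg Systolic peak pressure.
#' @param lvedp_mmHg End-diastolic pressure (onset pressure of each beat).
#' @param diastolic_floor_mmHg Asymptote of late relaxation; must not exceed
#'   `lvedp_mmHg`. Default `max(0, lvedp_mmHg - 8)`.
#' @param dpdt_max_mmHg_per_s Maximum upstroke slope.
#' @param neg_dpdt_max_mmHg_per_s Maximum fall slope, as a positive magnitude.
#' @param tau66_ms Time from the -dP/dt_max point to a 66% drop of the
#'   systolic-to-diastolic distance, in ms.
#' @param noise_sd_mmHg Additive Gaussian measurement noise sd.
#' @param drift_amplitude_mmHg Amplitude of a sinusoidal circadian baseline
#'   drift added to the whole signal.
#' @param drift_period_h Period of the drift, hours (default 24).
#' @param ectopic_rate Per-beat probability of an ectopic (premature,
#'   attenuated) beat, applied by [inject_artifacts()].
#' @param wall_contact_rate Catheter wall-contact artifact events per hour,
#'   applied by [inject_artifacts()].
#' @param duration_s Recording duration in seconds.
#' @param sampling_rate_hz Output sampling rate (default 500).
#' @param seed Integer seed; all randomness in the simulator derives from it
#'   through fixed per-purpose sub-streams, so toggling one artifact type
#'   does not shift the draws of another.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration_s = 20, rr_cv = 0, noise_sd_mmHg = 0)
#' sim <- simulate_recording(cfg)
#' nrow(sim$truth$beats)  # 20 s at 240 bpm -> 80 complete beats
#' @export
sim_config <- function(heart_rate_bpm = 240, rr_cv = 0.03,
                       lvsp_mmHg = 107, lvedp_mmHg = 20,
                       diastolic_floor_mmHg = NULL,
                       dpdt_max_mmHg_per_s = 3000,
                       neg_dpdt_max_mmHg_per_s = 2500,
                       tau66_ms = 29,
                       noise_sd_mmHg = 0.5,
                       drift_amplitude_mmHg = 2, drift_period_h = 24,
                       ectopic_rate = 0, wall_contact_rate = 0,
                       duration_s = 600, sampling_rate_hz = 500,
                       seed = 1L) {
  if (is.null(diastolic_floor_mmHg)) {
    diastolic_floor_mmHg <- max(0, lvedp_mmHg - 8)
  }
  cfg <- list(heart_rate_bpm = heart_rate_bpm, rr_cv = rr_cv,
              lvsp_mmHg = lvsp_mmHg, lvedp_mmHg = lvedp_mmHg,
              diastolic_floor_mmHg = diastolic_floor_mmHg,
              dpdt_max_mmHg_per_s = dpdt_max_mmHg_per_s,
              neg_dpdt_max_mmHg_per_s = neg_dpdt_max_mmHg_per_s,
              tau66_ms = tau66_ms, noise_sd_mmHg = noise_sd_mmHg,
              drift_amplitude_mmHg = drift_amplitude_mmHg,
              drift_period_h = drift_period_h,
              ectopic_rate = ectopic_rate,
              wall_contact_rate = wall_contact_rate,
              duration_s = duration_s, sampling_rate_hz = sampling_rate_hz,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("heart_rate_bpm", "rr_cv", "lvsp_mmHg", "lvedp_mmHg",
              "diastolic_floor_mmHg", "dpdt_max_mmHg_per_s",
              "neg_dpdt_max_mmHg_per_s", "tau66_ms", "noise_sd_mmHg",
              "drift_amplitude_mmHg", "drift_period_h", "ectopic_rate",
              "wall_contact_rate", "duration_s", "sampling_rate_hz")) {
    if (!num1(cfg[[f]])) stop("sim_config field `", f, "` must be a single finite number")
  }
  if (cfg$heart_rate_bpm <= 0 || cfg$heart_rate_bpm >= 600) {
    stop("heart_rate_bpm must lie in (0, 600)")
  }
  if (!(cfg$diastolic_floor_mmHg <= cfg$lvedp_mmHg &&
        cfg$lvedp_mmHg < cfg$lvsp_mmHg)) {
    stop("pressure ordering violated: need diastolic_floor <= lvedp < lvsp")
  }
  for (f in c("dpdt_max_mmHg_per_s", "neg_dpdt_max_mmHg_per_s", "tau66_ms",
              "duration_s", "sampling_rate_hz", "drift_period_h")) {
    if (cfg[[f]] <= 0) stop("sim_config field `", f, "` must be strictly positive")
  }
  if (cfg$rr_cv < 0) stop("rr_cv must be >= 0")
  if (cfg$noise_sd_mmHg < 0 || cfg$drift_amplitude_mmHg < 0) {
    stop("noise and drift amplitudes must be >= 0")
  }
  if (cfg$ectopic_rate < 0 || cfg$ectopic_rate > 1) stop("ectopic_rate must be in [0, 1]")
  if (cfg$wall_contact_rate < 0) stop("wall_contact_rate must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> HR %g bpm (cv %g), LVSP %g / LVEDP %g mmHg, ",
                     "dP/dt +%g/-%g mmHg/s, Tau66 %g ms, noise %g mmHg, ",
                     "%g s @ %g Hz, seed %d\n"),
              x$heart_rate_bpm, x$rr_cv, x$lvsp_mmHg, x$lvedp_mmHg,
              x$dpdt_max_mmHg_per_s, x$neg_dpdt_max_mmHg_per_s, x$tau66_ms,
              x$noise_sd_mmHg, x$duration_s, x$sampling_rate_hz, x$seed))
  invisible(x)
}

# RNG sub-stream offsets (added to config$seed)
.seed_rr <- 101L
.seed_ectopic <- 303L
.seed_wall <- 404L
.seed_noise_base <- 1000003L  # + 20-s block index

# Draw the RR interval stream for the full duration (deterministic given the
# config seed).
sim_rr_stream <- function(config) {
  rr_mean <- 60 / config$heart_rate_bpm
  n_est <- ceiling(config$duration_s / rr_mean * (1 + 6 * config$rr_cv)) + 20L
  if (config$rr_cv == 0) {
    rr <- rep(rr_mean, n_est)
  } else {
    sdlog <- sqrt(log(1 + config$rr_cv^2))
    meanlog <- log(rr_mean) - sdlog^2 / 2
    set.seed(config$seed + .seed_rr)
    rr <- stats::rlnorm(n_est, meanlog, sdlog)
  }
  rr
}

# Beat plan: one row per beat with onset, RR and per-beat template
# parameters. `artifacts = TRUE` additionally applies the ectopic-beat
# modifications and draws the wall-contact event list.
make_sim_plan <- function(config, artifacts = TRUE) {
  rr <- sim_rr_stream(config)
  onset <- cumsum(c(0, rr))
  keep <- onset < config$duration_s - 1e-12
  onset <- onset[keep]
  rr <- rr[seq_along(onset)]
  n <- length(onset)
  beats <- data.frame(
    beat = seq_len(n), onset_s = onset, rr_s = rr, kind = rep("normal", n),
    lvsp = rep(config$lvsp_mmHg, n), lvedp = rep(config$lvedp_mmHg, n),
    floor_p = rep(config$diastolic_floor_mmHg, n),
    dpdt = rep(config$dpdt_max_mmHg_per_s, n),
    negdpdt = rep(config$neg_dpdt_max_mmHg_per_s, n),
    tau66_s = rep(config$tau66_ms / 1000, n),
    stringsAsFactors = FALSE)

  wall <- data.frame(start_s = numeric(), end_s = numeric(),
                     amp = numeric(), freq = numeric(), phase = numeric())
  if (artifacts) {
    if (config$ectopic_rate > 0) beats <- apply_ectopics(beats, config)
    if (config$wall_contact_rate > 0) {
      set.seed(config$seed + .seed_wall)
      n_ev <- stats::rpois(1, config$wall_contact_rate * config$duration_s / 3600)
      if (n_ev > 0) {
        len <- stats::runif(n_ev, 0.2, 2)
        start <- stats::runif(n_ev, 0, max(config$duration_s - max(len), 0.1))
        wall <- data.frame(start_s = start,
                           end_s = pmin(start + len, config$duration_s),
                           amp = stats::runif(n_ev, 40, 80),
                           freq = stats::runif(n_ev, 25, 45),
                           phase = stats::runif(n_ev, 0, 2 * pi))
        wall <- wall[order(wall$start_s), , drop = FALSE]
      }
    }
  }
  beats$complete <- beats$onset_s + beats$rr_s <= config$duration_s + 1e-9
  geo <- beat_geometry(beats$lvsp, beats$lvedp, beats$floor_p, beats$dpdt,
                       beats$negdpdt, beats$tau66_s, beats$rr_s)
  list(beats = beats, geometry = geo, wall = wall, config = config)
}

# Premature (ectopic) beats: beat k fires early at 62% of the preceding RR,
# with attenuated amplitude and slopes, followed by a compensatory pause.
apply_ectopics <- function(beats, config) {
  set.seed(config$seed + .seed_ectopic)
  draw <- stats::rbinom(nrow(beats), 1L, config$ectopic_rate) == 1L
  n <- nrow(beats)
  min_rr <- function(dp, dpdt, negdpdt, tau66) {
    (0.01 + 0.025 + pi * dp / (2 * dpdt) +
       pi * 0.33 * dp / (2 * negdpdt) + tau66) / 0.85
  }
  for (k in which(draw)) {
    dp <- beats$lvsp[k] - beats$lvedp[k]
    beats$kind[k] <- "ectopic"
    beats$lvsp[k] <- beats$lvedp[k] + 0.65 * dp
    beats$dpdt[k] <- 0.75 * beats$dpdt[k]
    beats$negdpdt[k] <- 0.75 * beats$negdpdt[k]
    if (k > 1 && beats$kind[k - 1] == "normal") {
      new_prev_rr <- 0.62 * beats$rr_s[k - 1]
      dp_prev <- beats$lvsp[k - 1] - beats$lvedp[k - 1]
      feasible <- new_prev_rr >= min_rr(dp_prev, beats$dpdt[k - 1],
                                        beats$negdpdt[k - 1], beats$tau66_s[k - 1])
      if (feasible) {
        shift <- beats$rr_s[k - 1] - new_prev_rr
        beats$rr_s[k - 1] <- new_prev_rr
        beats$onset_s[k] <- beats$onset_s[k] - shift
        beats$rr_s[k] <- beats$rr_s[k] + shift
      }
    }
  }
  beats
}

sim_drift <- function(config, t) {
  if (config$drift_amplitude_mmHg == 0) return(rep(0, length(t)))
  config$drift_amplitude_mmHg * sin(2 * pi * t / (config$drift_period_h * 3600))
}

# Measurement noise drawn in fixed 20-s blocks, each block seeded from the
# config seed plus the block index: chunked rendering reproduces the full-run
# stream exactly regardless of chunk boundaries.
sim_noise <- function(config, i0, n) {
  if (config$noise_sd_mmHg == 0 || n == 0) return(numeric(n))
  fs <- config$sampling_rate_hz
  block_len <- as.integer(round(20 * fs))
  out <- numeric(n)
  b0 <- i0 %/% block_len
  b1 <- (i0 + n - 1L) %/% block_len
  for (b in b0:b1) {
    set.seed(config$seed + .seed_noise_base + b)
    z <- stats::rnorm(block_len, 0, config$noise_sd_mmHg)
    g_start <- b * block_len            # global index of block start (0-based)
    lo <- max(g_start, i0)
    hi <- min(g_start + block_len - 1L, i0 + n - 1L)
    out[(lo - i0 + 1L):(hi - i0 + 1L)] <- z[(lo - g_start + 1L):(hi - g_start + 1L)]
  }
  out
}

# Render samples with 0-based global indices i0 .. i0+n-1 from a plan,
# including drift, noise and wall-contact overlays.
render_range <- function(plan, i0, n) {
  config <- plan$config
  fs <- config$sampling_rate_hz
  t <- (i0 + seq_len(n) - 1) / fs
  k <- findInterval(t, plan$beats$onset_s)
  k[k < 1L] <- 1L
  u <- t - plan$beats$onset_s[k]
  p <- eval_beats(u, k, plan$geometry)
  p <- p + sim_drift(config, t) + sim_noise(config, i0, n)
  if (nrow(plan$wall)) {
    for (j in seq_len(nrow(plan$wall))) {
      w <- plan$wall[j, ]
      if (w$start_s >= t[n] || w$end_s <= t[1]) next
      m <- t >= w$start_s & t < w$end_s
      rel <- (t[m] - w$start_s) / (w$end_s - w$start_s)
      p[m] <- p[m] + w$amp * sin(2 * pi * w$freq * (t[m] - w$start_s) + w$phase) *
        sin(pi * rel)^2
    }
  }
  p
}

plan_truth <- function(plan) {
  config <- plan$config
  cb <- plan$beats$complete
  beats <- cbind(plan$beats[cb, c("beat", "onset_s", "rr_s", "kind")],
                 geometry_truth(plan$geometry[cb, , drop = FALSE]))
  # report onsets at the end-diastolic upstroke foot (end of the diastolic
  # hold), the fiducial a detector anchored on the dP/dt upstroke sees
  beats$onset_s <- beats$onset_s + plan$geometry$t1[cb]
  beats$heart_rate_bpm <- 60 / beats$rr_s
  if (config$drift_amplitude_mmHg > 0) {
    d_on <- sim_drift(config, beats$onset_s)
    d_mid <- sim_drift(config, beats$onset_s + beats$rr_s / 2)
    beats$lvsp_mmHg <- beats$lvsp_mmHg + d_on
    beats$lvedp_mmHg <- beats$lvedp_mmHg + d_on
    beats$mean_lvp_mmHg <- beats$mean_lvp_mmHg + d_mid
  }
  artifacts <- plan$wall[, c("start_s", "end_s"), drop = FALSE]
  if (nrow(artifacts)) artifacts$kind <- "wall_contact"
  else artifacts <- data.frame(start_s = numeric(), end_s = numeric(),
                               kind = character())
  ect <- plan$beats$kind == "ectopic" & cb
  if (any(ect)) {
    artifacts <- rbind(artifacts,
                       data.frame(start_s = plan$beats$onset_s[ect],
                                  end_s = plan$beats$onset_s[ect] + plan$beats$rr_s[ect],
                                  kind = "ectopic"))
    artifacts <- artifacts[order(artifacts$start_s), , drop = FALSE]
  }
  rownames(beats) <- rownames(artifacts) <- NULL
  structure(list(beats = beats, artifacts = artifacts, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d beats (%d ectopic), %d artifact intervals\n",
              nrow(x$beats), sum(x$beats$kind == "ectopic"), nrow(x$artifacts)))
  invisible(x)
}

#' Simulate a telemetric LVP recording with known ground truth
#'
#' Concatenates per-beat templates (see [beat_template()]) with lognormal RR
#' jitter, adds sinusoidal circadian drift and Gaussian measurement noise,
#' and samples the result at the configured rate. Ectopic and wall-contact
#' artifacts are not applied here; see [inject_artifacts()]. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `lvp_simulation`: list with `recording`
#'   (a [pressure_recording()]) and `truth` (a `ground_truth` with the
#'   per-beat analytic index table for every complete beat, and an artifact
#'   interval list).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  plan <- make_sim_plan(config, artifacts = FALSE)
  n <- as.integer(round(config$duration_s * config$sampling_rate_hz))
  p <- render_range(plan, 0L, n)
  rec <- pressure_recording(p, sampling_rate_hz = config$sampling_rate_hz,
                            start_time = "2000-01-01T00:00:00Z",
                            units = "mmHg")
  structure(list(recording = rec, truth = plan_truth(plan), config = config,
                 plan = plan),
            class = "lvp_simulation")
}

#' Inject ectopic-beat and wall-contact artifacts into a simulation
#'
#' Applies the artifact processes configured in the simulation's
#' [sim_config()]: premature ectopic beats (shortened RR, attenuated
#' amplitude and slopes, compensatory pause) drawn per beat with probability
#' `ectopic_rate`, and catheter wall-contact transients (0.2-2 s windows of
#' high-frequency, high-amplitude deflections) drawn as a Poisson process at
#' `wall_contact_rate` events/hour. Each artifact type uses its own RNG
#' sub-stream derived from the config seed, so enabling one does not shift
#' the draws of the other, and the underlying RR/noise streams are
#' unchanged. All injected artifacts are logged in the returned ground
#' truth. With both rates zero the recording is returned unchanged.
#'
#' @param sim An `lvp_simulation` from [simulate_recording()].
#' @param config Optional replacement [sim_config()] (e.g. the same
#'   configuration with nonzero artifact rates); defaults to the
#'   simulation's own config.
#' @return An `lvp_simulation` with artifacts applied and ground truth
#'   updated.
#' @export
inject_artifacts <- function(sim, config = NULL) {
  stopifnot(inherits(sim, "lvp_simulation"))
  if (is.null(config)) config <- sim$config
  stopifnot(inherits(config, "sim_config"))
  if (config$ectopic_rate == 0 && config$wall_contact_rate == 0) return(sim)
  plan <- make_sim_plan(config, artifacts = TRUE)
  n <- length(sim$recording$samples)
  p <- render_range(plan, 0L, n)
  rec <- pressure_recording(p, sampling_rate_hz = config$sampling_rate_hz,
                            start_time = sim$recording$start_time,
                            units = "mmHg")
  structure(list(recording = rec, truth = plan_truth(plan), config = config,
                 plan = plan),
            class = "lvp_simulation")
}

#' Write simulation ground truth to disk
#'
#' The per-beat table goes to CSV (via [write_metrics_table()]); the
#' configuration and artifact interval list go to a JSON sidecar.
#'
#' @param truth A `ground_truth` object.
#' @param csv_path Output path for the beat table.
#' @param json_path Output path for the config/artifact sidecar.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, csv_path, json_path) {
  stopifnot(inherits(truth, "ground_truth"))
  write_metrics_table(truth$beats, csv_path)
  sidecar <- list(config = unclass(truth$config),
                  artifacts = truth$artifacts)
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(csv_path)
}
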