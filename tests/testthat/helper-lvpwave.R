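# Shared helpers: beat-to-ground-truth matching and config sampling.

# Match detected beats to ground-truth beats by onset time.
match_truth <- function(analysis, truth, tol_s = 0.010) {
  tb <- truth$beats
  db <- analysis$beats
  out_t <- integer()
  out_d <- integer()
  for (k in seq_len(nrow(tb))) {
    dif <- abs(db$onset_time_s - tb$onset_s[k])
    j <- which.min(dif)
    if (length(j) && dif[j] <= tol_s) {
      out_t <- c(out_t, k)
      out_d <- c(out_d, j)
    }
  }
  core <- db$flag != "edge"   # trailing truncated beat is not a detection error
  list(truth = tb[out_t, , drop = FALSE],
       det = db[out_d, , drop = FALSE],
       sensitivity = length(out_t) / nrow(tb),
       precision = length(unique(out_d[db$flag[out_d] != "edge"])) /
         max(sum(core), 1L))
}

# Draw a feasible SimConfig across the printed baseline physiological ranges.
# Joint extremes (slow Tau + slow upstroke + short RR) can be geometrically
# infeasible; those draws are rejected and redrawn.
draw_baseline_config <- function(seed, duration_s = 60, noise_sd = 0,
                                 rr_cv = 0.02) {
  set.seed(seed)
  for (try in 1:50) {
    cfg <- try(sim_config(
      heart_rate_bpm = runif(1, 200, 300),
      lvsp_mmHg = runif(1, 99, 114),
      lvedp_mmHg = runif(1, 17, 24),
      dpdt_max_mmHg_per_s = runif(1, 2116, 4126),
      neg_dpdt_max_mmHg_per_s = runif(1, 2099, 3067),
      tau66_ms = runif(1, 22, 54),
      rr_cv = rr_cv, noise_sd_mmHg = noise_sd,
      drift_amplitude_mmHg = 0,
      duration_s = duration_s, seed = seed + try), silent = TRUE)
    if (inherits(cfg, "try-error")) next
    geo <- try(lvpwave:::beat_geometry(cfg$lvsp_mmHg, cfg$lvedp_mmHg,
                             cfg$diastolic_floor_mmHg,
                             cfg$dpdt_max_mmHg_per_s,
                             cfg$neg_dpdt_max_mmHg_per_s,
                             cfg$tau66_ms / 1000,
                             0.85 * 60 / cfg$heart_rate_bpm), silent = TRUE)
    if (!inherits(geo, "try-error")) return(cfg)
  }
  stop("could not draw a feasible config")
}

quiet_analyze <- function(rec, ...) suppressWarnings(analyze_recording(rec, ...))
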