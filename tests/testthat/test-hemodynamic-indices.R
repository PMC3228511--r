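toy_beat <- function(onset, dpdt, peak, neg, end, rr = (end - onset) / 500) {
  data.frame(onset_idx = onset, dpdt_max_idx = dpdt, systolic_peak_idx = peak,
             neg_dpdt_max_idx = neg, end_idx = end, rr_s = rr,
             onset_time_s = (onset - 1) / 500, flag = "")
}

test_that("LVSP is the window maximum (triangular toy beat and brute oracle)", {
  p <- c(seq(20, 100, length.out = 26), seq(100, 20, length.out = 26)[-1])
  rec <- pressure_recording(p, 500)
  b <- toy_beat(1, 10, 26, 45, 51)
  expect_equal(compute_lvsp(b, rec), 100)

  set.seed(3)
  for (case in 1:50) {
    p <- rnorm(100, 60, 20)
    rec <- pressure_recording(p, 500)
    b <- toy_beat(1, 5, 20, 80, 100)
    brute <- -Inf
    for (i in 5:80) brute <- max(brute, p[i])
    expect_identical(compute_lvsp(b, rec), brute)
  }
})

test_that("LVEDP equals the onset-sample pressure exactly", {
  set.seed(4)
  p <- rnorm(60, 30, 5)
  rec <- pressure_recording(p, 500)
  b <- toy_beat(7, 12, 20, 40, 55)
  expect_identical(compute_lvedp(b, rec), p[7])
  p[7] <- NA
  expect_error(compute_lvedp(b, pressure_recording(p, 500)), "gap")
})

test_that("dP/dt extrema are symmetric on a symmetric triangular beat", {
  p <- c(seq(20, 100, length.out = 26), seq(100, 20, length.out = 26)[-1])
  rec <- pressure_recording(p, 500)
  d <- estimate_derivative(rec)
  b <- toy_beat(1, 13, 26, 39, 51)
  ex <- compute_dpdt_extrema(b, d)
  expect_equal(unname(ex["dpdt_max"]), unname(ex["neg_dpdt_max"]))
  expect_gt(ex["dpdt_max"], 0)
})

test_that("Vmax is invariant to uniform pressure scaling and matches a dense oracle", {
  sim <- simulate_recording(sim_config(duration_s = 10, rr_cv = 0,
                                       noise_sd_mmHg = 0, drift_amplitude_mmHg = 0))
  an <- quiet_analyze(sim$recording)
  b <- an$beats[5, ]
  d <- estimate_derivative(sim$recording, "backward")
  v1 <- compute_vmax(b, sim$recording, d)
  rec2 <- sim$recording
  rec2$samples <- rec2$samples * 3
  v2 <- compute_vmax(b, rec2, 3 * d)
  expect_equal(v1, v2, tolerance = 1e-12)

  # dense 100 kHz oracle on the analytic template
  cfg <- sim_config(duration_s = 10)
  tpl <- beat_template(cfg, 0.25)
  tt <- seq(0, tpl$geometry$t2, by = 1e-5)
  pp <- tpl$f(tt)
  dd <- c(diff(pp) / 1e-5, 0)
  oracle <- max(dd / pmax(pp, 1))
  expect_equal(tpl$truth$vmax_per_s, oracle, tolerance = 1e-3)
  # sampled-pipeline Vmax agrees with the analytic value
  med <- median(an$beats$vmax_per_s, na.rm = TRUE)
  expect_equal(med, sim$truth$beats$vmax_per_s[1], tolerance = 0.02)
})

test_that("Vmax flags nonpositive-pressure windows instead of crashing", {
  p <- c(rep(-5, 20), seq(-5, 50, length.out = 30))
  rec <- pressure_recording(p, 500)
  d <- estimate_derivative(rec)
  v <- compute_vmax(toy_beat(1, 15, 40, 45, 50), rec, d)
  expect_true(is.na(v) || is.finite(v))  # floor guards the finite case
  v2 <- compute_vmax(toy_beat(1, 10, 40, 45, 50), pressure_recording(rep(-5, 50), 500),
                     estimate_derivative(pressure_recording(rep(-5, 50), 500)))
  expect_true(is.na(v2))
  expect_equal(attr(v2, "flag"), "vmax_undefined")
})

test_that("Tau66 on a pure exponential matches the analytic crossing", {
  # P(t) = 20 + 90 exp(-t / 25 ms), lvsp 110, lvedp 20 -> target 50.6 mmHg,
  # crossing at 25 * log(90/30.6) ~= 26.97 ms
  t <- (0:499) / 500
  p <- 20 + 90 * exp(-t / 0.025)
  rec <- pressure_recording(p, 500)
  b <- toy_beat(1, 2, 3, 1, 500)
  b$neg_dpdt_max_idx <- 1; b$systolic_peak_idx <- 1; b$dpdt_max_idx <- 1
  tau <- compute_tau66(b, rec, lvsp = 110, lvedp = 20)
  analytic <- 1000 * 0.025 * log(90 / 30.6)
  expect_equal(analytic, 26.9702, tolerance = 1e-5)
  # bisection oracle on the sampled signal
  bis <- uniroot(function(tt) 20 + 90 * exp(-tt / 0.025) - 50.6, c(0, 0.2),
                 tol = 1e-12)$root * 1000
  expect_equal(analytic, bis, tolerance = 1e-6)
  expect_lt(abs(tau - analytic), 2)
})

test_that("Tau66 of a linear decay over T is 0.66 T", {
  n <- 201
  p <- seq(110, 20, length.out = n)  # 0.4 s fall at 500 Hz
  rec <- pressure_recording(p, 500)
  b <- toy_beat(1, 1, 1, 1, n)
  tau <- compute_tau66(b, rec, lvsp = 110, lvedp = 20)
  expect_equal(tau, 0.66 * 400, tolerance = 1e-6)
})

test_that("Tau66 flags beats whose target is never crossed", {
  p <- rep(100, 100)
  rec <- pressure_recording(p, 500)
  tau <- compute_tau66(toy_beat(1, 2, 3, 10, 100), rec, lvsp = 110, lvedp = 20)
  expect_true(is.na(tau))
  expect_equal(attr(tau, "flag"), "tau_unmeasurable")
})

test_that("mean LVP equals the brute half-open window mean and HR is 60/RR", {
  sim <- simulate_recording(sim_config(duration_s = 10, rr_cv = 0,
                                       noise_sd_mmHg = 0, drift_amplitude_mmHg = 0))
  an <- quiet_analyze(sim$recording)
  b <- an$beats[3, ]
  brute <- mean(sim$recording$samples[b$onset_idx:(b$end_idx - 1)])
  expect_equal(b$mean_lvp_mmHg, brute, tolerance = 1e-12)
  expect_equal(an$beats$heart_rate_bpm, 60 / an$beats$rr_s, tolerance = 1e-12)
  expect_equal(60 / 0.25, 240)  # rr 0.25 s <-> 240 bpm
})

test_that("lvedp <= mean LVP <= lvsp on every valid beat", {
  for (seed in c(2, 9)) {
    cfg <- draw_baseline_config(seed, duration_s = 30, noise_sd = 0.5)
    an <- quiet_analyze(simulate_recording(cfg)$recording)
    b <- an$beats[an$beats$flag == "", ]
    expect_true(all(b$lvedp_mmHg <= b$mean_lvp_mmHg + 1e-9))
    expect_true(all(b$mean_lvp_mmHg <= b$lvsp_mmHg + 1e-9))
  }
})

test_that("indices are invariant to shifting the recording in time", {
  sim <- simulate_recording(sim_config(duration_s = 20, rr_cv = 0,
                                       noise_sd_mmHg = 0, drift_amplitude_mmHg = 0))
  a1 <- quiet_analyze(sim$recording)
  shift <- 1000L  # 2 s, a whole number of beats at 240 bpm
  rec2 <- pressure_recording(sim$recording$samples[(shift + 1):length(sim$recording$samples)],
                             500)
  a2 <- quiet_analyze(rec2)
  b1 <- a1$beats[a1$beats$onset_idx > shift + 500 & a1$beats$flag == "", ]
  b2 <- a2$beats[a2$beats$flag == "", ]
  common <- intersect(b1$onset_idx - shift, b2$onset_idx)
  expect_gt(length(common), 20)
  m1 <- b1[match(common, b1$onset_idx - shift), ]
  m2 <- b2[match(common, b2$onset_idx), ]
  expect_equal(m1$lvsp_mmHg, m2$lvsp_mmHg, tolerance = 1e-9)
  expect_equal(m1$tau66_ms, m2$tau66_ms, tolerance = 1e-9)
  expect_equal(m1$dpdt_max_mmHg_per_s, m2$dpdt_max_mmHg_per_s, tolerance = 1e-9)
})
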