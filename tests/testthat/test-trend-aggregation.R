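# Fabricate a beat-metrics table spanning `hours` of recording without
# simulating a waveform: one row per beat at the given rate.
fake_beats <- function(hours, hr = 240, seed = 1, flag_frac = 0) {
  set.seed(seed)
  rr <- 60 / hr
  onset <- seq(0, hours * 3600 - rr, by = rr)
  n <- length(onset)
  df <- data.frame(onset_time_s = onset, rr_s = rr,
                   heart_rate_bpm = hr + rnorm(n),
                   mean_lvp_mmHg = 55 + rnorm(n),
                   lvsp_mmHg = 107 + rnorm(n),
                   lvedp_mmHg = 20 + rnorm(n),
                   dpdt_max_mmHg_per_s = 3000 + 20 * rnorm(n),
                   vmax_per_s = 100 + rnorm(n),
                   neg_dpdt_max_mmHg_per_s = 2500 + 20 * rnorm(n),
                   tau66_ms = 29 + 0.2 * rnorm(n),
                   flag = "")
  if (flag_frac > 0) df$flag[runif(n) < flag_frac] <- "irregular"
  df
}

test_that("72 h of 20-s epochs gives 12960 epochs holding ~80 beats each", {
  beats <- fake_beats(1)  # epoch counting itself only needs the time axis
  ep <- epoch_summarize(beats, epoch_s = 20, duration_s = 72 * 3600)
  expect_equal(nrow(ep), 72 * 3600 / 20)  # 12,960
  full <- ep[ep$n_beats > 0, ]
  expect_true(all(full$n_beats == 80))
  expect_equal(ep$end_s - ep$start_s, rep(20, nrow(ep)))
})

test_that("epoch means equal brute-force group-by means and exclude flagged beats", {
  beats <- fake_beats(0.5, seed = 7, flag_frac = 0.1)
  ep <- epoch_summarize(beats, epoch_s = 20)
  valid <- beats[beats$flag == "", ]
  g <- floor(valid$onset_time_s / 20)
  for (k in sample(unique(g), 10)) {
    expect_equal(ep$lvsp_mmHg[ep$epoch == k],
                 mean(valid$lvsp_mmHg[g == k]), tolerance = 1e-12)
  }
  gall <- floor(beats$onset_time_s / 20)
  k0 <- as.integer(names(which.max(table(gall[beats$flag != ""]))))
  expect_equal(ep$artifact_fraction[ep$epoch == k0],
               mean(beats$flag[gall == k0] != ""), tolerance = 1e-12)
})

test_that("empty epochs carry missing means and zero counts", {
  beats <- fake_beats(0.1)
  beats <- beats[beats$onset_time_s < 100 | beats$onset_time_s > 200, ]
  ep <- epoch_summarize(beats, epoch_s = 20, duration_s = 360)
  hole <- ep$start_s >= 100 & ep$end_s <= 200
  expect_true(all(ep$n_beats[hole] == 0))
  expect_true(all(is.na(ep$lvsp_mmHg[hole])))
  expect_error(epoch_summarize(beats, epoch_s = -1), "positive")
})

test_that("every valid beat lands in exactly one epoch and every epoch in one day", {
  beats <- fake_beats(2, seed = 3, flag_frac = 0.05)
  ep <- epoch_summarize(beats, epoch_s = 20)
  expect_equal(sum(ep$n_beats), sum(beats$flag == ""))
  daily <- daily_summary(ep)
  hr_rows <- daily[daily$parameter == "heart_rate_bpm", ]
  expect_equal(sum(hr_rows$n_epochs), sum(!is.na(ep$heart_rate_bpm)))
})

test_that("moving averages match a brute-force sliding-window oracle", {
  beats <- fake_beats(1.5, seed = 11, flag_frac = 0.02)
  ep <- epoch_summarize(beats, epoch_s = 20)
  ep$lvsp_mmHg[sample(nrow(ep), 15)] <- NA  # missing epochs excluded, not zero-filled
  tr <- moving_average(ep, window_s = 600)   # 30-epoch window
  k <- 30
  lv <- tr[tr$parameter == "lvsp_mmHg", ]
  expect_equal(nrow(lv), nrow(ep) - k + 1)
  for (i in sample(seq_len(nrow(lv)), 25)) {
    w <- ep$lvsp_mmHg[i:(i + k - 1)]
    w <- w[!is.na(w)]
    expect_equal(lv$mean[i], mean(w), tolerance = 1e-9)
    expect_equal(lv$sem[i], sd(w) / sqrt(length(w)), tolerance = 1e-9)
    expect_equal(lv$n_epochs[i], length(w))
  }
  expect_error(moving_average(ep, window_s = 5), "multiple")
})

test_that("a constant epoch series gives a constant trend with zero SEM", {
  beats <- fake_beats(0.5)
  for (col in intersect(names(beats), lvpwave:::metric_columns())) {
    beats[[col]] <- 42
  }
  ep <- epoch_summarize(beats, epoch_s = 20)
  tr <- moving_average(ep, window_s = 300)
  expect_true(all(abs(tr$mean - 42) < 1e-9))
  expect_true(all(tr$sem < 1e-9))
})

test_that("moving averages are invariant to chunking the beat list", {
  beats <- fake_beats(1, seed = 13)
  ep_all <- epoch_summarize(beats, epoch_s = 20, duration_s = 3600)
  cut <- beats$onset_time_s < 1800
  ep_a <- epoch_summarize(beats[cut, ], epoch_s = 20, duration_s = 1800)
  ep_b <- epoch_summarize(beats[!cut, ], epoch_s = 20, duration_s = 3600)
  ep_b <- ep_b[ep_b$start_s >= 1800, ]
  ep_cat <- rbind(ep_a, ep_b)
  ep_cat$epoch <- seq_len(nrow(ep_cat)) - 1L
  t1 <- moving_average(ep_all, 600)
  t2 <- moving_average(ep_cat, 600)
  expect_equal(t1$mean, t2$mean, tolerance = 1e-12)
  expect_equal(t1$sem, t2$sem, tolerance = 1e-12)
})

test_that("daily summaries partition days, flag partial days, and conserve the mean", {
  beats <- fake_beats(30, seed = 17)  # 1 day + 6 h partial
  ep <- epoch_summarize(beats, epoch_s = 20)
  daily <- daily_summary(ep)
  hr <- daily[daily$parameter == "heart_rate_bpm", ]
  expect_equal(nrow(hr), 2L)
  expect_false(hr$partial[1])
  expect_true(hr$partial[2])
  expect_match(hr$mean_sem[1], "±")
  # epoch-count-weighted mean of daily means equals the grand epoch mean
  grand <- mean(ep$heart_rate_bpm, na.rm = TRUE)
  weighted <- sum(hr$mean * hr$n_epochs) / sum(hr$n_epochs)
  expect_equal(weighted, grand, tolerance = 1e-12)
  # daily means equal brute-force means over the day's epochs
  expect_equal(hr$mean[1], mean(ep$heart_rate_bpm[ep$start_s < 86400], na.rm = TRUE),
               tolerance = 1e-12)
})
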