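test_that("heart rate from inter-beat intervals", {
  ibi <- data.frame(time_s = cumsum(rep(0.8, 100)), ibi_s = rep(0.8, 100))
  hr <- heart_rate_from_ibi(ibi, feature_rate_hz = 1)
  expect_true(all(abs(hr$values - 75) < 1e-9))
  expect_equal(hr$channel, "HR")
  ibi2 <- data.frame(time_s = cumsum(rep(1, 60)), ibi_s = rep(1, 60))
  expect_true(all(abs(heart_rate_from_ibi(ibi2)$values - 60) < 1e-9))
  # alternating 0.5/1.0-s beats: interpolated HR bounded by [60, 120]
  iv <- rep(c(0.5, 1), 60)
  ibi3 <- data.frame(time_s = cumsum(iv), ibi_s = iv)
  hr3 <- heart_rate_from_ibi(ibi3)
  expect_true(all(hr3$values >= 60 - 1e-9 & hr3$values <= 120 + 1e-9))
  expect_error(heart_rate_from_ibi(data.frame(time_s = 1, ibi_s = 1)),
               "2 beats")
  expect_error(heart_rate_from_ibi(data.frame(time_s = c(1, 2),
                                              ibi_s = c(1, -1))), "invalid")
})

test_that("round trip: IBIs from a constant heart rate reproduce it", {
  hr <- channel_series(rep(72, 100), "HR", 1, participant_id = "a")
  rr <- channel_series(rep(14, 100), "RR", 1, participant_id = "a")
  raw <- generate_raw_signals(hr, rr, seed = 1)
  hr2 <- heart_rate_from_ibi(raw$ibi, feature_rate_hz = 1, duration_s = 100)
  expect_lt(max(abs(hr2$values - 72)), 1e-9)
})

test_that("RMSSD windows: constants give zero, alternation gives the closed form", {
  ibi <- data.frame(time_s = cumsum(rep(0.85, 200)), ibi_s = rep(0.85, 200))
  hrv <- rmssd_hrv(ibi)
  expect_true(all(hrv$values[!is.na(hrv$values)] == 0))
  # alternating 0.8/0.9 s: every successive difference is 0.1 s -> 100 ms
  iv <- rep(c(0.8, 0.9), 100)
  ibi2 <- data.frame(time_s = cumsum(iv), ibi_s = iv)
  hrv2 <- rmssd_hrv(ibi2)
  mid <- hrv2$values[20:120]
  expect_true(all(abs(mid - 100) < 1e-9))
  # two beats in a window: exactly one difference -> RMSSD = |delta|
  ibi3 <- data.frame(time_s = c(10, 11.2), ibi_s = c(1.0, 1.2))
  hrv3 <- rmssd_hrv(ibi3, window_s = 30, duration_s = 20)
  expect_equal(unique(hrv3$values[!is.na(hrv3$values)]), 200)
})

test_that("RMSSD is invariant to adding a constant to all IBIs", {
  set.seed(2)
  iv <- runif(150, 0.7, 1.0)
  t <- cumsum(iv)
  a <- rmssd_hrv(data.frame(time_s = t, ibi_s = iv), duration_s = 100)
  b <- rmssd_hrv(data.frame(time_s = t, ibi_s = iv + 0.3), duration_s = 100)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("respiration features from a sinusoidal belt waveform", {
  t <- seq(0, 300 - 1 / 8, by = 1 / 8)
  w <- channel_series(sin(2 * pi * 0.2 * t), "RESP_raw", 8,
                      participant_id = "a")
  out <- respiration_features(w, feature_rate_hz = 1)
  rr <- out$RR$values
  expect_true(all(abs(rr - 12) < 0.5))  # 0.2 Hz = 12 breaths/min
  # phase preserved: grid resample crosses zero where the waveform does
  rv <- out$RESP$values
  expect_equal(length(rv), 300)
  expect_lt(abs(mean(rv)), 1e-9)
  # flat waveform: RR undefined with a warning, RESP returned as zeros
  flat <- channel_series(rep(1, 800), "RESP_raw", 8)
  expect_warning(out2 <- respiration_features(flat), "peaks")
  expect_null(out2$RR)
  expect_true(all(out2$RESP$values == 0))
})

test_that("phasic SCR isolates fast transients and absorbs slow trends", {
  rate <- 8
  flat <- channel_series(rep(2, 100 * rate), "EDA_raw", rate)
  expect_true(all(phasic_scr(flat)$values == 0))
  # rectangular impulse of height 1 and 5-s width on a flat baseline
  x <- rep(2, 100 * rate); x[400:440] <- 3
  imp <- phasic_scr(channel_series(x, "EDA_raw", rate))
  expect_gte(max(imp$values), 0.5)
  expect_lte(max(imp$values), 1.0)
  # pure slow ramp: the tonic estimate absorbs it
  ramp <- channel_series(seq(1, 3, length.out = 300 * rate), "EDA_raw", rate)
  out <- phasic_scr(ramp)
  expect_lt(max(out$values), 0.1 * 2)
  expect_error(phasic_scr(channel_series(c(NA, NA, NA), "EDA_raw", 1)),
               "all-missing")
})

test_that("feature series share the grid for a simulated participant", {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 1,
                           duration_s = 120, seed = 9)
  drv <- generate_driver(cfg, "c1")
  aud <- generate_audience(cfg, drv, "c1")
  hr_t <- aud$series[[1]]$HR
  rr_t <- aud$series[[1]]$RR
  raw <- generate_raw_signals(hr_t, rr_t, scr_driver = drv, seed = 4)
  hr <- heart_rate_from_ibi(raw$ibi, 1, duration_s = 120)
  hrv <- rmssd_hrv(raw$ibi, 30, 1, duration_s = 120)
  resp <- respiration_features(raw$resp_waveform, 1)
  scr <- phasic_scr(raw$eda_trace, 1)
  lens <- c(length(hr$values), length(hrv$values), length(resp$RESP$values),
            length(scr$values))
  expect_true(all(lens == 120))
  # derived HR follows the simulated target (beat-rate sampling limits
  # recovery of the fastest fluctuations)
  expect_gt(cor(hr$values, hr_t$values), 0.75)
})
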