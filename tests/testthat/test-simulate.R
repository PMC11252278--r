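test_that("driver is deterministic and follows the AR(1) coefficient", {
  cfg0 <- simulation_config(n_concerts = 1, n_participants_per_concert = 2,
                            duration_s = 1000, driver_ar_coefficient = 1e-9,
                            driver_smooth_s = 0, seed = 4)
  d <- generate_driver(cfg0, "c1")
  expect_lt(abs(acf(d$values, plot = FALSE)$acf[2]), 0.1)  # white noise
  expect_identical(generate_driver(cfg0, "c1")$values, d$values)
  expect_false(identical(generate_driver(cfg0, "c2")$values, d$values))

  cfg95 <- simulation_config(n_concerts = 1, n_participants_per_concert = 2,
                             duration_s = 5000, driver_ar_coefficient = 0.95,
                             driver_smooth_s = 0, seed = 4)
  d95 <- generate_driver(cfg95, "c1")
  expect_equal(acf(d95$values, plot = FALSE)$acf[2], 0.95, tolerance = 0.03)
  expect_equal(mean(d95$values), 0, tolerance = 1e-12)
  expect_equal(sd(d95$values), 1, tolerance = 1e-12)
})

test_that("configuration validation rejects bad values", {
  expect_error(simulation_config(duration_s = -5), "configuration|segments")
  expect_error(simulation_config(driver_ar_coefficient = 1.5), "configuration")
  expect_error(simulation_config(duration_s = 40), "segments")
  expect_error(simulation_config(piece_boundaries_s = data.frame(
    piece = "X", start_s = 100, end_s = 2000)), "boundaries")
  expect_error(simulation_config(piece_boundaries_s = data.frame(
    piece = c("A", "B"), start_s = c(0, 100), end_s = c(200, 300))),
    "disjoint")
})

test_that("audience coupling honours the configuration and RESP is uncoupled", {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 20,
                           duration_s = 120, coupling_mean = 0,
                           coupling_sd = 0, covariate_effects = c(), seed = 3)
  aud <- generate_audience(cfg, generate_driver(cfg, "c1"), "c1")
  expect_true(all(aud$ground_truth$kappa == 0))
  cfg2 <- simulation_config(n_concerts = 1, n_participants_per_concert = 30,
                            duration_s = 120, seed = 3)
  aud2 <- generate_audience(cfg2, generate_driver(cfg2, "c1"), "c1")
  expect_true(all(aud2$ground_truth$kappa[, "RESP"] == 0))
  expect_true(all(aud2$ground_truth$kappa >= 0))
  expect_named(aud2$series[[1]], c("HR", "HRV", "SCR", "RR", "RESP"))
})

test_that("planted covariate effects shape the coupling distribution", {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 500,
                           duration_s = 60, feature_rate_hz = 1,
                           coupling_mean = 0.5,
                           covariate_effects = c(Openness = 0.3), seed = 8)
  aud <- generate_audience(cfg, generate_driver(cfg, "c1"), "c1")
  gt <- aud$ground_truth
  expect_gt(cor(gt$covariates$Openness, gt$kappa[, "HR"]), 0.3)
})

test_that("surveys carry the exact covariates used for coupling", {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 25,
                           duration_s = 120, seed = 5)
  aud <- generate_audience(cfg, generate_driver(cfg, "c1"), "c1")
  sv <- generate_surveys(aud$ground_truth, cfg)
  expect_identical(sv$Openness, aud$ground_truth$covariates$Openness)
  expect_identical(sv$participant_id, aud$ground_truth$participant_id)
  expect_true(all(sv$Extraversion >= 1 & sv$Extraversion <= 5))
  expect_true(all(sv$liked_Dean >= 1 & sv$liked_Dean <= 5))
})

test_that("planted affect changes are detectable and nulls stay null", {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 300,
                           duration_s = 60,
                           affect_change_es = c(PA = 0, NA. = 0.5, VA = 0),
                           seed = 12)
  aud <- generate_audience(cfg, generate_driver(cfg, "c1"), "c1")
  sv <- generate_surveys(aud$ground_truth, cfg)
  expect_lt(t.test(sv$NA_pre, sv$NA_post, paired = TRUE,
                   alternative = "greater")$p.value, 0.01)
  es_pa <- affect_change_effect_size(sv$PA_pre, sv$PA_post)$es
  expect_lt(abs(es_pa), 0.15)
})

test_that("whole-dataset simulation is deterministic and well-formed", {
  cfg <- simulation_config(n_concerts = 2, n_participants_per_concert = 3,
                           duration_s = 120, piece_boundaries_s = data.frame(
                             piece = c("A", "B"), start_s = c(0, 60),
                             end_s = c(60, 120)), seed = 31)
  ds1 <- simulate_concerts(cfg)
  ds2 <- simulate_concerts(cfg)
  expect_identical(ds1$timeseries, ds2$timeseries)
  expect_identical(ds1$survey, ds2$survey)
  # rows = concerts x participants x channels x samples
  expect_equal(nrow(ds1$timeseries), 2 * 3 * 5 * 120)
  expect_equal(nrow(ds1$survey), 6)
  expect_equal(nrow(ds1$concert_meta), 4)
})

test_that("raw-level signals track their feature targets", {
  hr <- channel_series(rep(60, 120), "HR", 1, participant_id = "a")
  rr <- channel_series(rep(12, 120), "RR", 1, participant_id = "a")
  raw <- generate_raw_signals(hr, rr, seed = 2)
  expect_true(all(abs(raw$ibi$ibi_s - 1.0) < 1e-9))  # 60 bpm -> 1-s beats
  # 12 breaths/min -> 5-s period: successive maxima of the waveform 5 s apart
  w <- raw$resp_waveform
  pk <- which(diff(sign(diff(w$values))) == -2) + 1
  expect_equal(median(diff(series_times(w)[pk])), 5, tolerance = 0.1)
  expect_error(generate_raw_signals(
    channel_series(c(-10, rep(60, 10)), "HR", 1), rr), "positive")
})

test_that("zero impulse rate leaves no phasic electrodermal component", {
  hr <- channel_series(rep(70, 120), "HR", 1, participant_id = "a")
  rr <- channel_series(rep(14, 120), "RR", 1, participant_id = "a")
  raw <- generate_raw_signals(hr, rr, impulse_rate_hz = 0, seed = 3)
  scr <- phasic_scr(raw$eda_trace, feature_rate_hz = 1)
  expect_lt(max(scr$values), 0.02)
})

test_that("per-piece coupling multipliers scale the driver term windows", {
  cfg <- simulation_config(
    n_concerts = 1, n_participants_per_concert = 2, duration_s = 120,
    piece_boundaries_s = data.frame(piece = c("A", "B"), start_s = c(0, 60),
                                    end_s = c(60, 120)),
    piece_coupling_multipliers = c(A = 2, B = 0.5), seed = 1)
  mult <- audiencesync:::.piece_multiplier(cfg, 120)
  expect_identical(mult, c(rep(2, 60), rep(0.5, 60)))
})
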