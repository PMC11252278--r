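#' Configuration of the synthetic concert simulator
#'
#' Defines the conditions under which synthetic audiences are generated:
#' a smooth shared stimulus driver per concert, per-participant coupling
#' strengths and response lags, channel-specific autocorrelated noise, an
#' uncoupled respiration-behaviour channel, and survey covariates with
#' planted associations to coupling strength. Defaults emulate an
#' eleven-concert series with three pieces per concert at desk scale
#' (900-s recordings standing in for full-length concerts).
#'
#' @param n_concerts number of concerts (default 11).
#' @param n_participants_per_concert audience size per concert (default 60).
#' @param duration_s recording duration in seconds (default 900).
#' @param feature_rate_hz feature-series sampling rate (default 1 Hz: 30-s
#'   segments hold 30 samples and the +/- 5-s lag window spans +/- 5
#'   samples).
#' @param driver_ar_coefficient AR(1) coefficient of the latent stimulus
#'   driver before smoothing, in (0, 1).
#' @param driver_smooth_s moving-average smoothing window applied to the
#'   driver, in seconds (0 disables smoothing; default 5).
#' @param coupling_mean,coupling_sd mean and jitter SD of the coupling
#'   strength kappa linking a participant's physiology to the driver.
#' @param lag_range_s participant response lags are drawn uniformly in
#'   `+/- lag_range_s` seconds (default 2.5, keeping dyadic lag differences
#'   inside the default +/- 5-s cross-correlation window).
#' @param noise_ar_coefficient AR(1) coefficient of the channel noise.
#' @param noise_sd noise standard deviation relative to the unit-variance
#'   driver (default 1).
#' @param covariate_effects named numeric vector: planted slope of each
#'   covariate (per SD of the covariate) on kappa. Recognized names:
#'   the Big-Five traits, `F1`..`F7`, `PA_change`, `NA_change`,
#'   `VA_change`. Default plants Openness +0.15, Extraversion -0.10,
#'   Neuroticism -0.10.
#' @param piece_boundaries_s data frame (`piece`, `start_s`, `end_s`) of
#'   disjoint ordered piece intervals inside `[0, duration_s]`.
#' @param piece_coupling_multipliers named numeric vector of per-piece
#'   multipliers on kappa (default all 1).
#' @param affect_change_es planted group-level pre-minus-post effect sizes
#'   for the PANAVA scales (positive = decrease), default
#'   `c(PA = 0.08, NA. = 0.37, VA = -0.10)`.
#' @param allow_negative_coupling if `FALSE` (default) kappa is truncated
#'   at 0; `TRUE` permits planted anti-phase coupling.
#' @param seed master seed for all simulator randomness.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_concerts = 11,
                              n_participants_per_concert = 60,
                              duration_s = 900,
                              feature_rate_hz = 1,
                              driver_ar_coefficient = 0.9,
                              driver_smooth_s = 5,
                              coupling_mean = 0.5,
                              coupling_sd = 0.15,
                              lag_range_s = 2.5,
                              noise_ar_coefficient = 0.6,
                              noise_sd = 1,
                              covariate_effects = c(Openness = 0.15,
                                                    Extraversion = -0.10,
                                                    Neuroticism = -0.10),
                              piece_boundaries_s = NULL,
                              piece_coupling_multipliers = NULL,
                              affect_change_es = c(PA = 0.08, NA. = 0.37,
                                                   VA = -0.10),
                              allow_negative_coupling = FALSE,
                              seed = 1L) {
  if (is.null(piece_boundaries_s)) {
    third <- duration_s / 3
    piece_boundaries_s <- data.frame(
      piece = c("Beethoven", "Dean", "Brahms"),
      start_s = c(0, third, 2 * third),
      end_s = c(third, 2 * third, duration_s))
  }
  cfg <- list(n_concerts = as.integer(n_concerts),
              n_participants_per_concert = as.integer(n_participants_per_concert),
              duration_s = duration_s, feature_rate_hz = feature_rate_hz,
              driver_ar_coefficient = driver_ar_coefficient,
              driver_smooth_s = driver_smooth_s,
              coupling_mean = coupling_mean, coupling_sd = coupling_sd,
              lag_range_s = lag_range_s,
              noise_ar_coefficient = noise_ar_coefficient,
              noise_sd = noise_sd,
              covariate_effects = covariate_effects,
              piece_boundaries_s = piece_boundaries_s,
              piece_coupling_multipliers = piece_coupling_multipliers,
              affect_change_es = affect_change_es,
              allow_negative_coupling = isTRUE(allow_negative_coupling),
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

#' Validate a simulation configuration
#' @param cfg a list with `simulation_config` fields.
#' @return the config, invisibly; stops with a configuration error otherwise.
#' @export
validate_simulation_config <- function(cfg) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(cfg$duration_s) || cfg$duration_s <= 0 ||
      !num_ok(cfg$feature_rate_hz) || cfg$feature_rate_hz <= 0 ||
      !num_ok(cfg$driver_ar_coefficient) ||
      cfg$driver_ar_coefficient < 0 || cfg$driver_ar_coefficient >= 1 ||
      !num_ok(cfg$noise_ar_coefficient) ||
      cfg$noise_ar_coefficient < 0 || cfg$noise_ar_coefficient >= 1 ||
      !num_ok(cfg$noise_sd) || cfg$noise_sd < 0 ||
      !num_ok(cfg$lag_range_s) || cfg$lag_range_s < 0 ||
      !num_ok(cfg$coupling_mean) || !num_ok(cfg$coupling_sd) ||
      cfg$coupling_sd < 0 ||
      cfg$n_concerts < 1 || cfg$n_participants_per_concert < 1) {
    stop("invalid simulation configuration")
  }
  if (cfg$duration_s < 60 || round(cfg$duration_s * cfg$feature_rate_hz) < 2) {
    stop("duration must allow at least two 30-s segments")
  }
  pb <- cfg$piece_boundaries_s
  if (!is.null(pb) && nrow(pb) > 0) {
    if (any(pb$start_s < 0) || any(pb$end_s > cfg$duration_s + 1e-9) ||
        any(pb$end_s <= pb$start_s)) {
      stop("piece boundaries must be ordered intervals within [0, duration]")
    }
    if (nrow(pb) > 1 && any(pb$start_s[-1] < pb$end_s[-nrow(pb)] - 1e-9)) {
      stop("piece intervals must be disjoint and ordered")
    }
  }
  invisible(cfg)
}

#' Generate the latent shared stimulus driver of one concert
#'
#' A zero-mean, unit-variance autocorrelated series on the feature grid:
#' AR(1) with coefficient `driver_ar_coefficient`, smoothed by a
#' `driver_smooth_s` moving average (a smooth, band-limited arousal proxy
#' standing in for the music stimulus), then standardized. Deterministic
#' given `(seed, concert_id)`.
#'
#' @param config a [simulation_config()].
#' @param concert_id concert identifier (integer or string).
#' @return a [channel_series()] with channel `"driver"`.
#' @export
generate_driver <- function(config, concert_id) {
  validate_simulation_config(config)
  n <- round(config$duration_s * config$feature_rate_hz)
  seed <- .stream_seed(config$seed, c("driver", as.character(concert_id)))
  x <- .with_seed(seed, .ar1(n, config$driver_ar_coefficient))
  w <- round(config$driver_smooth_s * config$feature_rate_hz)
  if (w > 1) x <- .moving_average(x, w)
  x <- (x - mean(x)) / stats::sd(x)
  channel_series(x, "driver", config$feature_rate_hz,
                 concert_id = as.character(concert_id),
                 participant_id = "stimulus")
}

# Channel display units: intercept + scale applied to the standardized
# series. Affine maps leave all correlations untouched.
.channel_units <- list(HR = c(70, 6), HRV = c(45, 12), SCR = c(0.5, 0.25),
                       RR = c(14, 2.5), RESP = c(0, 1))

# Per-piece coupling multiplier evaluated on the feature grid.
.piece_multiplier <- function(config, n) {
  mult <- rep(1, n)
  pm <- config$piece_coupling_multipliers
  if (is.null(pm)) return(mult)
  t <- (seq_len(n) - 1L) / config$feature_rate_hz
  pb <- config$piece_boundaries_s
  for (r in seq_len(nrow(pb))) {
    p <- as.character(pb$piece[r])
    if (!is.null(pm[[p]])) {
      mult[t >= pb$start_s[r] & t < pb$end_s[r]] <- pm[[p]]
    }
  }
  mult
}

# Draw the covariate pool of one audience. Traits on [1,5]; factor scores
# standard normal; PANAVA pre/post with planted group-level change.
.draw_covariates <- function(config, n) {
  traits <- c("Extraversion", "Agreeableness", "Conscientiousness",
              "Neuroticism", "Openness")
  cov <- list()
  for (tr in traits) cov[[tr]] <- pmin(pmax(stats::rnorm(n, 3, 0.8), 1), 5)
  for (f in paste0("F", 1:7)) cov[[f]] <- stats::rnorm(n)
  panava_mu <- c(PA = 0.7, NA. = -1.0, VA = 1.3)
  panava_sd <- c(PA = 1.0, NA. = 1.0, VA = 1.0)
  for (sc in c("PA", "NA.", "VA")) {
    pre <- stats::rnorm(n, panava_mu[[sc]], panava_sd[[sc]])
    es <- config$affect_change_es[[sc]]
    if (is.null(es)) es <- 0
    # pre - post has mean es * sd(pre): positive es plants a decrease
    post <- pre - es * panava_sd[[sc]] + stats::rnorm(n, 0, 0.6)
    cov[[paste0(sc, "_pre")]] <- pre
    cov[[paste0(sc, "_post")]] <- post
    cov[[paste0(sub("\\.$", "", sc), "_change")]] <-
      (pre - post) / panava_sd[[sc]]
  }
  as.data.frame(cov, check.names = FALSE)
}

# Standardize a covariate column for the kappa linear predictor.
.std_cov <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Generate one synthetic audience
#'
#' Each participant's coupled channel (HR, HRV, SCR, RR) is
#' `kappa * driver(t - lag) + AR(1) noise`, standardized and mapped to
#' plausible channel units; respiration behaviour (RESP) is an independent
#' per-participant oscillator, so its coupling is exactly zero. Coupling
#' `kappa` is `coupling_mean + sum(effects * standardized covariates) +
#' Gaussian jitter`, truncated at zero unless negative coupling is allowed.
#'
#' @param config a [simulation_config()].
#' @param driver the concert driver from [generate_driver()].
#' @param concert_id concert identifier.
#' @return list with `series` (per participant, a named list of
#'   [channel_series()] over HR, HRV, SCR, RR, RESP) and `ground_truth`
#'   (coupling matrix `kappa`, lags, covariates, and the covariate effects
#'   used).
#' @export
generate_audience <- function(config, driver, concert_id) {
  validate_simulation_config(config)
  stopifnot(inherits(driver, "channel_series"))
  n <- length(driver$values)
  np <- config$n_participants_per_concert
  rate <- config$feature_rate_hz
  seed <- .stream_seed(config$seed, c("audience", as.character(concert_id)))
  coupled <- c("HR", "HRV", "SCR", "RR")
  .with_seed(seed, {
    covs <- .draw_covariates(config, np)
    lags <- stats::runif(np, -config$lag_range_s, config$lag_range_s)
    eff <- config$covariate_effects
    lin <- rep(config$coupling_mean, np)
    for (nm in names(eff)) {
      if (!nm %in% names(covs)) stop("unknown covariate in effects: ", nm)
      lin <- lin + eff[[nm]] * .std_cov(covs[[nm]])
    }
    kappa <- matrix(0, np, 5, dimnames = list(NULL, c(coupled, "RESP")))
    for (ch in coupled) {
      k <- lin + stats::rnorm(np, 0, config$coupling_sd)
      if (!config$allow_negative_coupling) k <- pmax(k, 0)
      kappa[, ch] <- k
    }
    mult <- .piece_multiplier(config, n)
    series <- vector("list", np)
    for (i in seq_len(np)) {
      pid <- sprintf("%s_p%03d", as.character(concert_id), i)
      lag_samples <- round(lags[i] * rate)
      drv_i <- .shift_edge(driver$values, lag_samples)
      chans <- list()
      for (ch in coupled) {
        noise <- .ar1(n, config$noise_ar_coefficient) * config$noise_sd
        raw <- kappa[i, ch] * mult * drv_i + noise
        u <- .channel_units[[ch]]
        chans[[ch]] <- channel_series(u[1] + u[2] * .zscore(raw), ch, rate,
                                      concert_id = as.character(concert_id),
                                      participant_id = pid)
      }
      # RESP: independent oscillator; per-participant base frequency with
      # slow drift decorrelates breathing across the audience (kappa = 0)
      f0 <- stats::runif(1, 0.2, 0.3)
      drift <- .ar1(n, 0.98)
      freq <- pmax(f0 * (1 + 0.08 * drift), 0.05)
      phase <- 2 * pi * cumsum(freq) / rate + stats::runif(1, 0, 2 * pi)
      resp <- sin(phase) + stats::rnorm(n, 0, 0.1)
      chans[["RESP"]] <- channel_series(.zscore(resp), "RESP", rate,
                                        concert_id = as.character(concert_id),
                                        participant_id = pid)
      series[[i]] <- chans
    }
    pids <- vapply(series, function(s) s$HR$participant_id, character(1))
    covs <- cbind(concert_id = as.character(concert_id),
                  participant_id = pids, covs)
    gt <- list(concert_id = as.character(concert_id),
               participant_id = pids, kappa = kappa, lag_s = lags,
               covariates = covs, covariate_effects = eff)
    list(series = stats::setNames(series, pids), ground_truth = gt)
  })
}

#' Generate the survey table of one audience
#'
#' Emits per participant the Big-Five traits, PANAVA positive activation
#' (PA), negative activation (NA) and valence (VA) pre and post concert
#' (with the planted mean changes), the orthogonal experience factor scores
#' F1-F7, and nine experience items per piece on a 1-5 scale. Covariates
#' are exactly those used to build the coupling strengths.
#'
#' @param ground_truth the `ground_truth` element of [generate_audience()].
#' @param config a [simulation_config()].
#' @return a data frame with one row per participant.
#' @export
generate_surveys <- function(ground_truth, config) {
  validate_simulation_config(config)
  covs <- ground_truth$covariates
  np <- nrow(covs)
  out <- data.frame(concert_id = covs$concert_id,
                    participant_id = covs$participant_id)
  for (tr in c("Extraversion", "Agreeableness", "Conscientiousness",
               "Neuroticism", "Openness")) out[[tr]] <- covs[[tr]]
  out$PA_pre <- covs$PA_pre;   out$PA_post <- covs$PA_post
  out$NA_pre <- covs$`NA._pre`; out$NA_post <- covs$`NA._post`
  out$VA_pre <- covs$VA_pre;   out$VA_post <- covs$VA_post
  for (f in paste0("F", 1:7)) out[[f]] <- covs[[f]]
  items <- c("liked", "knew", "annoyed", "moved", "interesting",
             "inspired", "melancholic", "happy", "bored")
  # item means loosely follow the piece-evaluation pattern: the
  # contemporary piece is liked/known least but found no less interesting
  item_mu <- list(
    Beethoven = c(4.0, 3.5, 1.5, 3.3, 3.5, 3.2, 2.8, 3.5, 1.8),
    Dean      = c(3.0, 1.5, 2.3, 3.0, 3.6, 3.2, 2.6, 2.4, 2.1),
    Brahms    = c(4.0, 3.2, 1.5, 3.5, 3.5, 3.3, 3.0, 3.6, 1.8))
  seed <- .stream_seed(config$seed, c("survey", covs$concert_id[1L]))
  .with_seed(seed, {
    for (p in as.character(config$piece_boundaries_s$piece)) {
      mu <- item_mu[[p]]
      if (is.null(mu)) mu <- rep(3, length(items))
      for (k in seq_along(items)) {
        col <- paste0(items[k], "_", p)
        out[[col]] <- pmin(pmax(round(stats::rnorm(np, mu[k], 0.8)), 1), 5)
      }
    }
  })
  out
}

#' Generate raw-level signals for one participant
#'
#' Produces the three raw signal types from feature-level targets, for
#' end-to-end exercise of the feature-derivation stage: inter-beat
#' intervals such that `60 / IBI` tracks the HR series; a respiration
#' waveform (sinusoid with instantaneous frequency `RR / 60`); and an
#' electrodermal trace built from a slow tonic drift plus Poisson impulses
#' (rate modulated by `scr_driver`) convolved with a bi-exponential kernel.
#'
#' @param hr a [channel_series()] of target heart rate (beats/min, all
#'   positive).
#' @param rr a [channel_series()] of target respiration rate (breaths/min).
#' @param scr_driver optional [channel_series()] modulating the impulse
#'   rate (e.g. the concert driver); `NULL` gives a constant rate.
#' @param raw_rate_hz sampling rate of the respiration/EDA traces
#'   (default 8).
#' @param impulse_rate_hz baseline skin-conductance impulse rate per second
#'   (default 0.05; 0 yields a purely tonic trace).
#' @param seed integer seed.
#' @return list with `ibi` (data frame `time_s`, `ibi_s`), `resp_waveform`
#'   and `eda_trace` (both [channel_series()] at `raw_rate_hz`).
#' @export
generate_raw_signals <- function(hr, rr, scr_driver = NULL, raw_rate_hz = 8,
                                 impulse_rate_hz = 0.05, seed = 1L) {
  stopifnot(inherits(hr, "channel_series"), inherits(rr, "channel_series"))
  if (any(hr$values <= 0, na.rm = TRUE)) stop("target HR must be positive")
  dur <- length(hr$values) / hr$rate_hz
  hr_t <- series_times(hr)
  # beat times: step forward by the instantaneous inter-beat interval
  beats <- numeric(0)
  t <- 0
  while (t < dur) {
    h <- stats::approx(hr_t, hr$values, t, rule = 2)$y
    ibi <- 60 / h
    t <- t + ibi
    if (t < dur) beats <- c(beats, t)
  }
  if (length(beats) < 2L) stop("duration too short for two beats")
  ibi_df <- data.frame(time_s = beats, ibi_s = diff(c(0, beats)))
  n_raw <- round(dur * raw_rate_hz)
  raw_t <- (seq_len(n_raw) - 1L) / raw_rate_hz
  rr_inst <- stats::approx(series_times(rr), rr$values, raw_t, rule = 2)$y
  resp <- sin(2 * pi * cumsum(rr_inst / 60) / raw_rate_hz)
  resp_cs <- channel_series(resp, "RESP_raw", raw_rate_hz,
                            concert_id = hr$concert_id,
                            participant_id = hr$participant_id)
  eda <- .with_seed(seed, {
    tonic <- 2 + 0.5 * sin(2 * pi * raw_t / max(dur, 1)) +
      cumsum(stats::rnorm(n_raw, 0, 0.001))
    rate <- rep(impulse_rate_hz, n_raw)
    if (!is.null(scr_driver)) {
      drv <- stats::approx(series_times(scr_driver), scr_driver$values,
                           raw_t, rule = 2)$y
      rate <- impulse_rate_hz * exp(0.8 * .zscore(drv))
    }
    impulses <- stats::rpois(n_raw, rate / raw_rate_hz)
    k_t <- seq(0, 10, by = 1 / raw_rate_hz)
    kernel <- exp(-k_t / 2) - exp(-k_t / 0.75)  # bi-exponential SCR shape
    kernel <- kernel / max(kernel)
    phasic <- stats::convolve(impulses, rev(kernel), type = "open")[seq_len(n_raw)]
    pmax(tonic + 0.4 * phasic, 0)
  })
  eda_cs <- channel_series(eda, "EDA_raw", raw_rate_hz,
                           concert_id = hr$concert_id,
                           participant_id = hr$participant_id)
  list(ibi = ibi_df, resp_waveform = resp_cs, eda_trace = eda_cs)
}

#' Simulate a full concert series
#'
#' Runs [generate_driver()], [generate_audience()] and [generate_surveys()]
#' for every concert and assembles the long-format dataset the pipeline
#' consumes.
#'
#' @param config a [simulation_config()].
#' @return list of class `concert_dataset`: `timeseries` (long data frame:
#'   `concert_id`, `participant_id`, `channel`, `time_s`, `value`),
#'   `survey`, `concert_meta` (piece boundaries per concert),
#'   `ground_truth` (per concert), and `series` (nested list of
#'   [channel_series()], concert -> participant -> channel).
#' @export
simulate_concerts <- function(config = simulation_config()) {
  validate_simulation_config(config)
  ts_list <- list(); surveys <- list(); gts <- list(); nested <- list()
  meta <- list()
  for (k in seq_len(config$n_concerts)) {
    cid <- sprintf("concert%02d", k)
    driver <- generate_driver(config, cid)
    aud <- generate_audience(config, driver, cid)
    surveys[[cid]] <- generate_surveys(aud$ground_truth, config)
    gts[[cid]] <- aud$ground_truth
    nested[[cid]] <- aud$series
    meta[[cid]] <- cbind(concert_id = cid, config$piece_boundaries_s)
    for (pid in names(aud$series)) {
      for (ch in names(aud$series[[pid]])) {
        s <- aud$series[[pid]][[ch]]
        ts_list[[length(ts_list) + 1L]] <- data.frame(
          concert_id = cid, participant_id = pid, channel = ch,
          time_s = series_times(s), value = s$values)
      }
    }
  }
  structure(list(timeseries = do.call(rbind, ts_list),
                 survey = do.call(rbind, c(surveys, make.row.names = FALSE)),
                 concert_meta = do.call(rbind, c(meta, make.row.names = FALSE)),
                 ground_truth = gts, series = nested, config = config),
            class = "concert_dataset")
}
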