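#' Heart rate from inter-beat intervals
#'
#' Instantaneous heart rate `60 / IBI` (beats per minute) evaluated at beat
#' times and linearly interpolated onto the uniform feature grid.
#'
#' @param ibi data frame with columns `time_s` (beat timestamps, seconds)
#'   and `ibi_s` (inter-beat intervals, seconds, all positive).
#' @param feature_rate_hz target grid rate in Hz.
#' @param duration_s grid duration; defaults to the last beat time.
#' @param concert_id,participant_id identifiers for the output series.
#' @return a [channel_series()] with channel `"HR"`.
#' @export
heart_rate_from_ibi <- function(ibi, feature_rate_hz = 1, duration_s = NULL,
                                concert_id = NA, participant_id = NA) {
  stopifnot(is.data.frame(ibi), all(c("time_s", "ibi_s") %in% names(ibi)))
  if (nrow(ibi) < 2L) stop("need at least 2 beats")
  if (any(ibi$ibi_s <= 0)) stop("invalid signal: non-positive inter-beat interval")
  if (is.null(duration_s)) duration_s <- max(ibi$time_s)
  grid <- seq(0, duration_s - 1 / feature_rate_hz, by = 1 / feature_rate_hz)
  hr <- stats::approx(ibi$time_s, 60 / ibi$ibi_s, grid, rule = 2)$y
  channel_series(hr, "HR", feature_rate_hz, concert_id = concert_id,
                 participant_id = participant_id)
}

#' RMSSD heart-rate variability series
#'
#' Root mean square of successive inter-beat-interval differences, in
#' milliseconds, over sliding windows centered on the feature-grid points.
#' A window needs at least two beats (one successive difference) for a
#' defined value; undefined windows are marked missing.
#'
#' @inheritParams heart_rate_from_ibi
#' @param window_s window duration in seconds (default 30, matching the
#'   SUSY segment length).
#' @return a [channel_series()] with channel `"HRV"` (RMSSD in ms).
#' @export
rmssd_hrv <- function(ibi, window_s = 30, feature_rate_hz = 1,
                      duration_s = NULL, concert_id = NA,
                      participant_id = NA) {
  stopifnot(is.data.frame(ibi), all(c("time_s", "ibi_s") %in% names(ibi)))
  if (any(ibi$ibi_s <= 0)) stop("invalid signal: non-positive inter-beat interval")
  if (is.null(duration_s)) duration_s <- max(ibi$time_s)
  grid <- seq(0, duration_s - 1 / feature_rate_hz, by = 1 / feature_rate_hz)
  half <- window_s / 2
  vals <- vapply(grid, function(t0) {
    inwin <- ibi$time_s >= t0 - half & ibi$time_s <= t0 + half
    v <- ibi$ibi_s[inwin]
    if (length(v) < 2L) return(NA_real_)
    d <- diff(v) * 1000  # ms
    sqrt(mean(d^2))
  }, numeric(1))
  if (all(is.na(vals))) {
    warning("no window contains two beats; HRV is all-missing")
  }
  channel_series(vals, "HRV", feature_rate_hz, concert_id = concert_id,
                 participant_id = participant_id)
}

# Local-maximum peak detection with minimum prominence and spacing.
# Prominence is measured against the lowest saddle toward a higher peak on
# either side (simplified to the running minima between candidate peaks).
.find_peaks <- function(x, rate_hz, min_prominence, min_spacing_s) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    left <- if (k == 1L) min(x[1:i]) else min(x[cand[k - 1L]:i])
    right <- if (k == length(cand)) min(x[i:n]) else min(x[i:cand[k + 1L]])
    keep[k] <- (x[i] - max(left, right)) >= min_prominence
  }
  pk <- cand[keep]
  # enforce minimum spacing, keeping the higher peak
  min_gap <- round(min_spacing_s * rate_hz)
  if (length(pk) > 1L && min_gap > 0L) {
    sel <- pk[1L]
    for (p in pk[-1L]) {
      last <- sel[length(sel)]
      if (p - last >= min_gap) sel <- c(sel, p)
      else if (x[p] > x[last]) sel[length(sel)] <- p
    }
    pk <- sel
  }
  pk
}

#' Respiration features from a belt waveform
#'
#' Respiration rate (RR) is `60 / inter-peak interval` from peak detection
#' (local maxima with minimum prominence 0.25 x SD and minimum spacing
#' 1.5 s), interpolated to the feature grid. Respiration behaviour (RESP)
#' is the waveform itself, z-scored and resampled to the grid with phase
#' information preserved.
#'
#' @param waveform a [channel_series()] holding the belt-distension
#'   waveform (rate at least 4x the maximum plausible breath frequency).
#' @param feature_rate_hz target grid rate in Hz.
#' @return list with `RR` and `RESP` [channel_series()]. If fewer than two
#'   peaks are found, `RR` is `NULL` (with a warning) and `RESP` is still
#'   returned.
#' @export
respiration_features <- function(waveform, feature_rate_hz = 1) {
  stopifnot(inherits(waveform, "channel_series"))
  x <- waveform$values
  t <- series_times(waveform)
  dur <- length(x) / waveform$rate_hz
  grid <- seq(waveform$t0_s, waveform$t0_s + dur - 1 / feature_rate_hz,
              by = 1 / feature_rate_hz)
  resp_vals <- stats::approx(t, x, grid, rule = 2)$y
  resp <- channel_series(.zscore(resp_vals), "RESP", feature_rate_hz,
                         t0_s = waveform$t0_s,
                         concert_id = waveform$concert_id,
                         participant_id = waveform$participant_id)
  s <- stats::sd(x)
  pk <- if (is.finite(s) && s > 0) {
    .find_peaks(x, waveform$rate_hz, 0.25 * s, 1.5)
  } else integer(0)
  if (length(pk) < 2L) {
    warning("fewer than 2 respiration peaks detected; RR undefined")
    return(list(RR = NULL, RESP = resp))
  }
  mid <- (t[pk[-1L]] + t[pk[-length(pk)]]) / 2
  rr_inst <- 60 / diff(t[pk])
  rr <- stats::approx(mid, rr_inst, grid, rule = 2)$y
  list(RR = channel_series(rr, "RR", feature_rate_hz, t0_s = waveform$t0_s,
                           concert_id = waveform$concert_id,
                           participant_id = waveform$participant_id),
       RESP = resp)
}

#' Phasic skin-conductance response from an electrodermal trace
#'
#' The tonic level is estimated by a centered 20-s moving median and
#' subtracted; negative residuals are clipped at zero and the result is
#' resampled to the feature grid. This moving-median detrending isolates
#' the fast phasic component (SCR) whose temporal shape drives the
#' synchrony analysis.
#'
#' @param eda a [channel_series()] holding the non-negative electrodermal
#'   trace.
#' @param feature_rate_hz target grid rate in Hz.
#' @param tonic_window_s moving-median window in seconds (default 20).
#' @return a [channel_series()] with channel `"SCR"`.
#' @export
phasic_scr <- function(eda, feature_rate_hz = 1, tonic_window_s = 20) {
  stopifnot(inherits(eda, "channel_series"))
  x <- eda$values
  if (all(is.na(x))) stop("electrodermal trace is all-missing")
  k <- round(tonic_window_s * eda$rate_hz)
  if (k %% 2 == 0) k <- k + 1L
  k <- max(min(k, length(x) - (1 - length(x) %% 2)), 1L)
  tonic <- stats::runmed(x, k, endrule = "median")
  phasic <- pmax(x - tonic, 0)
  t <- series_times(eda)
  dur <- length(x) / eda$rate_hz
  grid <- seq(eda$t0_s, eda$t0_s + dur - 1 / feature_rate_hz,
              by = 1 / feature_rate_hz)
  vals <- stats::approx(t, phasic, grid, rule = 2)$y
  channel_series(vals, "SCR", feature_rate_hz, t0_s = eda$t0_s,
                 concert_id = eda$concert_id,
                 participant_id = eda$participant_id)
}
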