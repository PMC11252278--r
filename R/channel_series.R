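#' Feature-series container
#'
#' A `channel_series` holds one participant's one-channel feature time series
#' on a uniform grid. Values are in channel units: HR beats/min, HRV (RMSSD)
#' ms, RR breaths/min, SCR microsiemens-equivalent arbitrary units, RESP
#' normalized displacement. Missing samples are `NA`.
#'
#' @param values numeric vector of feature values (may contain `NA`).
#' @param channel one of `"HR"`, `"HRV"`, `"SCR"`, `"RR"`, `"RESP"`, or a
#'   free-form label for non-physiological series (e.g. the latent driver).
#' @param rate_hz sampling rate of the uniform grid in Hz.
#' @param t0_s time of the first sample in seconds.
#' @param concert_id,participant_id identifiers carried through the pipeline.
#' @return an object of class `channel_series`.
#' @export
channel_series <- function(values, channel, rate_hz = 1, t0_s = 0,
                           concert_id = NA_character_,
                           participant_id = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("channel_series needs at least one sample")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a positive finite number")
  }
  if (any(is.infinite(values))) stop("values must be finite or NA")
  structure(
    list(values = values, channel = as.character(channel),
         rate_hz = rate_hz, t0_s = as.numeric(t0_s),
         concert_id = as.character(concert_id),
         participant_id = as.character(participant_id)),
    class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series %s> participant %s, concert %s\n",
              x$channel, x$participant_id, x$concert_id))
  cat(sprintf("  %d samples at %g Hz, t0 = %g s, %d missing\n",
              length(x$values), x$rate_hz, x$t0_s, sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.channel_series <- function(x) length(x$values)

#' Sample times of a channel series
#' @param x a `channel_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "channel_series"))
  x$t0_s + (seq_along(x$values) - 1L) / x$rate_hz
}

#' Extract the sub-series inside a time window
#'
#' Keeps samples with `start_s <= t < end_s` and resets `t0_s` to the first
#' retained sample. Used to slice a concert recording into pieces.
#'
#' @param x a `channel_series`.
#' @param start_s,end_s window boundaries in seconds.
#' @return a `channel_series` restricted to the window.
#' @export
window_series <- function(x, start_s, end_s) {
  stopifnot(inherits(x, "channel_series"))
  t <- x$t0_s + (seq_along(x$values) - 1L) / x$rate_hz
  keep <- t >= start_s & t < end_s
  if (!any(keep)) stop("window contains no samples")
  channel_series(x$values[keep], x$channel, x$rate_hz,
                 t0_s = t[which(keep)[1L]],
                 concert_id = x$concert_id,
                 participant_id = x$participant_id)
}
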