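# Independent brute-force implementations used as oracles. These loop
# directly over segments and lags and share no code with the package
# internals.

# Brute-force SUSY observed Z: direct loops, pairwise-complete Pearson.
oracle_observed_Z <- function(xv, yv, seg_len, max_lag, min_frac = 0.8) {
  n_seg <- length(xv) %/% seg_len
  seg_means <- numeric(0)
  for (s in seq_len(n_seg)) {
    xs <- xv[((s - 1) * seg_len + 1):(s * seg_len)]
    ys <- yv[((s - 1) * seg_len + 1):(s * seg_len)]
    zs <- numeric(0)
    for (tau in (-max_lag):max_lag) {
      m <- seg_len
      if (m - abs(tau) < max(3, ceiling(min_frac * m))) next
      if (tau >= 0) { a <- xs[1:(m - tau)]; b <- ys[(1 + tau):m] }
      else { a <- xs[(1 - tau):m]; b <- ys[1:(m + tau)] }
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < max(3, ceiling(min_frac * m))) next
      a <- a[ok]; b <- b[ok]
      if (sd(a) == 0 || sd(b) == 0) next
      r <- cor(a, b)
      zs <- c(zs, atanh(min(max(r, -0.999), 0.999)))
    }
    if (length(zs) > 0) seg_means <- c(seg_means, mean(zs))
  }
  mean(seg_means)
}

# White-noise channel series helper.
wn_series <- function(n, id = "a", channel = "HR", rate = 1, sd = 1) {
  channel_series(rnorm(n, sd = sd), channel, rate, participant_id = id)
}

# Shared-driver dyad: two participants coupled to one latent driver with
# strength kappa, via the package simulator, single concert.
driver_dyad <- function(kappa, noise_sd = 1, seed = 1, duration_s = 600) {
  cfg <- simulation_config(n_concerts = 1, n_participants_per_concert = 2,
                           duration_s = duration_s, coupling_mean = kappa,
                           coupling_sd = 0, covariate_effects = c(),
                           noise_sd = noise_sd, seed = seed)
  drv <- generate_driver(cfg, "c1")
  aud <- generate_audience(cfg, drv, "c1")
  list(x = aud$series[[1]]$HR, y = aud$series[[2]]$HR)
}
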