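#' Parameters for surrogate synchrony (SUSY)
#'
#' Controls segmentation, the lag window, the surrogate null, and the RNG.
#' Defaults follow the standard SUSY setup: 30-s segments with lags up to
#' +/- 5 s, so all cross-correlations inside a ten-second window (the
#' cross-correlation range L) enter the statistic.
#'
#' @param segment_length_s segment duration in seconds (default 30).
#' @param max_lag_s maximum lag in seconds in each direction (default 5);
#'   must be smaller than `segment_length_s`.
#' @param n_surrogates number of surrogate segment alignments (default 100).
#'   For small segment counts the number of distinct derangements caps this.
#' @param min_overlap_fraction minimum fraction of a segment that must
#'   overlap (and be non-missing) for a lag or segment to be used (default
#'   0.8).
#' @param rng_seed master seed; per-dyad surrogate streams are derived from
#'   it and the dyad identity, so results are reproducible regardless of
#'   evaluation order.
#' @param surrogate_mode `"derangement"` (each surrogate realigns the whole
#'   segment sequence by a random fixed-point-free permutation) or
#'   `"segment_pairs"` (the n(n-1) ordered mismatched segment pairs each
#'   yield one surrogate value).
#' @return an object of class `susy_params`.
#' @export
susy_params <- function(segment_length_s = 30, max_lag_s = 5,
                        n_surrogates = 100, min_overlap_fraction = 0.8,
                        rng_seed = 1L,
                        surrogate_mode = c("derangement", "segment_pairs")) {
  surrogate_mode <- match.arg(surrogate_mode)
  stopifnot(segment_length_s > 0, max_lag_s >= 0,
            max_lag_s < segment_length_s,
            n_surrogates >= 1,
            min_overlap_fraction > 0, min_overlap_fraction <= 1)
  structure(list(segment_length_s = segment_length_s, max_lag_s = max_lag_s,
                 n_surrogates = as.integer(n_surrogates),
                 min_overlap_fraction = min_overlap_fraction,
                 rng_seed = as.integer(rng_seed),
                 surrogate_mode = surrogate_mode),
            class = "susy_params")
}

#' Fisher's Z transform of a correlation
#'
#' `arctanh(r)` after clipping `r` to +/- 0.999 so that degenerate identical
#' segments (r = 1) stay finite and can be averaged.
#'
#' @param r correlation value(s) in \[-1, 1\] (NA allowed).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  bad <- !is.na(r) & abs(r) > 1 + 1e-10
  if (any(bad)) stop("correlation outside [-1, 1]")
  atanh(pmin(pmax(r, -0.999), 0.999))
}

#' Cut a series into SUSY segments
#'
#' Consecutive non-overlapping segments of `segment_length_s`; a trailing
#' partial segment is dropped. Segments missing more than
#' `1 - min_overlap_fraction` of their samples are flagged unusable.
#'
#' @param series a [channel_series()].
#' @param params a [susy_params()].
#' @return list with `segments` (matrix, one column per segment), `usable`
#'   (logical per segment), and `n_dropped` (trailing samples discarded).
#' @export
segment_series <- function(series, params = susy_params()) {
  stopifnot(inherits(series, "channel_series"))
  m <- round(params$segment_length_s * series$rate_hz)
  if (m < 2) stop("segment_length_s x rate_hz must be at least 2 samples")
  n_seg <- length(series$values) %/% m
  if (n_seg < 2) {
    stop("series shorter than 2 segments; surrogate alignment impossible")
  }
  mat <- matrix(series$values[seq_len(n_seg * m)], nrow = m)
  usable <- colMeans(is.na(mat)) <= (1 - params$min_overlap_fraction)
  list(segments = mat, usable = usable,
       n_dropped = length(series$values) - n_seg * m)
}

# --- internal: per-series preparation for fast lagged correlations --------

# Standardize columns to zero mean / unit Euclidean norm; zero-variance
# columns become all-NA so crossprod yields NA correlations.
.colstd <- function(M) {
  M <- sweep(M, 2L, colMeans(M), "-")
  nrm <- sqrt(colSums(M^2))
  bad <- !is.finite(nrm) | nrm < .Machine$double.eps^0.5
  nrm[bad] <- 1
  M <- sweep(M, 2L, nrm, "/")
  M[, bad] <- NA_real_
  M
}

# Precompute, for one series, segment matrix plus head/tail standardized
# truncations for every lag magnitude 0..Lmax. Reused across all dyads a
# participant enters, which makes all-pairs audience computation cheap.
.susy_prep <- function(series, params) {
  seg <- segment_series(series, params)
  m <- nrow(seg$segments)
  lmax <- round(params$max_lag_s * series$rate_hz)
  if (lmax >= m) stop("max_lag_s must be below segment_length_s")
  has_na <- anyNA(seg$segments)
  head_s <- vector("list", lmax + 1L)
  tail_s <- vector("list", lmax + 1L)
  if (!has_na) {
    for (a in 0:lmax) {
      head_s[[a + 1L]] <- .colstd(seg$segments[seq_len(m - a), , drop = FALSE])
      tail_s[[a + 1L]] <- .colstd(seg$segments[(1L + a):m, , drop = FALSE])
    }
  }
  list(segments = seg$segments, usable = seg$usable, m = m, lmax = lmax,
       n_seg = ncol(seg$segments), has_na = has_na,
       head_s = head_s, tail_s = tail_s,
       rate_hz = series$rate_hz,
       concert_id = series$concert_id,
       participant_id = series$participant_id,
       channel = series$channel)
}

# Pearson correlation of overlapping parts of two segments at one lag,
# excluding missing samples pairwise; NA if overlap support is too small
# or either side is constant.
.lag_cor_slow <- function(xs, ys, a, sign_pos, min_n) {
  m <- length(xs)
  if (sign_pos) { xv <- xs[seq_len(m - a)]; yv <- ys[(1L + a):m] }
  else          { xv <- xs[(1L + a):m];     yv <- ys[seq_len(m - a)] }
  ok <- !is.na(xv) & !is.na(yv)
  if (sum(ok) < min_n) return(NA_real_)
  xv <- xv[ok]; yv <- yv[ok]
  sx <- stats::sd(xv); sy <- stats::sd(yv)
  if (sx == 0 || sy == 0) return(NA_real_)
  stats::cor(xv, yv)
}

# Full cross-segment correlation tensor between two prepared series:
# R[i, j, l] = cor(x segment i at time t, y segment j at time t + tau_l),
# tau_l running from -lmax..+lmax samples. Positive lag means y lags x.
.corr_tensor <- function(px, py, params) {
  stopifnot(px$m == py$m, px$lmax == py$lmax)
  m <- px$m; lmax <- px$lmax
  min_n <- max(3, ceiling(params$min_overlap_fraction * m))
  lags <- (-lmax):lmax
  R <- array(NA_real_, dim = c(px$n_seg, py$n_seg, length(lags)))
  fast <- !px$has_na && !py$has_na
  for (li in seq_along(lags)) {
    tau <- lags[li]; a <- abs(tau)
    if (m - a < min_n) next  # lag undefined: overlap too short
    if (fast) {
      R[, , li] <- if (tau >= 0) {
        crossprod(px$head_s[[a + 1L]], py$tail_s[[a + 1L]])
      } else {
        crossprod(px$tail_s[[a + 1L]], py$head_s[[a + 1L]])
      }
    } else {
      for (i in seq_len(px$n_seg)) {
        for (j in seq_len(py$n_seg)) {
          R[i, j, li] <- .lag_cor_slow(px$segments[, i], py$segments[, j],
                                       a, tau >= 0, min_n)
        }
      }
    }
  }
  attr(R, "lags") <- lags
  R
}

# Mean over defined lags of Fisher-Z transformed correlations:
# G[i, j] = mean_tau fisher_z(R[i, j, tau]). NaN where no lag is defined.
.lagmean_z <- function(R) {
  Z <- fisher_z(R)
  cnt <- rowSums(!is.na(Z), dims = 2L)
  G <- rowSums(Z, na.rm = TRUE, dims = 2L) / cnt
  G[cnt == 0L] <- NA_real_
  G
}

#' Lagged cross-correlations of one segment pair
#'
#' Pearson correlation of `x_seg[t]` with `y_seg[t + tau]` for integer-sample
#' lags `tau` in `-max_lag..+max_lag` (positive lag: y lags x), on the
#' truncated overlap. Lags with too little overlap or zero variance are `NA`.
#'
#' @param x_seg,y_seg numeric vectors of equal length (one segment each).
#' @param params a [susy_params()].
#' @param rate_hz sampling rate of the segments in Hz.
#' @return named numeric vector of correlations, names = lag in samples.
#' @export
segment_cross_correlations <- function(x_seg, y_seg, params = susy_params(),
                                       rate_hz = 1) {
  stopifnot(length(x_seg) == length(y_seg))
  m <- length(x_seg)
  lmax <- round(params$max_lag_s * rate_hz)
  min_n <- max(3, ceiling(params$min_overlap_fraction * m))
  lags <- (-lmax):lmax
  r <- vapply(lags, function(tau) {
    if (m - abs(tau) < min_n) return(NA_real_)
    .lag_cor_slow(x_seg, y_seg, abs(tau), tau >= 0, min_n)
  }, numeric(1))
  stats::setNames(r, lags)
}

# Shared validation and preparation for a dyad.
.dyad_prep <- function(x, y, params) {
  stopifnot(inherits(x, "channel_series"), inherits(y, "channel_series"))
  if (x$rate_hz != y$rate_hz) stop("series must share the feature grid")
  if (length(x$values) != length(y$values)) {
    stop("series must have equal length on the shared grid")
  }
  list(px = .susy_prep(x, params), py = .susy_prep(y, params))
}

#' Observed synchrony Z of a dyad
#'
#' Mean over usable segments of the per-segment mean (over defined lags) of
#' Fisher-Z transformed lagged cross-correlations. Non-absolute values are
#' used throughout, so in-phase synchrony gives Z > 0 and anti-phase Z < 0.
#'
#' @param x,y [channel_series()] on the same grid.
#' @param params a [susy_params()].
#' @return list with `Z` and `n_segments` (segments actually used).
#' @export
observed_Z <- function(x, y, params = susy_params()) {
  pr <- .dyad_prep(x, y, params)
  G <- .lagmean_z(.corr_tensor(pr$px, pr$py, params))
  use <- pr$px$usable & pr$py$usable
  seg_z <- diag(G)[use]
  seg_z <- seg_z[!is.na(seg_z)]
  if (length(seg_z) == 0L) stop("no usable segment for this dyad")
  list(Z = mean(seg_z), n_segments = length(seg_z))
}

# --- derangements ---------------------------------------------------------

# Subfactorial D(n): number of permutations without fixed points.
.count_derangements <- function(n) {
  if (n == 0L) return(1)
  if (n == 1L) return(0)
  d2 <- 1; d1 <- 0
  for (k in 2:n) { d <- (k - 1) * (d1 + d2); d2 <- d1; d1 <- d }
  d1
}

# Enumerate all derangements of 1..n (only called for small n).
.all_derangements <- function(n) {
  res <- list()
  rec <- function(prefix, remaining) {
    pos <- length(prefix) + 1L
    if (length(remaining) == 0L) { res[[length(res) + 1L]] <<- prefix; return() }
    for (v in remaining) {
      if (v != pos) rec(c(prefix, v), setdiff(remaining, v))
    }
  }
  rec(integer(0), seq_len(n))
  res
}

# One uniform random derangement by rejection sampling.
.random_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

# Surrogate Z values from a precomputed lag-mean matrix G restricted to the
# usable segments. Each derangement sigma realigns x segment i with y
# segment sigma(i); its surrogate Z is the mean over segments of G.
.surrogates_from_G <- function(G, use, params, seed) {
  idx <- which(use)
  k <- length(idx)
  if (k < 2L) stop("need at least 2 usable segments for surrogates")
  Gu <- G[idx, idx, drop = FALSE]
  if (params$surrogate_mode == "segment_pairs") {
    vals <- Gu[row(Gu) != col(Gu)]
    return(vals[!is.na(vals)])
  }
  n_distinct <- .count_derangements(k)
  if (k == 2L) {
    warning("only 2 usable segments: a single surrogate alignment exists")
  }
  sigmas <- if (k <= 7L && n_distinct <= params$n_surrogates) {
    .all_derangements(k)
  } else {
    .with_seed(seed, replicate(params$n_surrogates,
                               .random_derangement(k), simplify = FALSE))
  }
  vapply(sigmas, function(sg) {
    v <- Gu[cbind(seq_len(k), sg)]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
}

#' Surrogate synchrony distribution of a dyad
#'
#' Builds the null by realigning y's segment sequence with seeded random
#' derangements (no segment is ever paired with itself) and recomputing the
#' Z aggregation for each alignment. For small segment counts all distinct
#' derangements are enumerated instead of sampled.
#'
#' @inheritParams observed_Z
#' @param seed optional integer overriding the stream seed derived from
#'   `params$rng_seed` and the dyad identity.
#' @return numeric vector of surrogate Z values.
#' @export
surrogate_Z <- function(x, y, params = susy_params(), seed = NULL) {
  pr <- .dyad_prep(x, y, params)
  G <- .lagmean_z(.corr_tensor(pr$px, pr$py, params))
  if (is.null(seed)) seed <- .dyad_stream_seed(pr$px, pr$py, params, "concert")
  .surrogates_from_G(G, pr$px$usable & pr$py$usable, params, seed)
}

# Seed for a dyad's surrogate stream, keyed by the unordered pair identity
# so computation order and argument order cannot change results.
.dyad_stream_seed <- function(px, py, params, scope) {
  ids <- sort(c(px$participant_id, py$participant_id))
  .stream_seed(params$rng_seed,
               c(px$concert_id, px$channel, ids, scope))
}

#' Dyadic surrogate synchrony (SUSY)
#'
#' Computes the observed synchrony Z, the surrogate null distribution, and
#' the effect size `ES = (Z - mean(Zsurr)) / sd(Zsurr)` for one pair of
#' series. Symmetric in its arguments: the pair is put in canonical order by
#' participant id, and the surrogate RNG stream is keyed by the unordered
#' pair, so `dyad_synchrony(x, y)` and `dyad_synchrony(y, x)` agree exactly.
#'
#' @inheritParams observed_Z
#' @param scope label for the analysis window, e.g. `"concert"` or a piece
#'   name; part of the surrogate RNG key.
#' @return a list of class `dyad_result` with elements `id1`, `id2`,
#'   `channel`, `scope`, `Z`, `Zsurr_mean`, `Zsurr_sd`, `ES`, `n_segments`,
#'   `n_surrogates_used`, and the raw `Zsurr` vector.
#' @export
dyad_synchrony <- function(x, y, params = susy_params(), scope = "concert") {
  # canonical order: makes ES exactly symmetric under argument swap
  if (!is.na(x$participant_id) && !is.na(y$participant_id) &&
      x$participant_id > y$participant_id) {
    tmp <- x; x <- y; y <- tmp
  }
  pr <- .dyad_prep(x, y, params)
  G <- .lagmean_z(.corr_tensor(pr$px, pr$py, params))
  use <- pr$px$usable & pr$py$usable
  seg_z <- diag(G)[use]
  seg_z <- seg_z[!is.na(seg_z)]
  if (length(seg_z) == 0L) stop("no usable segment for this dyad")
  Z <- mean(seg_z)
  seed <- .dyad_stream_seed(pr$px, pr$py, params, scope)
  zs <- .surrogates_from_G(G, use, params, seed)
  zs <- zs[!is.na(zs)]
  zs_sd <- stats::sd(zs)
  es <- if (length(zs) >= 2L && is.finite(zs_sd) && zs_sd > 0) {
    (Z - mean(zs)) / zs_sd
  } else NA_real_
  structure(list(id1 = x$participant_id, id2 = y$participant_id,
                 channel = x$channel, scope = scope,
                 Z = Z, Zsurr_mean = mean(zs), Zsurr_sd = zs_sd,
                 ES = es, n_segments = length(seg_z),
                 n_surrogates_used = length(zs), Zsurr = zs),
            class = "dyad_result")
}

#' @export
print.dyad_result <- function(x, ...) {
  cat(sprintf("<dyad %s-%s %s/%s> Z = %.4f, Zsurr = %.4f (%.4f), ES = %.2f [%d segments, %d surrogates]\n",
              x$id1, x$id2, x$channel, x$scope, x$Z, x$Zsurr_mean,
              x$Zsurr_sd, x$ES, x$n_segments, x$n_surrogates_used))
  invisible(x)
}
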