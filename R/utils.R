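# Internal helpers: seeded RNG streams and small numeric utilities.

# Deterministic 31-bit hash of a character key (polynomial rolling hash).
# Doubles carry the arithmetic exactly: 31 * (2^31 - 1) < 2^53.
.hash31 <- function(key) {
  h <- 0
  for (code in utf8ToInt(paste(key, collapse = "\r"))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Combine a master seed with a key into a stream seed < 2^31.
.stream_seed <- function(master_seed, key) {
  as.integer((as.double(master_seed) %% 2147483647 * 48271 +
                .hash31(key)) %% 2147483647)
}

# Evaluate expr with a local RNG state; global .Random.seed is untouched.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# AR(1) series with unit marginal variance (innovation sd scaled), length n.
.ar1 <- function(n, phi, innov_sd = sqrt(1 - phi^2)) {
  x <- numeric(n)
  e <- stats::rnorm(n, sd = innov_sd)
  x[1L] <- e[1L] / sqrt(max(1 - phi^2, .Machine$double.eps))
  for (t in seq_len(n)[-1L]) x[t] <- phi * x[t - 1L] + e[t]
  x
}

# Centered moving average with edge shrinkage (window of w samples).
.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# z-score with a guard for zero variance (returns zeros, with attribute).
.zscore <- function(x) {
  mu <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mu) / s
}

# Shift a vector by k samples (positive k delays), extending edge values.
.shift_edge <- function(x, k) {
  n <- length(x)
  if (abs(k) >= n) stop("requested lag exceeds series length")
  if (k == 0L) return(x)
  if (k > 0L) c(rep(x[1L], k), x[seq_len(n - k)])
  else c(x[(1L - k):n], rep(x[n], -k))
}
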