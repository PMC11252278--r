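test_that("fisher_z matches arctanh and applies the clipping rule", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  # r = 1 is clipped to 0.999 before the transform
  expect_equal(fisher_z(1), 3.800201, tolerance = 1e-6)
  expect_equal(fisher_z(-1), -fisher_z(1))
  expect_error(fisher_z(1.2), "outside")
  expect_true(is.na(fisher_z(NA)))
})

test_that("segmentation cuts 30-s blocks, drops the partial tail, needs 2 segments", {
  p <- susy_params()
  s600 <- channel_series(rnorm(600), "HR", 1)
  seg <- segment_series(s600, p)
  expect_equal(ncol(seg$segments), 20)
  expect_equal(seg$n_dropped, 0)
  s615 <- channel_series(rnorm(615), "HR", 1)
  seg <- segment_series(s615, p)
  expect_equal(ncol(seg$segments), 20)
  expect_equal(seg$n_dropped, 15)
  expect_error(segment_series(channel_series(rnorm(45), "HR", 1), p),
               "2 segments")
})

test_that("segments with too many missing samples are flagged unusable", {
  p <- susy_params()
  v <- rnorm(120)
  v[31:45] <- NA  # second segment 50% missing
  seg <- segment_series(channel_series(v, "HR", 1), p)
  expect_identical(seg$usable, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("lagged cross-correlations recover a constructed shift", {
  set.seed(1)
  x <- rnorm(30)
  expect_equal(unname(segment_cross_correlations(x, x)[["0"]]), 1)
  # y lags x by 2 samples: maximum correlation at tau = +2
  y <- c(rnorm(2), x[1:28])
  r <- segment_cross_correlations(x, y)
  expect_equal(names(which.max(r)), "2")
  # constant segment: zero variance, all lags undefined
  expect_true(all(is.na(segment_cross_correlations(rep(1, 30), x))))
})

test_that("observed_Z equals the brute-force oracle", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(c(120, 300, 600), 1)
    xv <- as.numeric(arima.sim(list(ar = 0.5), n))
    yv <- 0.5 * xv + rnorm(n)
    x <- channel_series(xv, "HR", 1, participant_id = "a")
    y <- channel_series(yv, "HR", 1, participant_id = "b")
    got <- observed_Z(x, y)
    expect_equal(got$Z, oracle_observed_Z(xv, yv, 30, 5), tolerance = 1e-12)
  }
})

test_that("observed_Z with missing samples matches the pairwise-complete oracle", {
  set.seed(21)
  xv <- rnorm(150); yv <- 0.6 * xv + rnorm(150)
  xv[c(10:12, 40, 95)] <- NA
  yv[c(70:72)] <- NA
  x <- channel_series(xv, "HR", 1, participant_id = "a")
  y <- channel_series(yv, "HR", 1, participant_id = "b")
  expect_equal(observed_Z(x, y)$Z, oracle_observed_Z(xv, yv, 30, 5),
               tolerance = 1e-12)
})

test_that("identical series give strongly positive Z, mirrored series negative Z", {
  set.seed(3)
  x <- wn_series(600, "a")
  y <- channel_series(x$values, "HR", 1, participant_id = "b")
  # the lag-0 term contributes arctanh(0.999)/11 per segment; the other ten
  # lags of white noise average out near zero
  z_id <- observed_Z(x, y)$Z
  expect_equal(z_id, atanh(0.999) / 11, tolerance = 0.15)
  expect_gt(z_id, 0.3)
  neg <- channel_series(-x$values + rnorm(600, sd = 0.05), "HR", 1,
                        participant_id = "b")
  expect_lt(observed_Z(x, neg)$Z, 0)
})

test_that("independent white noise has small Z", {
  set.seed(11)
  x <- wn_series(600, "a"); y <- wn_series(600, "b")
  expect_lt(abs(observed_Z(x, y)$Z), 0.2)
})

test_that("Z is exactly symmetric and invariant to positive affine maps", {
  set.seed(5)
  x <- wn_series(300, "a"); y <- wn_series(300, "b")
  p <- susy_params(rng_seed = 5)
  d1 <- dyad_synchrony(x, y, p); d2 <- dyad_synchrony(y, x, p)
  expect_equal(d1$Z, d2$Z, tolerance = 1e-12)
  expect_equal(d1$ES, d2$ES, tolerance = 1e-12)
  x2 <- channel_series(3.7 * x$values + 42, "HR", 1, participant_id = "a")
  expect_equal(observed_Z(x2, y)$Z, observed_Z(x, y)$Z, tolerance = 1e-12)
})

test_that("surrogate alignments are deterministic derangements", {
  set.seed(9)
  x <- wn_series(600, "a"); y <- wn_series(600, "b")
  p <- susy_params(rng_seed = 42)
  expect_identical(surrogate_Z(x, y, p), surrogate_Z(x, y, p))
  # 2 segments: a single derangement (the swap), with a warning
  x2 <- wn_series(60, "a"); y2 <- wn_series(60, "b")
  expect_warning(zs2 <- surrogate_Z(x2, y2, p), "single surrogate")
  expect_length(zs2, 1)
  # 3 segments: exactly the 2 distinct derangements
  x3 <- wn_series(90, "a"); y3 <- wn_series(90, "b")
  expect_length(surrogate_Z(x3, y3, p), 2)
})

test_that("derangement utilities: counts and no fixed points", {
  expect_equal(audiencesync:::.count_derangements(2), 1)
  expect_equal(audiencesync:::.count_derangements(3), 2)
  expect_equal(audiencesync:::.count_derangements(4), 9)
  ders <- audiencesync:::.all_derangements(4)
  expect_length(ders, 9)
  for (d in ders) expect_false(any(d == seq_along(d)))
})

test_that("segment_pairs surrogate mode yields n(n-1) values", {
  set.seed(13)
  x <- wn_series(150, "a"); y <- wn_series(150, "b")  # 5 segments
  p <- susy_params(surrogate_mode = "segment_pairs")
  expect_length(surrogate_Z(x, y, p), 5 * 4)
})

test_that("dyad ES is large for a strongly coupled pair, NA when surrogates degenerate", {
  d <- driver_dyad(1, noise_sd = 0.3, seed = 2)
  res <- dyad_synchrony(d$x, d$y, susy_params(rng_seed = 2))
  expect_gt(res$ES, 2)
  expect_equal(res$ES, (res$Z - res$Zsurr_mean) / res$Zsurr_sd)
})
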