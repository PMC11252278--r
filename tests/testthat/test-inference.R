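test_that("affect change effect size matches hand computation", {
  expect_equal(affect_change_effect_size(c(1, 2, 3), c(1, 2, 3))$es, 0)
  # pre = (0, 2), post = (-1, 1): (1 - 0) / sd(c(0, 2)) = 1 / sqrt(2)
  out <- affect_change_effect_size(c(0, 2), c(-1, 1))
  expect_equal(out$es, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(out$change, c(1 / sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)
  # increase (post > pre) gives a negative effect size
  expect_lt(affect_change_effect_size(c(1, 2, 3), c(2, 3, 4))$es, 0)
  expect_error(affect_change_effect_size(c(1, 1), c(0, 2)), "zero")
})

test_that("paired pre/post t-tests per concert and pooled", {
  pre <- c(1, 2, 3, 4); post <- pre
  expect_warning(tt <- prepost_ttest(pre, post), "zero variance")
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  expect_warning(tt2 <- prepost_ttest(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_true(tt2$degenerate)
  expect_true(is.na(tt2$t))
  set.seed(15)
  pre <- rnorm(60, 0, 1); post <- pre - 0.5 + rnorm(60, 0, 0.7)
  res <- prepost_ttest(pre, post, concert = rep(c("c1", "c2"), each = 30))
  expect_equal(nrow(res), 3)  # two concerts + pooled row
  expect_lt(res$p[res$concert == "all"], 0.05)
  expect_gt(res$es[res$concert == "all"], 0)
})

test_that("within-group centering zeroes every group mean", {
  expect_equal(center_within_group(c(1, 2, 3), rep("g", 3)), c(-1, 0, 1))
  x <- c(-1, 0, 1)
  expect_equal(center_within_group(x, rep("g", 3)), x)
  v <- c(1, 2, 10, 20)
  g <- c("a", "a", "b", "b")
  cv <- center_within_group(v, g)
  expect_equal(as.numeric(tapply(cv, g, mean)), c(0, 0), tolerance = 1e-12)
  expect_error(center_within_group(c(NA, 1), c("a", "b")), "non-missing")
})

test_that("random-intercept model recovers a planted slope", {
  set.seed(33)
  g <- rep(sprintf("c%02d", 1:10), each = 60)
  offs <- rnorm(10, 0, 1)[as.integer(factor(g))]
  x <- rnorm(600)
  d <- data.frame(y = 2 * x + offs + rnorm(600, 0, 0.1), x = x, g = g)
  fit <- fit_random_intercept_model(d, "y", "x", "g")
  sl <- fit$fixed$estimate[fit$fixed$term == "x"]
  expect_gt(sl, 1.9); expect_lt(sl, 2.1)
  expect_gt(fit$random_intercept_var_share, 50)  # strong concert offsets
  expect_lt(fit$fixed$p[fit$fixed$term == "x"], 1e-10)
  expect_true(fit$r2 >= 0 && fit$r2 <= 100)
})

test_that("with a single group the model reduces to ordinary least squares", {
  set.seed(44)
  d <- data.frame(y = rnorm(50), x1 = rnorm(50), x2 = rnorm(50),
                  g = "only")
  fit <- fit_random_intercept_model(d, "y", c("x1", "x2"), "g",
                                    center_predictors = TRUE)
  ols <- lm(y ~ I(x1 - mean(x1)) + I(x2 - mean(x2)), data = d)
  expect_equal(unname(fit$fixed$estimate), unname(coef(ols)),
               tolerance = 1e-6)
  expect_equal(fit$random_intercept_var_share, 0)
})

test_that("group-constant predictors with centering are flagged as degenerate", {
  set.seed(3)
  d <- data.frame(y = rnorm(40), x = rep(c(1, 2), each = 20),
                  g = rep(c("a", "b"), each = 20))
  # x is constant within each group: centering zeroes it out entirely
  expect_error(fit_random_intercept_model(d, "y", "x", "g",
                                          center_predictors = TRUE),
               "collinear|degenerate")
})

test_that("null predictors rarely reach significance", {
  set.seed(55)
  hits <- vapply(1:50, function(i) {
    g <- rep(c("c1", "c2", "c3", "c4"), each = 50)
    d <- data.frame(y = rnorm(200), x = rnorm(200), g = g)
    # singular fits are expected under a null outcome (variance ~ 0)
    fit <- suppressWarnings(fit_random_intercept_model(d, "y", "x", "g"))
    abs(fit$fixed$t[fit$fixed$term == "x"]) > 1.96
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("piece contrasts produce ordered rank strings", {
  set.seed(66)
  n <- 200
  base <- data.frame(
    concert_id = rep(sprintf("c%d", 1:5), length.out = 3 * n),
    scope = rep(c("Beethoven", "Dean", "Brahms"), each = n))
  shift <- c(Beethoven = 0, Dean = 1.0, Brahms = 0.5)
  base$ES_contribution <- rnorm(3 * n, shift[base$scope], 0.8)
  out <- piece_contrast_analysis(base)
  expect_equal(out$rank_string, "Dean > Brahms > Beethoven")
  expect_equal(nrow(out$contrasts), 3)
  # identical distributions: nothing significant, empty rank string
  base$ES_contribution <- rnorm(3 * n)
  out2 <- piece_contrast_analysis(base)
  expect_equal(out2$rank_string, "")
  # two pieces with a large shift: the single contrast is significant
  two <- base[base$scope != "Brahms", ]
  two$ES_contribution <- rnorm(nrow(two)) + 2 * (two$scope == "Dean")
  out3 <- piece_contrast_analysis(two)
  expect_equal(nrow(out3$contrasts), 1)
  expect_lt(out3$contrasts$p_holm, 0.001)
  expect_error(piece_contrast_analysis(base[base$scope == "Dean", ]),
               "2 pieces")
})
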