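#' Pre/post affect change effect size
#'
#' Group-level effect size `(mean(pre) - mean(post)) / SD(pre)` (positive
#' values indicate a decline) and per-participant change scores
#' `(pre_i - post_i) / SD(pre)` for use as predictors.
#'
#' @param pre,post numeric vectors of pre- and post-concert scale values
#'   (pairwise aligned; incomplete pairs are dropped).
#' @return list with `es` (group effect size) and `change` (per-participant
#'   standardized change scores, `NA` where a value was missing).
#' @export
affect_change_effect_size <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- !is.na(pre) & !is.na(post)
  if (sum(ok) < 2L) stop("need at least 2 complete pre/post pairs")
  sd_pre <- stats::sd(pre[ok])
  if (!is.finite(sd_pre) || sd_pre == 0) stop("SD of pre values is zero")
  change <- rep(NA_real_, length(pre))
  change[ok] <- (pre[ok] - post[ok]) / sd_pre
  list(es = (mean(pre[ok]) - mean(post[ok])) / sd_pre, change = change)
}

#' Paired pre/post t-tests per concert
#'
#' Two-sided paired t-tests of a scale before versus after the concert, per
#' concert and pooled over all concerts (refit on the pooled pairs).
#'
#' @param pre,post numeric vectors (aligned per participant).
#' @param concert factor/character of concert ids (same length); `NULL`
#'   treats all values as one group.
#' @return data frame with `concert` (including an `"all"` row when several
#'   concerts are present), `mean_pre`, `mean_post`, `t`, `p`, `es`, `n`,
#'   `degenerate` (`TRUE` when the difference variance is zero).
#' @export
prepost_ttest <- function(pre, post, concert = NULL) {
  if (is.null(concert)) concert <- rep("all", length(pre))
  concert <- as.character(concert)
  one <- function(pp, qq, label) {
    ok <- !is.na(pp) & !is.na(qq)
    pp <- pp[ok]; qq <- qq[ok]
    if (length(pp) < 3L) {
      return(data.frame(concert = label, mean_pre = mean(pp),
                        mean_post = mean(qq), t = NA_real_, p = NA_real_,
                        es = NA_real_, n = length(pp), degenerate = NA))
    }
    d <- pp - qq
    degen <- stats::sd(d) == 0
    if (degen) {
      warning("zero variance of pre-post differences in ", label)
      t_v <- if (mean(d) == 0) 0 else NA_real_
      p_v <- if (mean(d) == 0) 1 else NA_real_
    } else {
      tt <- stats::t.test(pp, qq, paired = TRUE)
      t_v <- unname(tt$statistic); p_v <- tt$p.value
    }
    es <- if (stats::sd(pp) > 0) (mean(pp) - mean(qq)) / stats::sd(pp) else NA_real_
    data.frame(concert = label, mean_pre = mean(pp), mean_post = mean(qq),
               t = t_v, p = p_v, es = es, n = length(pp), degenerate = degen)
  }
  labs <- unique(concert)
  rows <- lapply(labs, function(l) one(pre[concert == l], post[concert == l], l))
  if (length(labs) > 1L) rows <- c(rows, list(one(pre, post, "all")))
  do.call(rbind, rows)
}

#' Center values within groups
#'
#' Subtracts the group mean, disentangling within-group from between-group
#' variance; every output group has mean exactly zero.
#'
#' @param values numeric vector.
#' @param group group labels (same length).
#' @return centered numeric vector (`NA`s preserved).
#' @export
center_within_group <- function(values, group) {
  stopifnot(length(values) == length(group))
  grp <- as.character(group)
  for (g in unique(grp)) {
    if (all(is.na(values[grp == g]))) stop("group ", g, " has no non-missing value")
  }
  values - stats::ave(values, grp, FUN = function(v) mean(v, na.rm = TRUE))
}

#' Random-intercept mixed model for synchrony contributions
#'
#' Fits `outcome ~ predictors + (1 | group)` by restricted maximum
#' likelihood (lme4), the hierarchical-regression workhorse linking
#' synchrony contributions to psychological covariates with a random
#' intercept per concert. Predictors can be centered within the grouping
#' variable first (the default for affect, experience and piece
#' predictors; personality traits are conventionally left uncentered as
#' traits carry no between-concert variance of interest). With fewer than
#' two group levels the model reduces to ordinary least squares.
#'
#' p-values use the residual degrees of freedom `n - p`. The explained
#' variance r2 is the squared correlation between fitted and observed
#' values; the random-effect variance share is
#' `100 * var(intercept) / (var(intercept) + var(residual))`.
#'
#' @param data data frame holding all columns.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor columns.
#' @param group name of the grouping column (e.g. `"concert_id"`).
#' @param center_predictors logical: center predictors within group first.
#' @return object of class `mixed_model_result`: list with `outcome`,
#'   `fixed` (data frame `term`, `estimate`, `se`, `t`, `p`),
#'   `random_intercept_var_share`, `n`, `r2`, `singular`, and the fitted
#'   `model`.
#' @export
fit_random_intercept_model <- function(data, outcome, predictors, group,
                                       center_predictors = TRUE) {
  stopifnot(outcome %in% names(data), group %in% names(data),
            all(predictors %in% names(data)))
  d <- data[, c(outcome, predictors, group)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1L) stop("too few complete observations")
  if (center_predictors && length(predictors) > 0L) {
    for (p in predictors) {
      if (is.numeric(d[[p]])) d[[p]] <- center_within_group(d[[p]], d[[group]])
    }
  }
  # collinearity / degeneracy guard on the fixed-effects design
  if (length(predictors) > 0L) {
    X <- stats::model.matrix(
      stats::reformulate(predictors), data = d)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("collinear or degenerate predictors: ", paste(bad, collapse = ", "))
    }
  }
  rhs <- if (length(predictors) == 0L) "1" else paste(predictors, collapse = " + ")
  n_groups <- length(unique(d[[group]]))
  singular <- FALSE
  if (n_groups >= 2L) {
    fml <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 |", group, ")"))
    fit <- lme4::lmer(fml, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular =
                                                    lme4::.makeCC(action = "ignore", tol = 1e-4)))
    if (lme4::isSingular(fit)) {
      singular <- TRUE
      warning("singular fit: random-intercept variance estimated at zero")
    }
    vc <- as.data.frame(lme4::VarCorr(fit))
    v_int <- vc$vcov[vc$grp == group][1L]
    v_res <- vc$vcov[vc$grp == "Residual"][1L]
    coefs <- summary(fit)$coefficients  # Estimate, Std. Error, t value
    fitted_v <- stats::fitted(fit)
  } else {
    fml <- stats::as.formula(paste(outcome, "~", rhs))
    fit <- stats::lm(fml, data = d)
    v_int <- 0; v_res <- summary(fit)$sigma^2
    coefs <- summary(fit)$coefficients[, 1:3, drop = FALSE]
    fitted_v <- stats::fitted(fit)
  }
  df_resid <- n - nrow(coefs)
  fixed <- data.frame(term = rownames(coefs),
                      estimate = coefs[, 1L], se = coefs[, 2L],
                      t = coefs[, 3L],
                      p = 2 * stats::pt(-abs(coefs[, 3L]), df = df_resid),
                      row.names = NULL)
  r2 <- if (stats::sd(fitted_v) > 0) {
    100 * stats::cor(fitted_v, d[[outcome]])^2
  } else 0
  structure(list(outcome = outcome, fixed = fixed,
                 random_intercept_var_share =
                   100 * v_int / (v_int + v_res),
                 n = n, r2 = r2, singular = singular, model = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Mixed model for %s (n = %d)\n", x$outcome, x$n))
  print(transform(x$fixed, estimate = round(estimate, 3), se = round(se, 3),
                  t = round(t, 2), p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("Random intercept: %.1f%% of variance; model r2 = %.1f%%\n",
              x$random_intercept_var_share, x$r2))
  invisible(x)
}

#' Piece contrasts of per-participant values
#'
#' Mixed model with piece as a categorical predictor and a concert random
#' intercept; all pairwise piece contrasts with Holm correction. When
#' contrasts separate the pieces, an ordered rank string such as
#' `"Dean > Brahms > Beethoven"` is emitted (`"~"` joins pieces whose
#' adjacent contrast is not significant; the string is empty when nothing
#' is significant).
#'
#' @param data data frame with one row per participant x piece.
#' @param value name of the value column.
#' @param piece name of the piece column.
#' @param group name of the concert column.
#' @param alpha significance level for the rank string (default 0.05).
#' @return list with `contrasts` (data frame: `contrast`, `estimate`, `t`,
#'   `p_holm`), `means` (estimated marginal means per piece), and
#'   `rank_string`.
#' @export
piece_contrast_analysis <- function(data, value = "ES_contribution",
                                    piece = "scope", group = "concert_id",
                                    alpha = 0.05) {
  d <- data[, c(value, piece, group)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d[[piece]] <- factor(d[[piece]])
  if (nlevels(d[[piece]]) < 2L) stop("need at least 2 pieces")
  fml <- stats::as.formula(paste(value, "~", piece, "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC(action = "ignore", tol = 1e-4)))
  emm <- emmeans::emmeans(fit, piece, lmer.df = "asymptotic")
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "holm"))
  means <- as.data.frame(emm)
  contrasts <- data.frame(contrast = as.character(prs$contrast),
                          estimate = prs$estimate,
                          t = prs$z.ratio %||% prs$t.ratio,
                          p_holm = prs$p.value)
  ord <- order(means$emmean, decreasing = TRUE)
  lv <- as.character(means[[piece]])[ord]
  sig <- function(a, b) {
    lab1 <- paste(a, "-", b); lab2 <- paste(b, "-", a)
    row <- contrasts$contrast %in% c(lab1, lab2)
    any(row) && all(contrasts$p_holm[row] < alpha)
  }
  seps <- vapply(seq_len(length(lv) - 1L),
                 function(i) sig(lv[i], lv[i + 1L]), logical(1))
  rank_string <- if (!any(vapply(seq_along(lv), function(i)
    any(vapply(seq_along(lv)[-i], function(j) sig(lv[i], lv[j]), logical(1))),
    logical(1)))) "" else {
      paste0(lv[1L], paste0(ifelse(seps, " > ", " ~ "), lv[-1L], collapse = ""))
    }
  list(contrasts = contrasts, means = means, rank_string = rank_string,
       model = fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
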