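#' All dyadic synchronies within an audience
#'
#' Computes the SUSY statistic for every unordered pair of participants
#' (N participants give N(N-1)/2 dyads). Per-participant segment
#' preparations are computed once and reused across pairs, so the all-pairs
#' computation scales to full audiences.
#'
#' @param audience list of [channel_series()] (one per participant, same
#'   channel, same grid), named or carrying `participant_id`s.
#' @param params a [susy_params()].
#' @param scope label for the analysis window (`"concert"` or a piece name).
#' @return a data frame of class `dyad_table` with one row per dyad
#'   (columns `id1`, `id2`, `channel`, `scope`, `Z`, `Zsurr_mean`,
#'   `Zsurr_sd`, `ES`, `n_segments`, `n_surrogates_used`) and an attribute
#'   `"Zsurr"`: the dyad-by-surrogate matrix of surrogate Z values used for
#'   participant-level aggregation.
#' @export
all_dyads <- function(audience, params = susy_params(), scope = "concert") {
  if (length(audience) < 2L) stop("an audience needs at least 2 participants")
  ids <- vapply(audience, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  ord <- order(ids)
  audience <- audience[ord]; ids <- ids[ord]
  preps <- lapply(audience, .susy_prep, params = params)
  n <- length(preps)
  rows <- vector("list", n * (n - 1L) / 2L)
  surr <- vector("list", length(rows))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      px <- preps[[i]]; py <- preps[[j]]
      G <- .lagmean_z(.corr_tensor(px, py, params))
      use <- px$usable & py$usable
      seg_z <- diag(G)[use]
      seg_z <- seg_z[!is.na(seg_z)]
      if (length(seg_z) == 0L) {
        rows[[k]] <- data.frame(id1 = ids[i], id2 = ids[j],
                                channel = px$channel, scope = scope,
                                Z = NA_real_, Zsurr_mean = NA_real_,
                                Zsurr_sd = NA_real_, ES = NA_real_,
                                n_segments = 0L, n_surrogates_used = 0L)
        surr[[k]] <- numeric(0)
        next
      }
      Z <- mean(seg_z)
      seed <- .dyad_stream_seed(px, py, params, scope)
      zs <- .surrogates_from_G(G, use, params, seed)
      zs <- zs[!is.na(zs)]
      zs_sd <- stats::sd(zs)
      es <- if (length(zs) >= 2L && is.finite(zs_sd) && zs_sd > 0) {
        (Z - mean(zs)) / zs_sd
      } else NA_real_
      rows[[k]] <- data.frame(id1 = ids[i], id2 = ids[j],
                              channel = px$channel, scope = scope,
                              Z = Z, Zsurr_mean = mean(zs), Zsurr_sd = zs_sd,
                              ES = es, n_segments = length(seg_z),
                              n_surrogates_used = length(zs))
      surr[[k]] <- zs
    }
  }
  out <- do.call(rbind, rows)
  smax <- max(lengths(surr), 1L)
  smat <- matrix(NA_real_, nrow = length(surr), ncol = smax)
  for (r in seq_along(surr)) {
    if (length(surr[[r]]) > 0L) smat[r, seq_along(surr[[r]])] <- surr[[r]]
  }
  attr(out, "Zsurr") <- smat
  class(out) <- c("dyad_table", class(out))
  out
}

#' Audience synchrony
#'
#' The mean of all dyadic synchrony Z values within the audience.
#'
#' @param dyads a `dyad_table` from [all_dyads()] (or any data frame with a
#'   `Z` column).
#' @return the mean dyadic Z.
#' @export
audience_synchrony <- function(dyads) {
  z <- dyads$Z
  z <- z[!is.na(z)]
  if (length(z) == 0L) stop("no dyads with defined Z")
  mean(z)
}

#' Per-participant synchrony contributions
#'
#' A participant's synchrony contribution is the mean of the dyadic Z values
#' of all pairs that participant enters (N-1 dyads in an audience of N).
#' The participant-level surrogate distribution is built by averaging, for
#' each surrogate index s, the s-th surrogate Z over the participant's
#' dyads; this preserves the between-surrogate variance needed for the
#' contribution-level effect size
#' `ES = (Z_contribution - mean(surr)) / sd(surr)`.
#'
#' @param dyads a `dyad_table` from [all_dyads()].
#' @return data frame with one row per participant: `participant_id`,
#'   `channel`, `scope`, `Z_contribution`, `Zsurr_contribution_mean`,
#'   `Zsurr_contribution_sd`, `ES_contribution`, `n_partners`.
#' @export
contributions <- function(dyads) {
  smat <- attr(dyads, "Zsurr")
  if (is.null(smat)) stop("dyads must carry the surrogate matrix (use all_dyads)")
  ids <- sort(unique(c(dyads$id1, dyads$id2)))
  rows <- lapply(ids, function(id) {
    sel <- which((dyads$id1 == id | dyads$id2 == id) & !is.na(dyads$Z))
    if (length(sel) == 0L) {
      message("participant ", id, " has no defined dyads; contribution missing")
      return(data.frame(participant_id = id, channel = dyads$channel[1L],
                        scope = dyads$scope[1L], Z_contribution = NA_real_,
                        Zsurr_contribution_mean = NA_real_,
                        Zsurr_contribution_sd = NA_real_,
                        ES_contribution = NA_real_, n_partners = 0L))
    }
    zc <- mean(dyads$Z[sel])
    surr_c <- colMeans(smat[sel, , drop = FALSE], na.rm = TRUE)
    surr_c <- surr_c[is.finite(surr_c)]
    sd_c <- stats::sd(surr_c)
    es <- if (length(surr_c) >= 2L && is.finite(sd_c) && sd_c > 0) {
      (zc - mean(surr_c)) / sd_c
    } else NA_real_
    data.frame(participant_id = id, channel = dyads$channel[1L],
               scope = dyads$scope[1L], Z_contribution = zc,
               Zsurr_contribution_mean = mean(surr_c),
               Zsurr_contribution_sd = sd_c,
               ES_contribution = es, n_partners = length(sel))
  })
  do.call(rbind, rows)
}

#' Slice a concert recording into pieces
#'
#' Restricts each participant's series to every piece interval of the
#' concert metadata; each piece is then re-segmented and analysed
#' independently. Pieces too short for at least two segments are skipped
#' with a warning.
#'
#' @param audience list of [channel_series()] covering one concert.
#' @param concert_meta data frame with columns `piece`, `start_s`, `end_s`
#'   (optionally `concert_id`).
#' @param params optional [susy_params()]; if supplied, pieces shorter than
#'   two segments are dropped.
#' @return named list (by piece) of lists of windowed series.
#' @export
slice_by_piece <- function(audience, concert_meta, params = NULL) {
  stopifnot(all(c("piece", "start_s", "end_s") %in% names(concert_meta)))
  s1 <- audience[[1L]]
  t_end <- s1$t0_s + length(s1$values) / s1$rate_hz
  out <- list()
  for (r in seq_len(nrow(concert_meta))) {
    piece <- as.character(concert_meta$piece[r])
    a <- concert_meta$start_s[r]; b <- concert_meta$end_s[r]
    if (a < s1$t0_s - 1e-9 || b > t_end + 1e-9 || b <= a) {
      stop("piece boundaries outside the recording: ", piece)
    }
    if (!is.null(params) && (b - a) < 2 * params$segment_length_s) {
      warning("piece ", piece, " shorter than 2 segments; skipped")
      next
    }
    out[[piece]] <- lapply(audience, window_series, start_s = a, end_s = b)
  }
  out
}

#' Group-level presence-of-synchrony test
#'
#' Paired t-test of participants' observed synchrony contributions against
#' their surrogate contributions, under the null hypothesis that both
#' distributions share the same mean. A significant positive t indicates
#' that synchrony is present in the audience.
#'
#' @param contribs data frame from [contributions()] (possibly pooled over
#'   concerts for one channel and scope).
#' @return data frame with `channel`, `scope`, `mean_Z`, `mean_Zsurr`,
#'   `t_statistic`, `p_value`, `mean_ES`, `n`.
#' @export
presence_test <- function(contribs) {
  ok <- stats::complete.cases(contribs[, c("Z_contribution",
                                           "Zsurr_contribution_mean")])
  d <- contribs[ok, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 participants with paired values")
  diffs <- d$Z_contribution - d$Zsurr_contribution_mean
  if (all(abs(diffs) < .Machine$double.eps^0.5) || stats::sd(diffs) == 0) {
    warning("all Z - Zsurr differences are zero; t reported as 0")
    tt <- list(statistic = 0, p.value = 1)
  } else {
    tt <- stats::t.test(d$Z_contribution, d$Zsurr_contribution_mean,
                        paired = TRUE)
  }
  data.frame(channel = d$channel[1L], scope = d$scope[1L],
             mean_Z = mean(d$Z_contribution),
             mean_Zsurr = mean(d$Zsurr_contribution_mean),
             t_statistic = unname(tt$statistic),
             p_value = unname(tt$p.value),
             mean_ES = mean(d$ES_contribution, na.rm = TRUE),
             n = nrow(d))
}

#' Composite synchrony contribution across channels
#'
#' "All synchronies taken together": per participant, the mean of
#' within-concert, within-channel z-standardized contribution effect sizes
#' over the physiological channels (RESP always excluded). Participants
#' missing a channel contribute the mean of their remaining channels.
#'
#' @param contrib_df long data frame of contributions across channels with
#'   columns `concert_id`, `participant_id`, `channel`, `scope`,
#'   `ES_contribution`.
#' @param channels channels entering the composite (default HR, HRV, SCR,
#'   RR).
#' @return data frame with one row per participant and `channel = "ALL"`:
#'   `concert_id`, `participant_id`, `channel`, `scope`,
#'   `ES_contribution` (the composite), `n_channels`.
#' @export
composite_contribution <- function(contrib_df,
                                   channels = c("HR", "HRV", "SCR", "RR")) {
  d <- contrib_df[contrib_df$channel %in% channels &
                    !is.na(contrib_df$ES_contribution), , drop = FALSE]
  if (nrow(d) == 0L) stop("no contributions for the requested channels")
  grp <- interaction(d$concert_id, d$channel, d$scope, drop = TRUE)
  mu <- stats::ave(d$ES_contribution, grp, FUN = mean)
  sdv <- stats::ave(d$ES_contribution, grp,
                    FUN = function(v) if (length(v) > 1L) stats::sd(v) else NA_real_)
  z <- (d$ES_contribution - mu) / sdv
  z[!is.finite(z)] <- NA_real_
  agg <- stats::aggregate(
    z, by = list(concert_id = d$concert_id, participant_id = d$participant_id,
                 scope = d$scope),
    FUN = function(v) mean(v, na.rm = TRUE))
  cnt <- stats::aggregate(
    !is.na(z), by = list(concert_id = d$concert_id,
                         participant_id = d$participant_id, scope = d$scope),
    FUN = sum)
  out <- data.frame(concert_id = agg$concert_id,
                    participant_id = agg$participant_id,
                    channel = "ALL", scope = agg$scope,
                    ES_contribution = ifelse(is.nan(agg$x), NA_real_, agg$x),
                    n_channels = cnt$x)
  out
}
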