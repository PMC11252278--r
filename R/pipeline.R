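# File-based pipeline: dataset IO, synchrony stage, analysis stage, report.
# CSV is the canonical interchange (UTF-8, header row, NA for missing).

#' Write a simulated dataset to disk
#'
#' Emits `timeseries.csv` (long format), `survey.csv`, `concert_meta.csv`
#' and `ground_truth.json` into a directory.
#'
#' @param dataset a `concert_dataset` from [simulate_concerts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "concert_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$timeseries, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$survey, file.path(dir, "survey.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$concert_meta, file.path(dir, "concert_meta.csv"),
                   row.names = FALSE)
  gt <- lapply(dataset$ground_truth, function(g) {
    list(concert_id = g$concert_id, participant_id = g$participant_id,
         kappa = as.data.frame(g$kappa), lag_s = g$lag_s,
         covariate_effects = as.list(g$covariate_effects))
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory
#'
#' Reads the files written by [write_dataset()] (or user-supplied files in
#' the same layout) and rebuilds the nested [channel_series()] structure.
#'
#' @param dir dataset directory.
#' @return a `concert_dataset`-like list with `timeseries`, `survey`,
#'   `concert_meta` and `series` (concert -> participant -> channel).
#' @export
read_dataset <- function(dir) {
  ts_path <- file.path(dir, "timeseries.csv")
  if (!file.exists(ts_path)) stop("missing timeseries.csv in ", dir)
  ts <- utils::read.csv(ts_path, stringsAsFactors = FALSE)
  need <- c("concert_id", "participant_id", "channel", "time_s", "value")
  if (!all(need %in% names(ts))) {
    stop("timeseries.csv must have columns: ", paste(need, collapse = ", "))
  }
  survey <- NULL
  if (file.exists(file.path(dir, "survey.csv"))) {
    survey <- utils::read.csv(file.path(dir, "survey.csv"),
                              stringsAsFactors = FALSE)
  }
  meta <- NULL
  if (file.exists(file.path(dir, "concert_meta.csv"))) {
    meta <- utils::read.csv(file.path(dir, "concert_meta.csv"),
                            stringsAsFactors = FALSE)
  }
  series <- series_from_long(ts)
  structure(list(timeseries = ts, survey = survey, concert_meta = meta,
                 series = series),
            class = "concert_dataset")
}

#' Build nested channel series from a long table
#'
#' @param ts long data frame (`concert_id`, `participant_id`, `channel`,
#'   `time_s`, `value`); each participant/channel must lie on a uniform
#'   grid.
#' @return nested list concert -> participant -> channel of
#'   [channel_series()].
#' @export
series_from_long <- function(ts) {
  out <- list()
  for (cid in unique(ts$concert_id)) {
    tc <- ts[ts$concert_id == cid, ]
    out[[as.character(cid)]] <- list()
    for (pid in unique(tc$participant_id)) {
      tp <- tc[tc$participant_id == pid, ]
      chans <- list()
      for (ch in unique(tp$channel)) {
        tv <- tp[tp$channel == ch, ]
        tv <- tv[order(tv$time_s), ]
        dt <- diff(tv$time_s)
        if (length(dt) > 0 && (max(dt) - min(dt)) > 1e-6) {
          stop("non-uniform grid for ", pid, "/", ch)
        }
        rate <- if (length(dt) > 0) 1 / stats::median(dt) else 1
        chans[[ch]] <- channel_series(tv$value, ch, rate, t0_s = tv$time_s[1L],
                                      concert_id = as.character(cid),
                                      participant_id = as.character(pid))
      }
      out[[as.character(cid)]][[as.character(pid)]] <- chans
    }
  }
  out
}

#' Run the synchrony stage over a dataset
#'
#' For every concert, channel and scope (whole concert plus each piece),
#' computes all dyadic synchronies, per-participant contributions, and the
#' group-level presence test; pools the presence test across concerts per
#' channel x scope, mirroring the per-channel, per-piece layout of the
#' presence analysis.
#'
#' @param dataset a `concert_dataset` (from [simulate_concerts()] or
#'   [read_dataset()]).
#' @param params a [susy_params()].
#' @param channels channels to analyse (default the five feature channels
#'   present).
#' @param scopes `"concert"`, piece labels, or both (default: concert and
#'   all pieces in the metadata).
#' @param out_dir optional directory to write `dyads.csv`,
#'   `contributions.csv`, `presence_tests.csv`.
#' @param verbose log per-stage progress to stderr.
#' @return list with `dyads`, `contributions` (both long data frames over
#'   concerts/channels/scopes) and `presence` (pooled tests per channel x
#'   scope).
#' @export
run_synchrony <- function(dataset, params = susy_params(), channels = NULL,
                          scopes = NULL, out_dir = NULL, verbose = FALSE) {
  series <- dataset$series
  meta <- dataset$concert_meta
  all_channels <- unique(unlist(lapply(series, function(cc)
    unlist(lapply(cc, names)))))
  if (is.null(channels)) channels <- intersect(
    c("HR", "HRV", "SCR", "RR", "RESP"), all_channels)
  pieces <- if (!is.null(meta)) unique(as.character(meta$piece)) else character(0)
  if (is.null(scopes)) scopes <- c("concert", pieces)
  dy_all <- list(); co_all <- list()
  for (cid in names(series)) {
    parts <- series[[cid]]
    for (ch in channels) {
      have <- vapply(parts, function(p) ch %in% names(p), logical(1))
      if (sum(have) < 2L) {
        warning("channel ", ch, " missing for concert ", cid, "; skipped")
        next
      }
      aud <- lapply(parts[have], `[[`, ch)
      for (sc in scopes) {
        t_start <- Sys.time()
        aud_sc <- if (sc == "concert") aud else {
          mrow <- meta[meta$concert_id == cid & meta$piece == sc, ]
          if (nrow(mrow) == 0L) next
          sl <- slice_by_piece(aud, mrow, params)
          if (length(sl) == 0L) next
          sl[[sc]]
        }
        dy <- all_dyads(aud_sc, params, scope = sc)
        co <- contributions(dy)
        dy$concert_id <- cid
        co <- cbind(concert_id = cid, co)
        dy_all[[length(dy_all) + 1L]] <- dy
        co_all[[length(co_all) + 1L]] <- co
        if (verbose) {
          message(sprintf("[synchrony] %s %s/%s: %d dyads (%.2fs)",
                          cid, ch, sc, nrow(dy),
                          as.numeric(Sys.time() - t_start, units = "secs")))
        }
      }
    }
  }
  if (length(dy_all) == 0L) stop("no channel/scope could be analysed")
  surr_mats <- lapply(dy_all, attr, "Zsurr")
  dyads <- do.call(rbind, lapply(dy_all, function(d) {
    attr(d, "Zsurr") <- NULL; class(d) <- "data.frame"; d
  }))
  contribs <- do.call(rbind, co_all)
  pres <- list()
  for (ch in unique(contribs$channel)) {
    for (sc in unique(contribs$scope)) {
      cc <- contribs[contribs$channel == ch & contribs$scope == sc, ]
      if (sum(stats::complete.cases(
        cc[, c("Z_contribution", "Zsurr_contribution_mean")])) >= 3L) {
        pres[[length(pres) + 1L]] <- presence_test(cc)
      }
    }
  }
  presence <- do.call(rbind, pres)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dyads, file.path(out_dir, "dyads.csv"), row.names = FALSE)
    utils::write.csv(contribs, file.path(out_dir, "contributions.csv"),
                     row.names = FALSE)
    utils::write.csv(presence, file.path(out_dir, "presence_tests.csv"),
                     row.names = FALSE)
  }
  list(dyads = dyads, contributions = contribs, presence = presence,
       surrogate_matrices = surr_mats)
}

#' Run the regression stage
#'
#' Joins contributions with the survey, builds the predictor blocks
#' (affect change, personality, experience factors, per-piece items) and
#' fits one random-intercept model per outcome channel x block. Affect,
#' experience and piece predictors are centered within concert; personality
#' predictors are not.
#'
#' @param contribs contributions data frame from [run_synchrony()].
#' @param survey survey data frame.
#' @param blocks subset of `c("affect", "personality", "experience",
#'   "piece")`.
#' @param channels outcome channels (default HR, HRV, SCR, RR and the ALL
#'   composite).
#' @param two_pass if `TRUE`, refit each model keeping only the predictors
#'   significant in a first pass (multicollinearity guard for the piece
#'   block).
#' @param out_dir optional directory for `models.csv`.
#' @return list of `mixed_model_result` objects (named
#'   `<channel>.<scope>.<block>`) plus a tidy `models` data frame.
#' @export
run_analysis <- function(contribs, survey,
                         blocks = c("affect", "personality", "experience"),
                         channels = c("HR", "HRV", "SCR", "RR", "ALL"),
                         two_pass = FALSE, out_dir = NULL) {
  comp <- composite_contribution(contribs[contribs$scope == "concert", ])
  base <- contribs[, c("concert_id", "participant_id", "channel", "scope",
                       "ES_contribution")]
  base <- rbind(base, comp[, names(base)])
  orphans <- setdiff(unique(base$participant_id), survey$participant_id)
  if (length(orphans) > 0L) {
    stop("participants without survey rows: ",
         paste(utils::head(orphans, 5), collapse = ", "))
  }
  # affect change scores standardized by each scale's pre-concert SD
  for (sc in c("PA", "NA", "VA")) {
    pre <- survey[[paste0(sc, "_pre")]]; post <- survey[[paste0(sc, "_post")]]
    if (!is.null(pre) && !is.null(post)) {
      survey[[paste0(sc, "_change")]] <- affect_change_effect_size(pre, post)$change
    }
  }
  block_cols <- list(
    affect = c("PA_change", "NA_change", "VA_change"),
    personality = c("Extraversion", "Agreeableness", "Conscientiousness",
                    "Neuroticism", "Openness"),
    experience = paste0("F", 1:7))
  centered <- c(affect = TRUE, personality = FALSE, experience = TRUE,
                piece = TRUE)
  fits <- list(); rows <- list()
  fit_one <- function(d, preds, center, label) {
    preds <- intersect(preds, names(d))
    preds <- preds[vapply(preds, function(p) !all(is.na(d[[p]])), logical(1))]
    if (length(preds) == 0L) return(NULL)
    fit <- tryCatch(
      fit_random_intercept_model(d, "ES_contribution", preds,
                                 "concert_id", center_predictors = center),
      error = function(e) {
        warning("model ", label, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) return(NULL)
    if (two_pass) {
      keep <- fit$fixed$term[fit$fixed$term != "(Intercept)" & fit$fixed$p < 0.05]
      keep <- intersect(keep, preds)
      if (length(keep) > 0L && length(keep) < length(preds)) {
        fit <- fit_random_intercept_model(d, "ES_contribution", keep,
                                          "concert_id",
                                          center_predictors = center)
      }
    }
    fits[[label]] <<- fit
    rows[[label]] <<- cbind(model = label, fit$fixed,
                            var_share = fit$random_intercept_var_share,
                            n = fit$n, r2 = fit$r2)
    fit
  }
  for (blk in blocks) {
    if (blk == "piece") next
    for (ch in channels) {
      d <- base[base$channel == ch & base$scope == "concert", ]
      d <- merge(d, survey, by = c("concert_id", "participant_id"))
      if (nrow(d) == 0L) next
      fit_one(d, block_cols[[blk]], centered[[blk]],
              paste(ch, "concert", blk, sep = "."))
    }
  }
  if ("piece" %in% blocks) {
    items <- c("liked", "knew", "annoyed", "moved", "interesting",
               "inspired", "melancholic", "happy", "bored")
    pieces <- setdiff(unique(base$scope), "concert")
    for (p in pieces) {
      cols <- paste0(items, "_", p)
      for (ch in setdiff(channels, "ALL")) {
        d <- base[base$channel == ch & base$scope == p, ]
        d <- merge(d, survey, by = c("concert_id", "participant_id"))
        if (nrow(d) == 0L) next
        have <- intersect(cols, names(d))
        fit_one(d, have, TRUE, paste(ch, p, "piece", sep = "."))
      }
    }
  }
  models <- if (length(rows) > 0L) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL
  if (!is.null(out_dir) && !is.null(models)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(models, file.path(out_dir, "models.csv"),
                     row.names = FALSE)
  }
  list(fits = fits, models = models)
}

#' Render a markdown analysis report
#'
#' Assembles presence tests, affect pre/post statistics and regression
#' tables into a markdown report; if ground truth is available, appends a
#' recovered-sign summary comparing fitted covariate effects with the
#' planted ones.
#'
#' @param synchrony result of [run_synchrony()].
#' @param analysis result of [run_analysis()] (optional).
#' @param survey survey data frame (optional, for the affect table).
#' @param ground_truth list of per-concert ground truth (optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
render_report <- function(synchrony, analysis = NULL, survey = NULL,
                          ground_truth = NULL, path = "report.md") {
  lines <- c("# Audience synchrony report", "")
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1L, function(r) paste("|", paste(r, collapse = " | "), "|")))
  }
  lines <- c(lines, "## Presence of synchrony (Z vs surrogate Z)", "",
             fmt(synchrony$presence), "")
  if (!is.null(survey) && all(c("NA_pre", "NA_post") %in% names(survey))) {
    aff <- do.call(rbind, lapply(c("PA", "NA", "VA"), function(sc) {
      tt <- prepost_ttest(survey[[paste0(sc, "_pre")]],
                          survey[[paste0(sc, "_post")]],
                          survey$concert_id)
      cbind(scale = sc, tt)
    }))
    lines <- c(lines, "## Affect change (pre vs post)", "", fmt(aff), "")
  }
  if (!is.null(analysis) && !is.null(analysis$models)) {
    lines <- c(lines, "## Hierarchical regressions", "", fmt(analysis$models), "")
  }
  if (!is.null(ground_truth) && !is.null(analysis)) {
    eff <- ground_truth[[1L]]$covariate_effects
    if (length(eff) > 0L) {
      rec <- list()
      for (lab in names(analysis$fits)) {
        fx <- analysis$fits[[lab]]$fixed
        for (nm in names(eff)) {
          row <- fx[fx$term == nm, ]
          if (nrow(row) == 1L) {
            rec[[length(rec) + 1L]] <- data.frame(
              model = lab, covariate = nm, planted_sign = sign(eff[[nm]]),
              estimated = row$estimate, p = row$p,
              sign_recovered = sign(row$estimate) == sign(eff[[nm]]))
          }
        }
      }
      if (length(rec) > 0L) {
        lines <- c(lines, "## Planted-effect sign recovery", "",
                   fmt(do.call(rbind, rec)), "")
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `simulation:` (fields of [simulation_config()]) and
#' `susy:` (fields of [susy_params()]); unknown keys are rejected.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the configured one.
#' @return list with `simulation` and `susy` objects.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), c("simulation", "susy"))
  if (length(unknown) > 0L) stop("unknown config keys: ",
                                 paste(unknown, collapse = ", "))
  sim_args <- cfg$simulation %||% list()
  if (!is.null(sim_args$piece_boundaries_s)) {
    sim_args$piece_boundaries_s <- as.data.frame(
      do.call(rbind, lapply(sim_args$piece_boundaries_s, as.data.frame)))
  }
  if (!is.null(seed)) sim_args$seed <- seed
  susy_args <- cfg$susy %||% list()
  if (!is.null(seed)) susy_args$rng_seed <- seed
  list(simulation = do.call(simulation_config, sim_args),
       susy = do.call(susy_params, susy_args))
}
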