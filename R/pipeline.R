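#' Run the full matched-pairs analysis on an in-memory cohort
#'
#' Orchestrates feature extraction, bout eligibility, control-window
#' enumeration, variable selection, within-subject kNN matching, outcome
#' construction and the mixed models for every participant of a cohort, and
#' returns all intermediate products. This is the engine behind
#' [run_pipeline()]; it performs no file I/O.
#'
#' @param cohort a `glyco_cohort` from [generate_cohort()], or any list with
#'   compatible `profiles`, `cgm`, `doses`, `bouts` (and optionally `carbs`)
#'   data frames.
#' @param params a [window_params()].
#' @param fit_models fit the mixed models (set `FALSE` to stop after
#'   matching).
#' @param test_poly passed to [fit_primary_model()].
#' @return list with `windows` (all PA windows with eligibility), `weights`,
#'   `pairs`, `dropped`, `balance`, `outcomes`, `primary_model`,
#'   `hypo_model`, `sensitivity` and the stage `counts` (candidate bouts →
#'   eligible → matched → analysed).
#' @export
analyze_cohort <- function(cohort, params = window_params(),
                           fit_models = TRUE, test_poly = TRUE) {
  prof <- cohort$profiles
  pids <- prof$participant_id
  cgm_split <- split(seq_len(nrow(cohort$cgm)), cohort$cgm$participant_id)
  dose_split <- split(seq_len(nrow(cohort$doses)),
                      cohort$doses$participant_id)
  bout_split <- split(seq_len(nrow(cohort$bouts)),
                      cohort$bouts$participant_id)

  traces <- lapply(cgm_split, function(ix) {
    data.frame(time = .time_min(cohort$cgm$time[ix]),
               glucose = cohort$cgm$glucose[ix])
  })
  cov_cols <- c("time_min", "start_glucose", "roc", "cv_pre", "iob",
                "clock_time")

  windows <- list(); cand_list <- list(); pool <- list()
  for (pid in pids) {
    bix <- bout_split[[pid]]
    if (is.null(bix)) next
    bouts_p <- cohort$bouts[bix, , drop = FALSE]
    trace <- traces[[pid]]
    dix <- dose_split[[pid]] %||% integer(0)
    doses_p <- data.frame(time = .time_min(cohort$doses$time[dix]),
                          units = cohort$doses$units[dix],
                          kind = cohort$doses$kind[dix])
    weight <- prof$weight[prof$participant_id == pid]

    ew <- eligible_bouts(bouts_p, trace, doses_p, weight, params)
    ew$participant_id <- pid
    ew$window_id <- sprintf("%s_b%03d", pid, seq_len(nrow(ew)))
    windows[[pid]] <- ew

    elig <- ew[ew$eligible, , drop = FALSE]
    if (nrow(elig) == 0L) next
    track <- .covariate_track(trace, doses_p, weight,
                              interval = params$interval)
    base_excl <- .merge_intervals(
      .exclusion_intervals(bouts_p, track$time_min, params))
    pool_idx <- integer(0)
    for (b in seq_len(nrow(elig))) {
      # the guard band around the matched bout is inside its own exclusion
      # zone, so the merged base intervals already cover it
      idx <- .admissible_starts(track, elig$duration[b], base_excl, params,
                                merged = TRUE)
      cc <- list2DF(lapply(cov_cols, function(cn) track[[cn]][idx]))
      names(cc) <- cov_cols
      cc$duration <- rep(elig$duration[b], length(idx))
      cand_list[[elig$window_id[b]]] <- cc
      pool_idx <- union(pool_idx, idx)
    }
    if (length(pool_idx) > 0L) {
      pool[[pid]] <- as.matrix(track[pool_idx, cov_cols])
    }
  }
  windows <- do.call(rbind, windows)
  rownames(windows) <- NULL
  pool <- do.call(rbind, pool)
  if (!is.null(pool)) {
    pm <- pool
    pool <- list2DF(lapply(seq_len(ncol(pm)), function(j) pm[, j]))
    names(pool) <- colnames(pm)
  }
  eligible <- windows[windows$eligible, , drop = FALSE]
  counts <- c(candidate_bouts = nrow(windows), eligible = nrow(eligible))

  if (nrow(eligible) == 0L) stop("no eligible PA bouts in the cohort")
  if (is.null(pool) || nrow(pool) == 0L) {
    stop("no admissible control candidates in the cohort")
  }
  pool$duration <- stats::median(eligible$duration)

  # PA-window outcomes for variable selection
  pa_out <- numeric(nrow(eligible))
  for (i in seq_len(nrow(eligible))) {
    pa_out[i] <- glucose_change(traces[[eligible$participant_id[i]]],
                                list(onset = eligible$onset_min[i],
                                     duration = eligible$duration[i]),
                                tail = params$tail, tol = params$snap_tol)
  }

  weights <- select_weights(eligible, pa_out, pool)
  match_res <- knn_match(eligible, cand_list, weights, guard = params$guard)
  pairs <- match_res$pairs
  counts["matched"] <- nrow(pairs)

  control_cov <- NULL; balance <- NULL; outcomes <- data.frame()
  primary <- NULL; hypo <- NULL; sens <- NULL
  if (nrow(pairs) > 0L) {
    control_cov <- as.data.frame(t(vapply(seq_len(nrow(pairs)), function(i) {
      cc <- cand_list[[pairs$window_id[i]]]
      j <- match(pairs$control_onset_min[i], cc$time_min)
      c(as.numeric(cc[j, cov_cols]), duration = pairs$duration[i])
    }, numeric(length(cov_cols) + 1L))))
    names(control_cov) <- c(cov_cols, "duration")
    balance <- balance_report(match_res, eligible, pool, control_cov)
    outcomes <- build_outcomes(pairs, eligible, control_cov,
                               cohort, tail = params$tail)
    counts["analysed"] <- length(unique(
      outcomes$pair_id[!is.na(outcomes$delta_glucose)]))
    if (fit_models) {
      primary <- fit_primary_model(outcomes, test_poly = test_poly)
      hypo <- fit_hypo_model(outcomes)
      sens <- sensitivity_analysis(outcomes, test_poly = FALSE)
    }
  }

  list(windows = windows, eligible = eligible, weights = weights,
       pairs = pairs, dropped = match_res$dropped, balance = balance,
       control_covariates = control_cov, outcomes = outcomes,
       primary_model = primary, hypo_model = hypo, sensitivity = sens,
       counts = counts)
}

#' Run one replicate of the calibrated study and summarize it
#'
#' Generates a synthetic cohort under `config` with the given seed, runs the
#' full analysis pipeline, and returns the headline quantities: the condition
#' fixed effect, the moderator table, raw matched means, the hypoglycaemia
#' incidence among matched PA windows, post-matching balance, pooled
#' glycaemic descriptives and stage counts. Large intermediates are
#' discarded, so replicate loops stay memory-light.
#'
#' @param seed RNG seed for the replicate.
#' @param config a [sim_config()].
#' @param params a [window_params()].
#' @return a named list of summary quantities.
#' @export
study_summary <- function(seed, config = sim_config(),
                          params = window_params()) {
  cohort <- generate_cohort(config, seed = seed)
  res <- analyze_cohort(cohort, params = params)
  pa <- res$outcomes[res$outcomes$condition == "PA", ]
  ct <- res$outcomes[res$outcomes$condition == "control", ]
  gm <- glycaemic_metrics(cohort$cgm)
  list(
    seed = seed,
    counts = res$counts,
    condition = condition_effect(res$primary_model),
    moderators = res$primary_model$moderators,
    mean_pa = mean(pa$delta_glucose, na.rm = TRUE),
    mean_control = mean(ct$delta_glucose, na.rm = TRUE),
    hypo_events = sum(pa$hypo, na.rm = TRUE),
    hypo_n = sum(!is.na(pa$hypo)),
    hypo_events_control = sum(ct$hypo, na.rm = TRUE),
    max_smd = max(abs(res$balance$smd$after)),
    cv_pooled = gm$cv, mean_glucose = gm$mean,
    median_matched_duration = stats::median(res$pairs$duration),
    n_pairs = nrow(res$pairs),
    sensitivity_estimate = if (!is.null(res$sensitivity$model)) {
      condition_effect(res$sensitivity$model)$estimate
    } else NA_real_,
    hypo_method = res$hypo_model$method
  )
}

#' Write a synthetic cohort to the standard CSV layout
#'
#' Emits `cgm.csv`, `doses.csv`, `bouts.csv`, `participants.csv`,
#' `carbs.csv` and `truth.csv` (ISO-8601 timestamps, UTF-8, header row) plus
#' the generating configuration as `sim_config.yaml`.
#'
#' @param cohort a `glyco_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) {
    for (cn in names(df)) {
      if (inherits(df[[cn]], "POSIXt")) {
        df[[cn]] <- format(df[[cn]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      }
    }
    utils::write.csv(df, file.path(dir, nm), row.names = FALSE)
  }
  wr(cohort$cgm, "cgm.csv")
  wr(cohort$doses, "doses.csv")
  wr(cohort$bouts, "bouts.csv")
  wr(cohort$profiles, "participants.csv")
  wr(cohort$carbs, "carbs.csv")
  wr(cohort$truth, "truth.csv")
  cfg <- cohort$config
  cfg$pa_per_participant <- as.list(cfg$pa_per_participant)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort from the standard CSV layout
#'
#' Counterpart of [write_cohort()]; `carbs.csv` and `truth.csv` are optional
#' (absent carbohydrate logs limit the sensitivity analysis to insulin).
#'
#' @param dir directory holding the CSVs.
#' @return a `glyco_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  rd <- function(nm, required = TRUE) {
    path <- file.path(dir, nm)
    if (!file.exists(path)) {
      if (required) stop("missing required file: ", path)
      return(NULL)
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    for (cn in intersect(names(df), c("time", "onset"))) {
      df[[cn]] <- as.POSIXct(df[[cn]], format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
    }
    df
  }
  cgm <- rd("cgm.csv")
  if (nrow(cgm) == 0L) stop("cgm.csv contains no readings")
  structure(list(profiles = rd("participants.csv"), cgm = cgm,
                 doses = rd("doses.csv"), carbs = rd("carbs.csv", FALSE),
                 bouts = rd("bouts.csv"), truth = rd("truth.csv", FALSE),
                 config = NULL),
            class = "glyco_cohort")
}

#' Run the end-to-end pipeline with file artifacts and a manifest
#'
#' Simulate (or load) → features/eligibility → matching → models → report,
#' writing every intermediate artifact to `out_dir` along with a
#' reproducibility manifest (package version, seed, stage counts mirroring
#' the analysis funnel candidate bouts → eligible → matched → analysed). A
#' stage failure is recorded in the manifest with its reason, downstream
#' stages are skipped, and the manifest is still written.
#'
#' @param config a [sim_config()] (to simulate) — exactly one of `config` and
#'   `data_dir` must be given.
#' @param data_dir directory of input CSVs (to analyse existing data).
#' @param out_dir output directory.
#' @param seed RNG seed recorded in the manifest and used for simulation.
#' @param params a [window_params()].
#' @param write_cgm also write the (large) simulated cgm.csv.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, data_dir = NULL, out_dir,
                         seed = if (!is.null(config)) config$seed else 1L,
                         params = window_params(), write_cgm = TRUE) {
  if (is.null(config) == is.null(data_dir)) {
    stop("provide exactly one of `config` (simulate) or `data_dir` (load)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "glycomatch",
                   version = as.character(utils::packageVersion("glycomatch")),
                   seed = as.integer(seed), stages = list())
  finish <- function(manifest) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(manifest)
  }

  cohort <- tryCatch({
    if (!is.null(config)) {
      ch <- generate_cohort(config, seed = seed)
      data_out <- file.path(out_dir, "data")
      if (write_cgm) write_cohort(ch, data_out)
      ch
    } else {
      read_cohort(data_dir)
    }
  }, error = function(e) e)
  if (inherits(cohort, "error")) {
    manifest$stages$data <- list(status = "failed",
                                 reason = conditionMessage(cohort))
    return(finish(manifest))
  }
  manifest$stages$data <- list(status = "ok",
                               n_participants = nrow(cohort$profiles),
                               n_readings = nrow(cohort$cgm))

  res <- tryCatch(analyze_cohort(cohort, params = params),
                  error = function(e) e)
  if (inherits(res, "error")) {
    manifest$stages$analysis <- list(status = "failed",
                                     reason = conditionMessage(res))
    return(finish(manifest))
  }
  manifest$stages$analysis <- list(status = "ok")
  manifest$counts <- as.list(res$counts)

  ## artifacts
  wr <- function(df, nm) {
    utils::write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  }
  wr(res$windows, "windows.csv")
  wr(res$pairs, "pairs.csv")
  if (nrow(res$outcomes) > 0L) wr(res$outcomes, "outcomes.csv")
  if (!is.null(res$balance)) {
    jsonlite::write_json(
      list(smd = res$balance$smd, n_matched = res$balance$n_matched,
           n_dropped = res$balance$n_dropped),
      file.path(out_dir, "balance.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
  }
  model_json <- function(m, nm) {
    if (is.null(m)) return()
    payload <- if (inherits(m, "glyco_effect_model")) {
      list(fixed = m$fixed, moderators = m$moderators,
           varcomp = m$varcomp, n_obs = m$n_obs, n_pairs = m$n_pairs,
           n_participants = m$n_participants, simplified = m$simplified)
    } else {
      list(fixed = m$fixed, n_events = m$n_events, method = m$method)
    }
    jsonlite::write_json(payload, file.path(out_dir, nm), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", null = "null")
  }
  model_json(res$primary_model, "model_primary.json")
  model_json(res$hypo_model, "model_hypo.json")
  if (!is.null(res$sensitivity)) {
    if (is.null(res$sensitivity$model)) {
      jsonlite::write_json(
        list(fitted = FALSE,
             reason = "refit not supported by the filtered sample",
             n_excluded_pairs = res$sensitivity$n_excluded_pairs,
             n_retained_pairs = res$sensitivity$n_retained_pairs),
        file.path(out_dir, "model_sensitivity.json"), auto_unbox = TRUE)
    } else {
      model_json(res$sensitivity$model, "model_sensitivity.json")
    }
  }
  if (!is.null(res$primary_model)) {
    hm <- predict_grid(res$primary_model)
    wr(hm$grid, "heatmap.csv")
    tb <- cohort_table(cohort$profiles, cohort$cgm)
    wr(tb$continuous, "table1.csv")
  }
  finish(manifest)
}
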