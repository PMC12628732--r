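#' Glucose change from window onset to 20 min post-event
#'
#' `G(end + tail) - G(onset)` with the nearest-reading rule (within the snap
#' tolerance) at both anchors; the 20-min tail absorbs CGM sensor lag.
#'
#' @inheritParams starting_glucose
#' @param window list or one-row data frame with `onset` and `duration`.
#' @param tail minutes after window end at which the endpoint is read.
#' @return change in mmol/L, or `NA_real_` when either anchor reading is
#'   missing (the pair is then excluded from the models).
#' @export
glucose_change <- function(trace, window, tail = 20, tol = 2.5) {
  t0 <- .time_min(window$onset)
  g0 <- starting_glucose(trace, t0, tol = tol)
  g1 <- starting_glucose(trace, t0 + window$duration + tail, tol = tol)
  g1 - g0
}

#' Hypoglycaemia during or within 20 min after a window
#'
#' TRUE when any reading in `[onset, end + tail]` is strictly below the
#' threshold (3.9 mmol/L). When the readings leave a coverage gap longer than
#' `max_gap` minutes inside the interval the result is indeterminate and `NA`
#' is returned.
#'
#' @inheritParams glucose_change
#' @param threshold hypoglycaemia threshold, mmol/L (strict `<`).
#' @param max_gap largest tolerated coverage gap, minutes.
#' @return logical or `NA`.
#' @export
detect_hypo <- function(trace, window, threshold = 3.9, tail = 20,
                        max_gap = 10) {
  t0 <- .time_min(window$onset)
  t1 <- t0 + window$duration + tail
  tm <- .time_min(trace$time)
  lo <- findInterval(t0 - 1e-9, tm) + 1L
  hi <- findInterval(t1 + 1e-9, tm)
  if (hi < lo) return(NA)
  tw <- tm[lo:hi]
  gaps <- c(tw[1] - t0, diff(tw), t1 - tw[length(tw)])
  if (any(gaps > max_gap)) return(NA)
  any(trace$glucose[lo:hi] < threshold)
}

# Events (times in minutes) falling inside [onset, end + tail].
#' @keywords internal
.events_in_window <- function(event_times, onset, duration, tail = 20) {
  event_times >= onset & event_times <= onset + duration + tail
}

#' Assemble the outcome table for the matched pairs
#'
#' One row per window (two per matched pair): the glucose change, the
#' hypoglycaemia indicator, intra-window insulin/carbohydrate flags, the
#' window's own covariates and the participant-level covariates used by the
#' mixed models.
#'
#' @param pairs `pairs` data frame from [knn_match()].
#' @param pa_windows eligible PA windows (with covariates and `window_id`).
#' @param control_covariates data frame of matched-control covariates aligned
#'   with `pairs` rows (columns as in [control_candidates()]).
#' @param cohort_data list with `cgm`, `doses`, `carbs`, `profiles` data
#'   frames covering the participants in `pairs`.
#' @param tail measurement tail, minutes.
#' @return data frame with columns `pair_id`, `window_id`, `participant_id`,
#'   `condition`, `delta_glucose`, `hypo`, `insulin_in_window`,
#'   `carb_in_window`, covariates and profile variables.
#' @export
build_outcomes <- function(pairs, pa_windows, control_covariates, cohort_data,
                           tail = 20) {
  if (nrow(pairs) == 0L) {
    return(data.frame())
  }
  prof <- cohort_data$profiles
  cgm_split <- split(seq_len(nrow(cohort_data$cgm)),
                     cohort_data$cgm$participant_id)
  # numeric-minute traces, built once per participant
  traces <- lapply(cgm_split, function(ix) {
    data.frame(time = .time_min(cohort_data$cgm$time[ix]),
               glucose = cohort_data$cgm$glucose[ix])
  })
  dose_split <- split(seq_len(nrow(cohort_data$doses)),
                      cohort_data$doses$participant_id)
  bolus_min <- lapply(dose_split, function(ix) {
    d <- cohort_data$doses[ix, , drop = FALSE]
    .time_min(d$time[d$kind == "bolus"])
  })
  carb_min <- if (!is.null(cohort_data$carbs) &&
                  nrow(cohort_data$carbs) > 0L) {
    lapply(split(seq_len(nrow(cohort_data$carbs)),
                 cohort_data$carbs$participant_id),
           function(ix) .time_min(cohort_data$carbs$time[ix]))
  } else NULL

  matched_pa <- pa_windows[match(pairs$window_id, pa_windows$window_id), ,
                           drop = FALSE]
  pr <- prof[match(pairs$participant_id, prof$participant_id), ,
             drop = FALSE]
  covc <- c("start_glucose", "roc", "cv_pre", "iob", "clock_time")

  block <- function(cond) {
    onset <- if (cond == "PA") pairs$pa_onset_min else
      pairs$control_onset_min
    covs <- if (cond == "PA") matched_pa[, covc] else
      control_covariates[, covc]
    meas <- vapply(seq_len(nrow(pairs)), function(i) {
      pid <- pairs$participant_id[i]
      win <- list(onset = onset[i], duration = pairs$duration[i])
      tr <- traces[[pid]]
      bolus_t <- bolus_min[[pid]] %||% numeric(0)
      carb_t <- if (!is.null(carb_min)) carb_min[[pid]] %||% numeric(0) else
        numeric(0)
      c(glucose_change(tr, win, tail = tail),
        as.numeric(detect_hypo(tr, win, tail = tail)),
        as.numeric(any(.events_in_window(bolus_t, onset[i],
                                         pairs$duration[i], tail))),
        as.numeric(any(.events_in_window(carb_t, onset[i],
                                         pairs$duration[i], tail))))
    }, numeric(4))
    cbind(
      data.frame(pair_id = pairs$pair_id, window_id = pairs$window_id,
                 participant_id = pairs$participant_id,
                 condition = cond, onset_min = onset,
                 duration = pairs$duration,
                 delta_glucose = meas[1, ], hypo = as.logical(meas[2, ]),
                 insulin_in_window = as.logical(meas[3, ]),
                 carb_in_window = as.logical(meas[4, ])),
      covs,
      data.frame(age = pr$age, bmi = pr$bmi, hba1c = pr$hba1c,
                 modality = pr$modality)
    )
  }
  out <- rbind(block("PA"), block("control"))
  out <- out[order(out$pair_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude pairs with intra-window insulin or carbohydrate from the PA bout
#'
#' Sensitivity analysis: removes matched pairs whose PA window contains any
#' bolus insulin or carbohydrate record between onset and 20 min post-event,
#' then the primary model can be refitted on the remainder. Covariate
#' adjustment stays pre-exposure only (the model formula is unchanged), since
#' intra-window intake is a post-exposure event, not a confounder.
#'
#' @param outcomes output of [build_outcomes()].
#' @return the filtered outcome table, with attributes `n_excluded_pairs` and
#'   `excluded_pair_ids`.
#' @export
sensitivity_filter <- function(outcomes) {
  if (nrow(outcomes) == 0L) return(outcomes)
  pa <- outcomes[outcomes$condition == "PA", , drop = FALSE]
  flagged <- pa$pair_id[pa$insulin_in_window | pa$carb_in_window]
  out <- outcomes[!(outcomes$pair_id %in% flagged), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_pairs") <- length(flagged)
  attr(out, "excluded_pair_ids") <- flagged
  out
}
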