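#' Parameters of window eligibility and control enumeration
#'
#' Collects every constant of the eligibility / control-window stage:
#' overnight hours, peri-activity exclusion margins, the anti-overlap guard
#' between matched periods, the enumeration stride and the covariate snap
#' tolerance.
#'
#' @param overnight_start,overnight_end local hours bounding the overnight
#'   exclusion (default 23:00-06:00).
#' @param pre_exclusion minutes excluded before every PA bout onset.
#' @param post_exclusion minutes excluded after every PA bout end.
#' @param guard minimum clearance in minutes between a selected control window
#'   and any PA bout or other selected control window.
#' @param stride candidate-onset stride in minutes (the CGM grid).
#' @param snap_tol reading snap tolerance in minutes.
#' @param interval nominal CGM cadence in minutes.
#' @param min_availability minimum fraction of expected CGM readings a
#'   participant must have for any bout to qualify.
#' @param glucose_threshold eligibility threshold on starting glucose, mmol/L
#'   (strict inequality).
#' @param dur_range admissible PA bout durations, minutes.
#' @param tail measurement tail after window end, minutes.
#' @return a named list of class `window_params`.
#' @export
window_params <- function(overnight_start = 23, overnight_end = 6,
                          pre_exclusion = 60, post_exclusion = 240,
                          guard = 40, stride = 5, snap_tol = 2.5,
                          interval = 5, min_availability = 0.7,
                          glucose_threshold = 10, dur_range = c(10, 30),
                          tail = 20) {
  structure(list(overnight_start = overnight_start,
                 overnight_end = overnight_end,
                 pre_exclusion = pre_exclusion,
                 post_exclusion = post_exclusion, guard = guard,
                 stride = stride, snap_tol = snap_tol, interval = interval,
                 min_availability = min_availability,
                 glucose_threshold = glucose_threshold,
                 dur_range = dur_range, tail = tail),
            class = "window_params")
}

#' Identify eligible PA bouts for one participant
#'
#' A bout qualifies when the participant has sufficient CGM availability, the
#' bout lasts 10-30 min, its starting glucose is strictly above the threshold
#' (10 mmol/L), and all four matching covariates (starting glucose, rate of
#' change, prior-hour CV, insulin on board) plus the measurement-tail endpoint
#' are computable. Dropped bouts carry a reason code.
#'
#' @param bouts activity log for one participant: data frame with columns
#'   `onset` (POSIXct or numeric minutes) and `duration` (minutes).
#' @param trace the participant's CGM trace (see [starting_glucose()]).
#' @param doses the participant's dose log (see [iob_at()]).
#' @param weight body weight, kg.
#' @param params a [window_params()].
#' @return data frame of PA event windows: onset, duration, condition,
#'   covariates (`start_glucose`, `roc`, `cv_pre`, `iob`, `clock_time`),
#'   `eligible` flag and `reason` code for drops (`"cgm_availability"`,
#'   `"duration"`, `"missing_covariate"`, `"start_glucose"`).
#' @export
eligible_bouts <- function(bouts, trace, doses, weight,
                           params = window_params()) {
  .assert_one_participant(trace)
  n <- nrow(bouts)
  onset_min <- .time_min(bouts$onset)
  out <- data.frame(
    onset = bouts$onset, onset_min = onset_min, duration = bouts$duration,
    condition = rep("PA", n), start_glucose = NA_real_, roc = NA_real_,
    cv_pre = NA_real_, iob = NA_real_, clock_time = onset_min %% 1440,
    eligible = rep(FALSE, n), reason = NA_character_
  )
  if (n == 0L) return(out)
  avail <- cgm_availability(trace, interval = params$interval)
  if (avail < params$min_availability) {
    out$reason <- "cgm_availability"
    return(out)
  }
  tm_last <- .time_min(trace$time)[nrow(trace)]
  for (b in seq_len(n)) {
    t0 <- onset_min[b]
    dur <- bouts$duration[b]
    if (dur < params$dur_range[1] || dur > params$dur_range[2]) {
      out$reason[b] <- "duration"
      next
    }
    sg <- starting_glucose(trace, t0, tol = params$snap_tol)
    roc <- roc_at(trace, t0, tol = params$snap_tol)
    cv <- cv_prior_hour(trace, t0, interval = params$interval)
    io <- iob_at(doses, weight, t0)
    out$start_glucose[b] <- sg; out$roc[b] <- roc
    out$cv_pre[b] <- cv; out$iob[b] <- io
    endpoint_ok <- t0 + dur + params$tail <= tm_last + params$snap_tol &&
      !is.na(.nearest_idx(.time_min(trace$time), t0 + dur + params$tail,
                          params$snap_tol))
    if (is.na(sg) || is.na(roc) || is.na(cv) || !endpoint_ok) {
      out$reason[b] <- "missing_covariate"
      next
    }
    if (sg <= params$glucose_threshold) {
      out$reason[b] <- "start_glucose"
      next
    }
    out$eligible[b] <- TRUE
  }
  out
}

#' Enumerate admissible non-PA control windows for a PA bout
#'
#' Candidate windows of the same duration as the PA bout are laid on the CGM
#' grid at the enumeration stride and retained when they (a) do not intersect
#' the overnight period, (b) do not intersect the exclusion zone
#' (1 h before to 4 h after) of any of the participant's PA bouts, (c) lie at
#' least `guard` minutes clear of the matched PA window, and (d) have all four
#' matching covariates computable and a readable measurement-tail endpoint.
#'
#' @param pa_window one row of the output of [eligible_bouts()].
#' @param bouts all of the participant's PA bouts (not just the matched one).
#' @inheritParams eligible_bouts
#' @return data frame of candidate control windows with onset, duration and
#'   covariates; zero rows when the bout is unmatchable.
#' @export
control_candidates <- function(pa_window, bouts, trace, doses, weight,
                               params = window_params()) {
  .assert_one_participant(trace)
  track <- .covariate_track(trace, doses, weight, interval = params$interval)
  excl <- .exclusion_intervals(bouts, track$time_min, params,
                               guard_window = pa_window)
  idx <- .admissible_starts(track, pa_window$duration, excl, params)
  cand <- track[idx, , drop = FALSE]
  if (nrow(cand) > 0L) {
    cand$onset <- if (inherits(trace$time, "POSIXt")) {
      .as_time(cand$time_min)
    } else {
      cand$time_min
    }
  } else {
    cand$onset <- if (inherits(trace$time, "POSIXt")) {
      .as_time(numeric(0))
    } else numeric(0)
  }
  cand$duration <- rep(pa_window$duration, nrow(cand))
  cand$condition <- rep("control", nrow(cand))
  rownames(cand) <- NULL
  cand[, c("onset", "time_min", "duration", "condition", "start_glucose",
           "roc", "cv_pre", "iob", "clock_time")]
}

## ---- internals -----------------------------------------------------------

# Exclusion intervals (numeric-minute [start, end] pairs): overnight periods
# spanning the record, the pre/post exclusion zone of every PA bout, and the
# guard band around the matched window itself (implied by the bout zones but
# enforced independently).
#' @keywords internal
.exclusion_intervals <- function(bouts, time_min, params,
                                 guard_window = NULL) {
  t0 <- time_min[1]; t1 <- time_min[length(time_min)]
  day_lo <- floor(t0 / 1440) - 1
  day_hi <- ceiling(t1 / 1440)
  days <- day_lo:day_hi
  nights <- cbind(days * 1440 + params$overnight_start * 60,
                  (days + 1) * 1440 + params$overnight_end * 60)
  iv <- nights
  if (!is.null(bouts) && nrow(bouts) > 0L) {
    o <- .time_min(bouts$onset); e <- o + bouts$duration
    iv <- rbind(iv, cbind(o - params$pre_exclusion,
                          e + params$post_exclusion))
  }
  if (!is.null(guard_window)) {
    o <- .time_min(guard_window$onset)
    iv <- rbind(iv, cbind(o - params$guard,
                          o + guard_window$duration + params$guard))
  }
  iv
}

# Merge possibly overlapping [start, end] intervals into disjoint sorted ones.
#' @keywords internal
.merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  s <- iv[, 1]; e <- iv[, 2]
  keep_s <- s[1]; keep_e <- e[1]
  for (j in seq_len(nrow(iv))[-1]) {
    k <- length(keep_e)
    if (s[j] <= keep_e[k]) {
      keep_e[k] <- max(keep_e[k], e[j])
    } else {
      keep_s <- c(keep_s, s[j]); keep_e <- c(keep_e, e[j])
    }
  }
  cbind(keep_s, keep_e)
}

# Grid indices whose window [t, t + dur] avoids every exclusion interval,
# has computable covariates and a readable endpoint at t + dur + tail.
# A window intersects interval [s, e] iff s - dur < t < e; with disjoint
# sorted intervals this reduces to two findInterval scans.
#' @keywords internal
.admissible_starts <- function(track, dur, intervals, params,
                               merged = FALSE) {
  t <- track$time_min
  t_last <- t[length(t)]
  ok <- !is.na(track$roc) & !is.na(track$cv_pre) &
    (t + dur + params$tail <= t_last + params$snap_tol) &
    (abs((t - t[1]) %% params$stride) < 1e-9)
  if (!is.null(intervals) && nrow(intervals) > 0L) {
    iv <- if (merged) intervals else .merge_intervals(intervals)
    n_open <- findInterval(t - 1e-9, iv[, 1] - dur)   # s - dur < t opens
    n_closed <- findInterval(t + 1e-9, iv[, 2] - 1e-9) # e <= t closes
    ok <- ok & (n_open <= n_closed)
  }
  which(ok)
}
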