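#' Starting glucose at event onset
#'
#' The CGM reading nearest to the event onset `t0`, within a snap tolerance of
#' half the nominal sampling cadence. Ties resolve to the earlier reading.
#'
#' @param trace single-participant CGM trace: data frame with columns `time`
#'   (POSIXct or numeric minutes) and `glucose` (mmol/L), times strictly
#'   increasing.
#' @param t0 event onset (POSIXct or numeric minutes).
#' @param tol snap tolerance in minutes.
#' @return glucose in mmol/L, or `NA_real_` when no reading lies within `tol`
#'   of `t0` (missing-covariate signal; callers exclude the event).
#' @export
starting_glucose <- function(trace, t0, tol = 2.5) {
  tm <- .time_min(trace$time)
  idx <- .nearest_idx(tm, .time_min(t0), tol)
  if (is.na(idx)) NA_real_ else trace$glucose[idx]
}

#' Glucose rate of change at event onset
#'
#' Mean of the three 5-min rate-of-change values immediately prior to onset:
#' readings are snapped (within `tol`) to the four anchors `t0`, `t0-5`,
#' `t0-10`, `t0-15` min and the three consecutive differences are averaged and
#' divided by 5. On a complete grid this telescopes to
#' `(G(t0) - G(t0-15)) / 15`.
#'
#' @inheritParams starting_glucose
#' @return rate of change in mmol/L per min, or `NA_real_` if any anchor
#'   reading is missing.
#' @export
roc_at <- function(trace, t0, tol = 2.5) {
  tm <- .time_min(trace$time)
  t0 <- .time_min(t0)
  anchors <- t0 - c(0, 5, 10, 15)
  idx <- vapply(anchors, function(a) .nearest_idx(tm, a, tol), integer(1))
  if (anyNA(idx)) return(NA_real_)
  g <- trace$glucose[idx]
  mean(g[1:3] - g[2:4]) / 5
}

#' Coefficient of variation of glucose in the hour before an event
#'
#' Sample SD over mean (as a percentage) of the readings in `[t0 - 60, t0]`
#' (onset reading included). At a 5-min cadence the hour is expected to supply
#' `60 / interval = 12` readings; the window is computed only when at least
#' `min_frac` of that count is present.
#'
#' @inheritParams starting_glucose
#' @param interval nominal CGM cadence, minutes.
#' @param min_frac minimum fraction of expected readings required.
#' @return CV in percent, or `NA_real_` when coverage is insufficient.
#' @export
cv_prior_hour <- function(trace, t0, interval = 5, min_frac = 0.75) {
  tm <- .time_min(trace$time)
  t0 <- .time_min(t0)
  lo <- findInterval(t0 - 60 - 1e-9, tm) + 1L
  hi <- findInterval(t0 + 1e-9, tm)
  n <- hi - lo + 1L
  expected <- 60 / interval
  if (n < min_frac * expected || n < 2L) return(NA_real_)
  g <- trace$glucose[lo:hi]
  100 * stats::sd(g) / mean(g)
}

#' Insulin on board per kilogram at a time point
#'
#' Residual rapid-acting insulin under a linear 4-h decay: every bolus dose
#' `d` with `0 <= t - t_d < 240` min contributes
#' `units_d * (1 - (t - t_d)/240)`; the sum is divided by body weight. Basal
#' records and doses after `t` are ignored; an empty log gives 0.
#'
#' @param doses dose log: data frame with columns `time` (POSIXct or numeric
#'   minutes), `units` (U) and `kind` (`"bolus"`/`"basal"`).
#' @param weight body weight in kg.
#' @param t evaluation time.
#' @param action_minutes duration of insulin action, minutes.
#' @return insulin on board in U/kg.
#' @export
iob_at <- function(doses, weight, t, action_minutes = 240) {
  stopifnot(weight > 0)
  if (is.null(doses) || nrow(doses) == 0L) return(0)
  t <- .time_min(t)
  rel <- t - .time_min(doses$time)
  keep <- doses$kind == "bolus" & rel >= 0 & rel < action_minutes
  if (!any(keep)) return(0)
  sum(doses$units[keep] * (1 - rel[keep] / action_minutes)) / weight
}

#' Descriptive glycaemic metrics of a CGM trace
#'
#' Equal-weight summaries over all readings: mean, SD, CV (%), and the
#' percentage of time in range 3.9-10.0 mmol/L (TIR), below 3.9 (TBR) and
#' above 10.0 (TAR). The three time fractions sum to 100.
#'
#' @inheritParams starting_glucose
#' @return a one-row data frame with columns `mean`, `sd`, `cv`, `tir`, `tbr`,
#'   `tar`.
#' @export
glycaemic_metrics <- function(trace) {
  g <- trace$glucose
  if (length(g) == 0L) stop("empty trace")
  m <- mean(g)
  s <- if (length(g) > 1L) stats::sd(g) else 0
  data.frame(
    mean = m, sd = s, cv = 100 * s / m,
    tir = 100 * mean(g >= 3.9 & g <= 10.0),
    tbr = 100 * mean(g < 3.9),
    tar = 100 * mean(g > 10.0)
  )
}

#' Fraction of expected CGM readings present over the study span
#'
#' Readings present divided by readings expected at the nominal cadence over
#' the observed span (first to last reading, inclusive endpoints).
#'
#' @inheritParams cv_prior_hour
#' @return availability fraction in (0, 1].
#' @export
cgm_availability <- function(trace, interval = 5) {
  tm <- .time_min(trace$time)
  if (length(tm) == 0L) return(0)
  expected <- floor((tm[length(tm)] - tm[1]) / interval) + 1
  min(1, length(tm) / expected)
}

# Vectorized per-grid-point covariates for a gap-free trace; used by the
# pipeline to score thousands of candidate control onsets cheaply. Values
# agree with the per-event functions at every grid time (property-tested).
# Returns a data.frame aligned with the trace rows; entries that cannot be
# computed (too close to the record start) are NA.
#' @keywords internal
.covariate_track <- function(trace, doses, weight, interval = 5) {
  tm <- .time_min(trace$time)
  if (!.is_regular_grid(tm, interval)) {
    stop("covariate track requires a gap-free regular CGM grid")
  }
  g <- trace$glucose
  n <- length(g)
  k_roc <- as.integer(round(15 / interval))
  roc <- rep(NA_real_, n)
  if (n > k_roc) {
    roc[(k_roc + 1):n] <- (g[(k_roc + 1):n] - g[1:(n - k_roc)]) / 15
  }
  # rolling CV over the inclusive prior-hour window (60/interval + 1 points)
  w <- as.integer(round(60 / interval)) + 1L
  cv <- rep(NA_real_, n)
  if (n >= w) {
    g0 <- mean(g)                       # shift for numerical stability
    gs <- g - g0
    cs <- cumsum(gs)
    cs2 <- cumsum(gs^2)
    s1 <- cs[w:n] - c(0, cs)[(w:n) - w + 1L]
    s2 <- cs2[w:n] - c(0, cs2)[(w:n) - w + 1L]
    m <- s1 / w
    v <- pmax(0, (s2 - w * m^2) / (w - 1))
    v[v < 1e-10] <- 0                   # exact-constant windows
    cv[w:n] <- 100 * sqrt(v) / (m + g0)
  }
  iob <- numeric(n)
  if (!is.null(doses) && nrow(doses) > 0L) {
    bol <- doses[doses$kind == "bolus", , drop = FALSE]
    if (nrow(bol) > 0L) {
      td <- .time_min(bol$time)
      for (j in seq_len(nrow(bol))) {
        # grid indices with 0 <= t - td < 240
        lo <- ceiling((td[j] - tm[1]) / interval) + 1
        hi <- ceiling((td[j] + 240 - tm[1]) / interval)  # strict upper bound
        if (abs((td[j] + 240 - tm[1]) / interval - round((td[j] + 240 - tm[1]) / interval)) < 1e-9) {
          hi <- round((td[j] + 240 - tm[1]) / interval)  # exclude rel == 240
        }
        lo <- max(1L, as.integer(lo)); hi <- min(n, as.integer(hi))
        if (lo <= hi) {
          rel <- tm[lo:hi] - td[j]
          iob[lo:hi] <- iob[lo:hi] + bol$units[j] * (1 - rel / 240)
        }
      }
    }
  }
  iob <- iob / weight
  clock <- tm %% 1440
  data.frame(time_min = tm, start_glucose = g, roc = roc, cv_pre = cv,
             iob = iob, clock_time = clock)
}
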