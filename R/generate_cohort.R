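#' Generate a synthetic type 1 diabetes CGM cohort with known causal structure
#'
#' Simulates a free-living cohort — participant profiles, CGM traces, insulin
#' dose and carbohydrate logs, and physical-activity (PA) bouts — whose
#' PA-attributable glucose changes are known exactly, so that the matching and
#' modelling stages of the pipeline can be validated against ground truth.
#'
#' Each participant's glucose is a discrete-time mean-reverting walk around an
#' individual set-point on the CGM grid, with additive meal excursions (rise
#' then decay over 60-120 min), bolus-driven declines following the linear 4-h
#' insulin action curve, and i.i.d. sensor noise. PA bouts are placed in
#' daytime hours (06:00-23:00), non-overlapping and separated by more than 5 h
#' so each bout owns clean exclusion zones. For every bout the generator adds,
#' as a uniform ramp over the bout plus its 20-min measurement tail, an
#' attributable change built from the bout's onset covariates (computed with
#' the same functions the analysis pipeline uses), a participant random effect
#' and bout noise; the realized change of every bout is recorded in `truth`.
#' Covariates in the effect formula are centred at their means over eligible
#' bouts (onset glucose > 10 mmol/L), so `effect_intercept` is the mean
#' differential effect in the analysed population. Optionally, rescue
#' carbohydrate intake is triggered when glucose falls low during a bout's
#' measurement window, emulating treatment reactions to rapid drops.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical seeds give
#'   byte-identical cohorts.
#' @return an object of class `glyco_cohort`: a list with data frames
#'   `profiles`, `cgm`, `doses`, `carbs`, `bouts`, `truth` and the `config`
#'   used. Bout onsets always lie inside their participant's CGM span, and
#'   `truth` has one row per placed bout.
#' @examples
#' cohort <- generate_cohort(sim_config(n_participants = 2, n_days = 3))
#' nrow(cohort$truth)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  config <- validate_sim_config(config)
  set.seed(seed)
  P <- config$n_participants
  interval <- config$cgm_interval
  spd <- as.integer(round(1440 / interval))
  N <- config$n_days * spd
  t_min <- (seq_len(N) - 1) * interval
  origin <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

  profiles <- .sim_profiles(P)

  ## --- shared glucose dynamics -------------------------------------------
  a <- config$ou_reversion
  s_stat <- if (config$ou_sigma > 0 && a > 0) {
    config$ou_sigma / sqrt(1 - (1 - a)^2)
  } else 0
  G <- .ou_paths(N, P, mu = profiles$mu_glucose, a = a,
                 sigma = config$ou_sigma, s_stat = s_stat)

  ## --- meals and carbohydrate log ----------------------------------------
  n_meals <- stats::rpois(P * config$n_days, config$meal_rate)
  meal_pid <- rep(rep(seq_len(P), each = config$n_days), n_meals)
  meal_day <- rep(rep(seq_len(config$n_days) - 1, times = P), n_meals)
  n_m <- length(meal_pid)
  meal_onset <- meal_day * 1440 + stats::runif(n_m, 390, 1260)
  meal_amp <- stats::rgamma(n_m, shape = 4, rate = 4 / config$meal_amplitude)
  meal_span <- stats::runif(n_m, 60, 120)
  if (n_m > 0L) {
    G <- .add_kernels(G, t_min, interval, meal_pid, meal_onset, meal_span,
                      function(rel, ev) {
                        rise <- 0.3 * meal_span[ev]
                        ifelse(rel <= rise,
                               meal_amp[ev] * rel / rise,
                               meal_amp[ev] *
                                 pmax(0, 1 - (rel - rise) /
                                        (meal_span[ev] - rise)))
                      })
  }

  ## --- boluses (meal-covering + corrections) -----------------------------
  covered <- if (n_m > 0L) stats::runif(n_m) < config$bolus_prob else logical(0)
  b_shape <- (config$bolus_mean / config$bolus_sd)^2
  b_scale <- config$bolus_sd^2 / config$bolus_mean
  bol_units <- stats::rgamma(sum(covered), shape = b_shape, scale = b_scale)
  bol_time <- meal_onset[covered] + stats::runif(sum(covered), -10, 5)
  bol_pid <- meal_pid[covered]

  n_corr <- stats::rpois(P * config$n_days, config$correction_rate)
  corr_pid <- rep(rep(seq_len(P), each = config$n_days), n_corr)
  corr_day <- rep(rep(seq_len(config$n_days) - 1, times = P), n_corr)
  corr_time <- corr_day * 1440 + stats::runif(length(corr_pid), 390, 1320)
  corr_units <- stats::rgamma(length(corr_pid), shape = 4, scale = 0.5)

  bolus_pid <- c(bol_pid, corr_pid)
  bolus_time <- c(bol_time, corr_time)
  bolus_units <- round(c(bol_units, corr_units), 2)
  keep <- bolus_time >= 0 & bolus_time <= t_min[N]
  bolus_pid <- bolus_pid[keep]; bolus_time <- bolus_time[keep]
  bolus_units <- bolus_units[keep]
  if (length(bolus_pid) > 0L) {
    k_ins <- config$insulin_action
    G <- .add_kernels(G, t_min, interval, bolus_pid, bolus_time,
                      rep(360, length(bolus_pid)),
                      function(rel, ev) {
                        h <- ifelse(rel <= 240, rel / 240,
                                    pmax(0, 1 - (rel - 240) / 120))
                        -bolus_units[ev] * k_ins * h
                      })
  }

  ## --- sensor noise -------------------------------------------------------
  if (config$sigma_noise > 0) {
    G <- G + matrix(stats::rnorm(N * P, 0, config$sigma_noise), N, P)
  }

  ## --- PA bouts -----------------------------------------------------------
  bouts <- .place_bouts(config, P)
  doses <- .assemble_doses(profiles, config, bolus_pid, bolus_time,
                           bolus_units)

  truth <- .apply_pa_effects(G, t_min, interval, bouts, doses, profiles,
                             config)
  G <- truth$G
  bouts$activity_type <- sample(c("walking", "cycling", "aerobic", "strength",
                                  "other"),
                                nrow(bouts), replace = TRUE,
                                prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
  bouts$intensity <- sample(c("light", "moderate", "vigorous"), nrow(bouts),
                            replace = TRUE, prob = c(0.4, 0.45, 0.15))

  ## --- rescue carbohydrates ----------------------------------------------
  rescue <- .apply_rescues(G, t_min, interval, bouts, config)
  G <- rescue$G

  ## --- clip to sensor range and assemble ---------------------------------
  G <- pmin(pmax(G, 2.2), 22.2)

  ids <- profiles$participant_id
  cgm <- data.frame(
    participant_id = rep(ids, each = N),
    time = origin + rep(t_min, P) * 60,
    glucose = as.numeric(G)
  )
  carbs <- data.frame(
    participant_id = c(ids[meal_pid], ids[rescue$pid]),
    time = origin + c(meal_onset, rescue$time) * 60,
    grams = c(round(meal_amp * 12), rep(config$rescue_grams,
                                        length(rescue$pid)))
  )
  carbs <- carbs[order(carbs$participant_id, carbs$time), , drop = FALSE]
  rownames(carbs) <- NULL
  doses$time <- origin + doses$time_min * 60
  doses <- doses[order(doses$participant_id, doses$time),
                 c("participant_id", "time", "units", "kind")]
  rownames(doses) <- NULL

  bouts_out <- data.frame(
    participant_id = ids[bouts$pid],
    onset = origin + bouts$onset * 60,
    duration = bouts$duration,
    activity_type = bouts$activity_type,
    intensity = bouts$intensity
  )
  truth_out <- data.frame(
    participant_id = ids[bouts$pid],
    onset = origin + bouts$onset * 60,
    duration = bouts$duration,
    delta = truth$delta,
    start_glucose = truth$cov$start_glucose,
    roc = truth$cov$roc,
    cv_pre = truth$cov$cv_pre,
    iob = truth$cov$iob,
    eligible_start = truth$eligible
  )
  ord <- order(bouts_out$participant_id, bouts_out$onset)
  bouts_out <- bouts_out[ord, , drop = FALSE]; rownames(bouts_out) <- NULL
  truth_out <- truth_out[ord, , drop = FALSE]; rownames(truth_out) <- NULL

  structure(list(profiles = profiles, cgm = cgm, doses = doses,
                 carbs = carbs, bouts = bouts_out, truth = truth_out,
                 config = config, seed = as.integer(seed)),
            class = "glyco_cohort")
}

#' @export
print.glyco_cohort <- function(x, ...) {
  cat("<glyco_cohort>\n")
  cat(sprintf("  %d participants, %d CGM readings, %d bouts, %d doses\n",
              nrow(x$profiles), nrow(x$cgm), nrow(x$bouts), nrow(x$doses)))
  cat(sprintf("  seed %d; effect intercept %.2f mmol/L\n", x$seed,
              x$config$effect_intercept))
  invisible(x)
}

## ---- internals -----------------------------------------------------------

#' @keywords internal
.sim_profiles <- function(P) {
  adult <- stats::runif(P) < 0.75
  age <- ifelse(adult,
                pmin(pmax(round(stats::rnorm(P, 35, 11)), 18), 70),
                sample(12:17, P, replace = TRUE))
  sex <- sample(c("F", "M"), P, replace = TRUE)
  height <- ifelse(adult, stats::rnorm(P, 1.70, 0.09),
                   stats::rnorm(P, 1.62, 0.09))
  bmi <- ifelse(adult,
                pmin(pmax(stats::rnorm(P, 25.5, 4), 16), 42),
                pmin(pmax(stats::rnorm(P, 21.5, 3), 14.5), 35))
  weight <- round(bmi * height^2, 1)
  hba1c <- pmin(pmax(round(stats::rnorm(P, 51, 8)), 35), 95)
  modality <- sample(c("closed_loop", "pump", "mdi"), P, replace = TRUE,
                     prob = c(0.47, 0.38, 0.15))
  mu <- pmin(pmax(stats::rnorm(P, 8.4, 1.2), 5.5), 12)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(P)),
    age = age, sex = sex, bmi = round(bmi, 1), weight = weight,
    hba1c = hba1c, modality = modality, mu_glucose = round(mu, 2)
  )
}

# Mean-reverting paths, one column per participant, initialized at the
# stationary distribution.
#' @keywords internal
.ou_paths <- function(N, P, mu, a, sigma, s_stat) {
  G <- matrix(0, N, P)
  dev <- stats::rnorm(P, 0, s_stat)
  G[1, ] <- mu + dev
  if (N > 1L) {
    innov <- matrix(stats::rnorm((N - 1) * P, 0, sigma), N - 1, P)
    for (k in 2:N) {
      dev <- (1 - a) * dev + innov[k - 1, ]
      G[k, ] <- mu + dev
    }
  }
  G
}

# Add event kernels to the trace matrix. Events are (pid, onset, span); the
# kernel function maps (rel-minutes, event-index) to additive values at grid
# times strictly after onset and at most onset + span.
#' @keywords internal
.add_kernels <- function(G, t_min, interval, pid, onset, span, kernel) {
  N <- nrow(G)
  i_lo <- pmax(1L, as.integer(floor(onset / interval)) + 2L)
  i_hi <- pmin(N, as.integer(floor((onset + span) / interval)) + 1L)
  len <- i_hi - i_lo + 1L
  keep <- len > 0L
  if (!any(keep)) return(G)
  i_lo <- i_lo[keep]; len <- len[keep]
  ev_keep <- which(keep)
  rows <- sequence(len, from = i_lo)
  ev <- rep(ev_keep, len)
  rel <- t_min[rows] - onset[ev]
  val <- kernel(rel, ev)
  flat <- rows + (pid[ev] - 1L) * N
  agg <- rowsum(val, flat, reorder = FALSE)
  G[as.integer(rownames(agg))] <- G[as.integer(rownames(agg))] + agg[, 1]
  G
}

# Daytime, non-overlapping bout placement with > 5 h separation. Errors when
# the wear period cannot host the requested bouts.
#' @keywords internal
.place_bouts <- function(config, P) {
  lo <- config$pa_per_participant[1]; hi <- config$pa_per_participant[2]
  sh <- config$pa_duration_shape
  out_pid <- integer(0); out_onset <- numeric(0); out_dur <- numeric(0)
  for (p in seq_len(P)) {
    n_b <- if (lo == hi) lo else sample(lo:hi, 1L)
    if (n_b == 0L) next
    dur <- round(10 + 20 * stats::rbeta(n_b, sh[1], sh[2]))
    onsets <- numeric(0); ends <- numeric(0)
    placed <- 0L; tries <- 0L
    while (placed < n_b && tries < 4000L) {
      tries <- tries + 1L
      d <- sample(seq_len(config$n_days), 1L) - 1L
      dcur <- dur[placed + 1L]
      o <- d * 1440 + round(stats::runif(1, 360, 1380 - dcur))
      e <- o + dcur
      ok <- all(o > ends + 300 | e < onsets - 300)
      if (ok) {
        placed <- placed + 1L
        onsets <- c(onsets, o); ends <- c(ends, e)
      }
    }
    if (placed < n_b) {
      stop(sprintf(
        "could not place %d PA bouts in %d days for participant %d; n_days too short for the requested bouts and exclusion zones",
        n_b, config$n_days, p))
    }
    out_pid <- c(out_pid, rep(p, n_b))
    out_onset <- c(out_onset, onsets)
    out_dur <- c(out_dur, dur)
  }
  data.frame(pid = out_pid, onset = out_onset, duration = out_dur)
}

#' @keywords internal
.assemble_doses <- function(profiles, config, bolus_pid, bolus_time,
                            bolus_units) {
  P <- nrow(profiles)
  basal_pid <- rep(seq_len(P), each = config$n_days)
  basal_time <- rep((seq_len(config$n_days) - 1) * 1440, times = P)
  basal_units <- round(0.25 * profiles$weight[basal_pid], 1)
  data.frame(
    participant_id = profiles$participant_id[c(bolus_pid, basal_pid)],
    time_min = c(bolus_time, basal_time),
    units = c(bolus_units, basal_units),
    kind = c(rep("bolus", length(bolus_pid)),
             rep("basal", length(basal_pid)))
  )
}

# Compute onset covariates for every bout with the pipeline's own feature
# functions, build the attributable change, and ramp it onto the traces.
#' @keywords internal
.apply_pa_effects <- function(G, t_min, interval, bouts, doses, profiles,
                              config) {
  n_b <- nrow(bouts)
  if (n_b == 0L) {
    return(list(G = G, delta = numeric(0),
                cov = data.frame(start_glucose = numeric(0), roc = numeric(0),
                                 cv_pre = numeric(0), iob = numeric(0)),
                eligible = logical(0)))
  }
  N <- nrow(G)
  cov <- data.frame(start_glucose = rep(NA_real_, n_b), roc = NA_real_,
                    cv_pre = NA_real_, iob = NA_real_)
  doses_by_pid <- split(seq_len(nrow(doses)),
                        match(doses$participant_id, profiles$participant_id))
  for (p in unique(bouts$pid)) {
    trace <- data.frame(time = t_min, glucose = G[, p])
    dp <- doses[doses_by_pid[[as.character(p)]] %||% integer(0), ,
                drop = FALSE]
    dp <- data.frame(time = dp$time_min, units = dp$units, kind = dp$kind)
    for (b in which(bouts$pid == p)) {
      t0 <- bouts$onset[b]
      cov$start_glucose[b] <- starting_glucose(trace, t0)
      cov$roc[b] <- roc_at(trace, t0)
      cov$cv_pre[b] <- cv_prior_hour(trace, t0, interval = interval)
      cov$iob[b] <- iob_at(dp, profiles$weight[p], t0)
    }
  }
  u <- cbind(
    roc_decline = -cov$roc / 0.1,
    start_lower = -cov$start_glucose,
    cv = cov$cv_pre,
    duration = bouts$duration,
    iob = cov$iob / 0.1,
    age = profiles$age[bouts$pid],
    bmi_lower = -profiles$bmi[bouts$pid]
  )
  eligible <- !is.na(cov$start_glucose) & cov$start_glucose > 10
  centre_set <- if (any(eligible)) eligible else rep(TRUE, n_b)
  u_bar <- colMeans(u[centre_set, , drop = FALSE], na.rm = TRUE)
  u_c <- sweep(u, 2, u_bar)
  u_c[is.na(u_c)] <- 0
  s <- config$effect_slopes[colnames(u)]
  b_part <- stats::rnorm(nrow(profiles), 0, config$effect_sd_between)
  eps <- stats::rnorm(n_b, 0, config$effect_sd_within)
  delta <- config$effect_intercept + drop(u_c %*% s) +
    b_part[bouts$pid] + eps
  span0 <- bouts$duration + 20
  G <- .add_kernels(G, t_min, interval, bouts$pid, bouts$onset,
                    span0 + 180,
                    function(rel, ev) {
                      ifelse(rel <= span0[ev],
                             delta[ev] * rel / span0[ev],
                             delta[ev] * pmax(0, 1 - (rel - span0[ev]) / 180))
                    })
  list(G = G, delta = delta, cov = cov, eligible = eligible)
}

# Drop-triggered rescue carbohydrates inside PA measurement windows.
#' @keywords internal
.apply_rescues <- function(G, t_min, interval, bouts, config) {
  pid <- integer(0); time <- numeric(0)
  if (config$rescue_enabled && nrow(bouts) > 0L) {
    N <- nrow(G)
    for (b in seq_len(nrow(bouts))) {
      p <- bouts$pid[b]
      lo <- max(1L, as.integer(ceiling(bouts$onset[b] / interval)) + 1L)
      hi <- min(N, as.integer(floor((bouts$onset[b] + bouts$duration[b] + 20) /
                                      interval)) + 1L)
      if (lo > hi) next
      gwin <- G[lo:hi, p]
      below <- which(gwin < config$rescue_threshold)
      if (length(below) == 0L) next
      if (stats::runif(1) < config$rescue_prob) {
        tcross <- t_min[lo + below[1] - 1L]
        pid <- c(pid, p); time <- c(time, tcross)
      }
    }
    if (length(pid) > 0L) {
      amp <- config$rescue_grams / 15 * 2.5
      G <- .add_kernels(G, t_min, interval, pid, time + 10, rep(80,
                                                                length(pid)),
                        function(rel, ev) {
                          ifelse(rel <= 20, amp * rel / 20,
                                 amp * pmax(0, 1 - (rel - 20) / 60))
                        })
    }
  }
  list(G = G, pid = pid, time = time)
}
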