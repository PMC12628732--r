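# Shared fixtures and independent oracles. Everything is generated in code;
# no stored data.

# A single-participant trace on a regular grid (times in minutes).
make_trace <- function(glucose, start = 0, interval = 5) {
  data.frame(time = start + (seq_along(glucose) - 1) * interval,
             glucose = glucose)
}

flat_trace <- function(value = 8, n = 300, start = 0, interval = 5) {
  make_trace(rep(value, n), start = start, interval = interval)
}

no_doses <- function() {
  data.frame(time = numeric(0), units = numeric(0), kind = character(0))
}

# A small but analysable cohort configuration.
small_config <- function(n_participants = 12, n_days = 14, ...) {
  sim_config(n_participants = n_participants, n_days = n_days, ...)
}

# Brute-force control-window enumeration: walks every stride position and
# re-derives admissibility from first principles with the public per-event
# functions and naive per-interval overlap loops.
oracle_candidates <- function(pa_window, bouts, trace, doses, weight,
                              params = window_params()) {
  tm <- trace$time
  dur <- pa_window$duration
  t_last <- tm[length(tm)]
  starts <- seq(tm[1], t_last, by = params$stride)
  keep <- logical(length(starts))
  # overnight intervals
  days <- (floor(tm[1] / 1440) - 1):ceiling(t_last / 1440)
  nights <- cbind(days * 1440 + params$overnight_start * 60,
                  (days + 1) * 1440 + params$overnight_end * 60)
  bo <- bouts$onset
  be <- bouts$onset + bouts$duration
  po <- pa_window$onset
  pe <- po + dur
  for (i in seq_along(starts)) {
    t <- starts[i]
    ok <- TRUE
    for (j in seq_len(nrow(nights))) {
      if (t < nights[j, 2] && t + dur > nights[j, 1]) ok <- FALSE
    }
    for (j in seq_along(bo)) {
      if (t < be[j] + params$post_exclusion &&
          t + dur > bo[j] - params$pre_exclusion) ok <- FALSE
    }
    if (t < pe + params$guard && t + dur > po - params$guard) ok <- FALSE
    if (ok) {
      sg <- starting_glucose(trace, t, tol = params$snap_tol)
      rc <- roc_at(trace, t, tol = params$snap_tol)
      cv <- cv_prior_hour(trace, t, interval = params$interval)
      ge <- starting_glucose(trace, t + dur + params$tail,
                             tol = params$snap_tol)
      if (is.na(sg) || is.na(rc) || is.na(cv) || is.na(ge)) ok <- FALSE
    }
    keep[i] <- ok
  }
  starts[keep]
}

# Brute-force best-first greedy matcher: recomputes everything from scratch
# at every step with plain loops; must agree exactly with knn_match().
oracle_knn <- function(pa_windows, candidates, weights, guard = 40) {
  vars <- weights$variables
  w <- as.numeric(weights$weights[vars])
  cal <- as.numeric(weights$calipers[vars])
  sds <- weights$standardizers$sd[match(vars,
                                        weights$standardizers$variable)]
  out <- list()
  for (pid in unique(pa_windows$participant_id)) {
    pw <- pa_windows[pa_windows$participant_id == pid, , drop = FALSE]
    taken <- list()
    assigned <- rep(FALSE, nrow(pw))
    repeat {
      best <- NULL
      for (i in which(!assigned)) {
        cc <- candidates[[pw$window_id[i]]]
        if (is.null(cc) || nrow(cc) == 0L) next
        for (j in seq_len(nrow(cc))) {
          admissible <- TRUE
          d2 <- 0
          for (k in seq_along(vars)) {
            gp <- abs(cc[[vars[k]]][j] - pw[[vars[k]]][i])
            if (gp > cal[k]) admissible <- FALSE
            d2 <- d2 + w[k] * (gp / sds[k])^2
          }
          if (!admissible) next
          for (tk in taken) {
            if (cc$time_min[j] < tk[2] + guard &&
                cc$time_min[j] + cc$duration[j] > tk[1] - guard) {
              admissible <- FALSE
            }
          }
          if (!admissible) next
          d <- sqrt(d2)
          if (is.null(best) ||
              d < best$d - 1e-12 ||
              (abs(d - best$d) <= 1e-12 &&
               (cc$time_min[j] < best$c_onset ||
                (cc$time_min[j] == best$c_onset &&
                 pw$onset_min[i] < best$p_onset)))) {
            best <- list(i = i, j = j, d = d, c_onset = cc$time_min[j],
                         p_onset = pw$onset_min[i],
                         dur = pw$duration[i])
          }
        }
      }
      if (is.null(best)) break
      out[[length(out) + 1L]] <- data.frame(
        window_id = pw$window_id[best$i], participant_id = pid,
        pa_onset_min = pw$onset_min[best$i],
        control_onset_min = best$c_onset, distance = best$d)
      assigned[best$i] <- TRUE
      taken[[length(taken) + 1L]] <- c(best$c_onset, best$c_onset + best$dur)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(window_id = character(0), participant_id = character(0),
               pa_onset_min = numeric(0), control_onset_min = numeric(0),
               distance = numeric(0))
  res[order(res$participant_id, res$pa_onset_min), , drop = FALSE]
}

# Random small matching instance for the oracle-equivalence fuzz.
random_match_instance <- function(n_bouts = NULL, n_cand = NULL) {
  n_bouts <- n_bouts %||% sample(1:8, 1)
  vars <- c("start_glucose", "roc", "cv_pre", "iob")
  mu <- c(11, 0, 20, 0.02)
  sdv <- c(1.5, 0.05, 8, 0.02)
  pw <- data.frame(
    window_id = sprintf("w%02d", seq_len(n_bouts)),
    participant_id = sample(c("A", "B"), n_bouts, replace = TRUE),
    onset_min = sort(sample(seq(400, 20000, by = 5), n_bouts)),
    duration = sample(10:30, n_bouts, replace = TRUE)
  )
  for (k in seq_along(vars)) {
    pw[[vars[k]]] <- stats::rnorm(n_bouts, mu[k], sdv[k])
  }
  cand <- list()
  for (i in seq_len(n_bouts)) {
    m <- n_cand %||% sample(0:30, 1)
    cc <- data.frame(
      time_min = sort(sample(seq(0, 40000, by = 5), m)),
      duration = rep(pw$duration[i], m)
    )
    for (k in seq_along(vars)) {
      cc[[vars[k]]] <- pw[[vars[k]]][i] + stats::rnorm(m, 0, sdv[k] * 0.6)
    }
    cand[[pw$window_id[i]]] <- cc
  }
  wts <- abs(stats::rnorm(4)) + 0.05
  wts <- wts / sum(wts)
  std <- data.frame(variable = vars, mean = mu, sd = sdv)
  weights <- structure(list(
    variables = vars, weights = stats::setNames(wts, vars),
    calipers = stats::setNames(0.2 * sdv * stats::runif(4, 0.8, 3), vars),
    standardizers = std, screening_p = NULL, fallback = FALSE
  ), class = "match_weights")
  list(pa_windows = pw, candidates = cand, weights = weights)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
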