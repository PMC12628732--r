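#' Select matching variables, weights and calipers
#'
#' Implements the outcome-oriented variable-selection step of the matching
#' design. The four physiologically central covariates — starting glucose,
#' rate of change, insulin on board and prior-hour CV — are always carried as
#' matching variables: control periods are drawn from anywhere in the
#' participant's record (before or after the bout, any time of day), and
#' duration equality is enforced structurally by the candidate enumeration,
#' so neither clock time nor duration is a matching variable by default
#' (`extra_vars` can add screened extras). Univariate Pearson correlations of
#' each candidate variable with the PA-window glucose change are computed as
#' the screening step; a multivariable linear mixed model of the outcome on
#' the z-scored matching variables with a participant random intercept then
#' supplies the weights, proportional to the absolute standardized
#' coefficients and normalized to sum 1. When no core variable survives the
#' univariate screen (e.g. a pure-noise outcome), weights fall back to equal
#' over the four core variables. Calipers are `caliper_factor` times the
#' pooled SD of each variable over PA windows and control candidates.
#'
#' @param pa_windows eligible PA windows (rows of [eligible_bouts()] output,
#'   with `participant_id`).
#' @param outcomes numeric vector of glucose changes, one per PA window.
#' @param candidate_pool data frame of (deduplicated) control candidates with
#'   the same covariate columns; used for the pooled standardizers and
#'   calipers.
#' @param core_vars always-included matching variables.
#' @param extra_vars additional variables admitted to matching when their
#'   univariate screen is significant.
#' @param screen_vars variables screened for reporting (and for the
#'   multivariable outcome model) without entering the matching distance.
#' @param alpha screening significance level.
#' @param caliper_factor caliper width as a multiple of the pooled SD.
#' @return an object of class `match_weights`: variables, weights, calipers,
#'   standardizers (pooled mean/SD), screening p-values and a `fallback` flag.
#' @export
select_weights <- function(pa_windows, outcomes, candidate_pool,
                           core_vars = c("start_glucose", "roc", "cv_pre",
                                         "iob"),
                           extra_vars = character(0),
                           screen_vars = c("clock_time", "duration"),
                           alpha = 0.05, caliper_factor = 0.2) {
  all_vars <- c(core_vars, extra_vars)
  screen_all <- unique(c(all_vars, screen_vars))
  ok <- stats::complete.cases(pa_windows[, all_vars, drop = FALSE]) &
    !is.na(outcomes)
  pw <- pa_windows[ok, , drop = FALSE]
  y <- outcomes[ok]
  if (nrow(pw) < 3L) stop("need at least 3 PA windows with outcomes")

  pvals <- vapply(intersect(screen_all, names(pw)), function(v) {
    x <- pw[[v]]
    if (stats::sd(x) == 0) return(1)
    stats::cor.test(x, y)$p.value
  }, numeric(1))
  screened <- names(pvals)[pvals < alpha]

  pooled <- rbind(pw[, all_vars, drop = FALSE],
                  candidate_pool[, all_vars, drop = FALSE])
  std <- data.frame(
    variable = all_vars,
    mean = vapply(all_vars, function(v) mean(pooled[[v]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(all_vars, function(v) stats::sd(pooled[[v]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL
  )

  variables <- unique(c(core_vars, intersect(extra_vars, screened)))
  # variables without spread cannot be standardized or matched on
  degenerate <- std$variable[is.na(std$sd) | std$sd <= 0]
  variables <- setdiff(variables, degenerate)

  fallback <- !any(core_vars %in% screened)
  if (fallback) {
    variables <- setdiff(core_vars, degenerate)
    w <- rep(1 / length(variables), length(variables))
    names(w) <- variables
  } else {
    z <- as.data.frame(lapply(variables, function(v) {
      (pw[[v]] - std$mean[std$variable == v]) / std$sd[std$variable == v]
    }))
    names(z) <- variables
    z$..y <- y
    z$..pid <- pw$participant_id
    fit <- tryCatch(
      lme4::lmer(stats::reformulate(c(variables, "(1 | ..pid)"),
                                    response = "..y"),
                 data = z, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")),
      error = function(e) NULL)
    coefs <- if (is.null(fit)) {
      stats::coef(stats::lm(stats::reformulate(variables, "..y"), data = z))
    } else {
      lme4::fixef(fit)
    }
    coefs <- coefs[variables]
    w <- abs(coefs)
    if (sum(w) == 0) w[] <- 1
    w <- w / sum(w)
  }

  std_use <- std[std$variable %in% variables, , drop = FALSE]
  calipers <- caliper_factor * std_use$sd
  names(calipers) <- std_use$variable
  structure(list(variables = variables, weights = w[variables],
                 calipers = calipers[variables],
                 standardizers = std_use, screening_p = pvals,
                 fallback = fallback),
            class = "match_weights")
}

#' @export
print.match_weights <- function(x, ...) {
  cat("<match_weights>", if (x$fallback) "(fallback: equal weights)" else "",
      "\n")
  for (v in x$variables) {
    cat(sprintf("  %-14s weight %.3f  caliper %.4g\n", v, x$weights[[v]],
                x$calipers[[v]]))
  }
  invisible(x)
}

#' Within-subject weighted kNN matching with calipers
#'
#' Pairs each PA window with its nearest same-participant control candidate in
#' weighted z-scored covariate space. Candidates violating any per-variable
#' caliper are inadmissible. Selection is without replacement within
#' participant: a chosen control window, extended by the guard band, becomes
#' unavailable to later bouts. Bouts are processed best-first (globally
#' smallest current best distance first) so the result does not depend on
#' input row order; distance ties resolve to the earlier-onset candidate, then
#' lexicographic order. Bouts with no admissible candidate are dropped with
#' reason `"insufficient_match_quality"`.
#'
#' @param pa_windows eligible PA windows with columns `window_id`,
#'   `participant_id`, `onset_min`, `duration` and the matching covariates.
#' @param candidates named list (by `window_id`) of candidate data frames as
#'   returned by [control_candidates()].
#' @param weights a [select_weights()] result.
#' @param seed unused (matching is fully deterministic); retained for
#'   interface uniformity across stages.
#' @param guard minimum separation in minutes between selected control windows
#'   of the same participant.
#' @return list with `pairs` (one row per matched pair: ids, onsets, duration,
#'   weighted distance and per-variable absolute gaps) and `dropped` (window
#'   ids with reasons).
#' @export
knn_match <- function(pa_windows, candidates, weights, seed = NULL,
                      guard = 40) {
  vars <- weights$variables
  w <- as.numeric(weights$weights[vars])
  cal <- as.numeric(weights$calipers[vars])
  sds <- weights$standardizers$sd[match(vars, weights$standardizers$variable)]

  pairs <- list(); dropped <- list()
  for (pid in unique(pa_windows$participant_id)) {
    rows <- which(pa_windows$participant_id == pid)
    res <- .match_participant(pa_windows[rows, , drop = FALSE], candidates,
                              vars, w, cal, sds, guard)
    pairs[[pid]] <- res$pairs
    dropped[[pid]] <- res$dropped
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  dropped <- do.call(rbind, dropped[!vapply(dropped, is.null, logical(1))])
  if (is.null(pairs)) pairs <- .empty_pairs(vars)
  if (is.null(dropped)) {
    dropped <- data.frame(window_id = character(0), reason = character(0))
  }
  rownames(pairs) <- NULL; rownames(dropped) <- NULL
  pairs <- pairs[order(pairs$participant_id, pairs$pa_onset_min), ,
                 drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs$pair_id <- sprintf("pair%05d", seq_len(nrow(pairs)))
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, dropped = dropped)
}

#' @keywords internal
.empty_pairs <- function(vars) {
  base <- data.frame(pair_id = character(0), window_id = character(0),
                     participant_id = character(0), pa_onset_min = numeric(0),
                     control_onset_min = numeric(0), duration = numeric(0),
                     distance = numeric(0))
  for (v in vars) base[[paste0("gap_", v)]] <- numeric(0)
  base
}

# Best-first greedy matching for one participant.
#' @keywords internal
.match_participant <- function(pw, candidates, vars, w, cal, sds, guard) {
  n <- nrow(pw)
  cand <- lapply(pw$window_id, function(id) {
    cc <- candidates[[id]]
    if (is.null(cc)) cc <- data.frame()
    cc
  })
  # per-bout caliper admissibility and weighted distances, computed once
  pre <- lapply(seq_len(n), function(i) {
    cc <- cand[[i]]
    m <- NROW(cc)
    if (m == 0L) return(list(ok = logical(0)))
    ok <- rep(TRUE, m)
    d2 <- numeric(m)
    gaps <- matrix(0, m, length(vars), dimnames = list(NULL, vars))
    for (j in seq_along(vars)) {
      gp <- abs(cc[[vars[j]]] - pw[[vars[j]]][i])
      ok <- ok & gp <= cal[j]
      d2 <- d2 + w[j] * (gp / sds[j])^2
      gaps[, j] <- gp
    }
    list(ok = ok, d = sqrt(d2), gaps = gaps, onset = cc$time_min,
         dur = cc$duration)
  })
  assigned <- rep(FALSE, n)
  blocked <- matrix(numeric(0), ncol = 2)   # [start, end] of taken windows
  out <- list(); drop_ids <- character(0)

  best_for <- function(i) {
    p <- pre[[i]]
    admissible <- p$ok
    if (!any(admissible)) return(NULL)
    if (nrow(blocked) > 0L) {
      for (k in seq_len(nrow(blocked))) {
        admissible <- admissible &
          !(p$onset < blocked[k, 2] + guard &
              p$onset + p$dur > blocked[k, 1] - guard)
      }
      if (!any(admissible)) return(NULL)
    }
    d <- p$d
    d[!admissible] <- Inf
    ord <- order(d, p$onset)
    j <- ord[1]
    list(j = j, d = d[j], gaps = p$gaps[j, ], onset = p$onset[j])
  }

  while (any(!assigned)) {
    open <- which(!assigned)
    bests <- lapply(open, best_for)
    has <- !vapply(bests, is.null, logical(1))
    if (!any(has)) {
      drop_ids <- c(drop_ids, pw$window_id[open])
      break
    }
    dists <- vapply(bests[has], `[[`, numeric(1), "d")
    onsets <- pw$onset_min[open[has]]
    pick <- order(dists, onsets)[1]
    i <- open[has][pick]
    b <- bests[has][[pick]]
    cc <- cand[[i]]
    row <- data.frame(pair_id = NA_character_, window_id = pw$window_id[i],
                      participant_id = pw$participant_id[i],
                      pa_onset_min = pw$onset_min[i],
                      control_onset_min = b$onset,
                      duration = pw$duration[i], distance = b$d)
    for (k in seq_along(vars)) row[[paste0("gap_", vars[k])]] <- b$gaps[k]
    out[[length(out) + 1L]] <- row
    assigned[i] <- TRUE
    blocked <- rbind(blocked, c(b$onset, b$onset + pw$duration[i]))
  }
  list(pairs = if (length(out)) do.call(rbind, out) else NULL,
       dropped = if (length(drop_ids)) {
         data.frame(window_id = drop_ids,
                    reason = "insufficient_match_quality")
       } else NULL)
}

#' Standardized mean difference
#'
#' `(mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)`. With zero pooled
#' variance the SMD is 0 when the means agree and `Inf` otherwise.
#'
#' @param x,y numeric samples (e.g. a covariate over PA and control windows).
#' @return dimensionless SMD.
#' @export
smd <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  vx <- if (length(x) > 1L) stats::var(x) else 0
  vy <- if (length(y) > 1L) stats::var(y) else 0
  pooled <- sqrt((vx + vy) / 2)
  dm <- mean(x) - mean(y)
  if (pooled == 0) {
    if (dm == 0) 0 else Inf
  } else {
    dm / pooled
  }
}

#' Covariate balance before and after matching
#'
#' Per-variable standardized mean differences comparing eligible PA windows
#' against the pre-match candidate pool (before) and matched PA windows
#' against their selected controls (after), plus matched/dropped counts.
#' Values below 0.1 in absolute value indicate acceptable balance.
#'
#' @param match_result result of [knn_match()].
#' @param pa_windows all eligible PA windows.
#' @param candidate_pool deduplicated candidate windows.
#' @param control_windows matched control windows with covariates (one row per
#'   pair, aligned with `match_result$pairs`).
#' @param variables covariates to report (defaults to the four matching
#'   variables).
#' @return list of class `balance_report` with `smd` (variable, before,
#'   after), `n_matched`, `n_dropped`.
#' @export
balance_report <- function(match_result, pa_windows, candidate_pool,
                           control_windows,
                           variables = c("start_glucose", "roc", "cv_pre",
                                         "iob")) {
  pairs <- match_result$pairs
  n_matched <- nrow(pairs)
  n_dropped <- nrow(match_result$dropped)
  matched_pa <- pa_windows[match(pairs$window_id, pa_windows$window_id), ,
                           drop = FALSE]
  tab <- data.frame(variable = variables, before = NA_real_,
                    after = NA_real_)
  for (k in seq_along(variables)) {
    v <- variables[k]
    tab$before[k] <- smd(pa_windows[[v]], candidate_pool[[v]])
    if (n_matched > 0L) {
      tab$after[k] <- smd(matched_pa[[v]], control_windows[[v]])
    }
  }
  structure(list(smd = tab, n_matched = n_matched, n_dropped = n_dropped),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> %d matched, %d dropped\n", x$n_matched,
              x$n_dropped))
  print(x$smd, row.names = FALSE)
  invisible(x)
}
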