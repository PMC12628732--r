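#' Three-level linear mixed model of the differential glucose change
#'
#' Fits `delta_glucose ~ condition * (centred covariates) + (1 | participant)
#' + (1 | pair)`: observations (one per window) are nested in matched pairs,
#' which are nested in participants. Continuous covariates — starting glucose,
#' rate of change, prior-hour CV, insulin on board, duration, clock time, age,
#' BMI, HbA1c — are centred at their sample means so the `condition` main
#' effect is the average differential effect of PA over matched non-PA
#' periods. Quadratic (and, where a quadratic is retained, cubic) terms of the
#' event-level covariates are tested by single-term Wald tests at
#' `poly_alpha` and kept only when significant. Inference is Wald: 95% CIs as
#' estimate ± 1.96 SE, two-sided normal p-values.
#'
#' When the full random structure fails to converge the model is refitted
#' without the pair intercept and flagged.
#'
#' @param outcomes output of [build_outcomes()] (or [sensitivity_filter()]).
#' @param covariates event-level covariate names entering main effects and
#'   condition interactions.
#' @param profile_covariates participant-level covariates treated the same
#'   way.
#' @param test_poly test and retain quadratic/cubic terms.
#' @param poly_alpha significance level for the polynomial-term tests.
#' @return object of class `glyco_effect_model`: `fixed` (term, estimate, se,
#'   ci_lo, ci_hi, p), `moderators` (the condition interactions on the
#'   reporting scales of [sim_config()]), variance components, counts,
#'   centring constants, covariate support quantiles, the retained polynomial
#'   terms and the underlying `lme4` fit.
#' @export
fit_primary_model <- function(outcomes,
                              covariates = c("start_glucose", "roc", "cv_pre",
                                             "iob", "duration", "clock_time"),
                              profile_covariates = c("age", "bmi", "hba1c"),
                              test_poly = TRUE, poly_alpha = 0.05) {
  dat <- outcomes[!is.na(outcomes$delta_glucose), , drop = FALSE]
  if (anyDuplicated(paste(dat$pair_id, dat$condition))) {
    stop("duplicated pair_id x condition rows; each pair must contribute one PA and one control observation")
  }
  all_cov <- c(covariates, profile_covariates)
  centres <- vapply(all_cov, function(v) mean(dat[[v]], na.rm = TRUE),
                    numeric(1))
  for (v in all_cov) dat[[paste0("c_", v)]] <- dat[[v]] - centres[[v]]
  dat$pa <- as.integer(dat$condition == "PA")

  cterms <- paste0("c_", all_cov)
  base_rhs <- c(sprintf("pa * (%s)", paste(cterms, collapse = " + ")))

  fit_once <- function(extra, drop_pair = FALSE) {
    re <- if (drop_pair) "(1 | participant_id)" else
      "(1 | participant_id) + (1 | pair_id)"
    f <- stats::reformulate(c(base_rhs, extra, re),
                            response = "delta_glucose")
    lme4::lmer(f, data = dat, REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore",
                                           check.scaleX = "ignore"))
  }
  safe_fit <- function(extra) {
    fit <- tryCatch(fit_once(extra), error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(fit_once(extra, drop_pair = TRUE),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      attr(fit, "simplified") <- TRUE
    }
    fit
  }

  retained_poly <- character(0)
  if (test_poly) {
    sq <- sprintf("I(c_%s^2)", covariates)
    aug <- safe_fit(sq)
    if (!is.null(aug)) {
      keep_sq <- sq[.wald_p(aug)[sq] < poly_alpha]
      keep_sq <- keep_sq[!is.na(keep_sq)]
      retained_poly <- keep_sq
      if (length(keep_sq) > 0L) {
        cu <- sub("\\^2", "^3", keep_sq)
        aug3 <- safe_fit(c(keep_sq, cu))
        if (!is.null(aug3)) {
          keep_cu <- cu[.wald_p(aug3)[cu] < poly_alpha]
          retained_poly <- c(keep_sq, keep_cu[!is.na(keep_cu)])
        }
      }
    }
  }

  fit <- safe_fit(retained_poly)
  if (is.null(fit)) stop("primary mixed model failed to converge")
  simplified <- isTRUE(attr(fit, "simplified"))

  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  fixed <- data.frame(
    term = names(est), estimate = as.numeric(est), se = as.numeric(se),
    ci_lo = as.numeric(est - 1.96 * se), ci_hi = as.numeric(est + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)), row.names = NULL
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  support <- lapply(c("start_glucose", "roc"), function(v) {
    stats::quantile(dat[[v]], c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  })
  names(support) <- c("start_glucose", "roc")

  res <- structure(list(
    fixed = fixed,
    moderators = .moderator_table(fixed),
    varcomp = vc[, c("grp", "vcov")],
    n_obs = nrow(dat), n_pairs = length(unique(dat$pair_id)),
    n_participants = length(unique(dat$participant_id)),
    centres = centres, covariates = covariates,
    profile_covariates = profile_covariates,
    retained_poly = retained_poly, support = support,
    converged = TRUE, simplified = simplified, fit = fit
  ), class = "glyco_effect_model")
  res
}

# Wald p-values for the fixed effects of a merMod.
#' @keywords internal
.wald_p <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  p <- 2 * stats::pnorm(-abs(est / se))
  names(p) <- names(est)
  p
}

# Condition-interaction coefficients re-expressed on the reporting scales
# used throughout the package: per 0.1 mmol/L/min faster onset decline, per
# 1 mmol/L lower starting glucose, per 1% CV, per minute, per 0.1 U/kg IOB,
# per year, per 1 kg/m2 lower BMI.
#' @keywords internal
.moderator_table <- function(fixed) {
  map <- data.frame(
    moderator = c("roc_decline", "start_lower", "cv", "duration", "iob",
                  "age", "bmi_lower"),
    term = c("pa:c_roc", "pa:c_start_glucose", "pa:c_cv_pre",
             "pa:c_duration", "pa:c_iob", "pa:c_age", "pa:c_bmi"),
    scale = c(-0.1, -1, 1, 1, 0.1, 1, -1)
  )
  idx <- match(map$term, fixed$term)
  keep <- !is.na(idx)
  map <- map[keep, , drop = FALSE]; idx <- idx[keep]
  s <- map$scale
  est <- fixed$estimate[idx] * s
  se <- fixed$se[idx] * abs(s)
  data.frame(
    moderator = map$moderator, estimate = est, se = se,
    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
    p = fixed$p[idx], row.names = NULL
  )
}

#' @export
print.glyco_effect_model <- function(x, ...) {
  cond <- x$fixed[x$fixed$term == "pa", ]
  cat("<glyco_effect_model>\n")
  cat(sprintf("  %d observations, %d pairs, %d participants%s\n", x$n_obs,
              x$n_pairs, x$n_participants,
              if (x$simplified) " (pair intercept dropped)" else ""))
  cat(sprintf(
    "  PA vs control: %.2f mmol/L [95%% CI %.2f, %.2f], p %s\n",
    cond$estimate, cond$ci_lo, cond$ci_hi, format.pval(cond$p, digits = 2)))
  cat("  moderators (per reporting unit):\n")
  m <- x$moderators
  for (i in seq_len(nrow(m))) {
    cat(sprintf("    %-12s %+.3f [%.3f, %.3f]\n", m$moderator[i],
                m$estimate[i], m$ci_lo[i], m$ci_hi[i]))
  }
  invisible(x)
}

#' Condition effect of a fitted primary model
#'
#' @param model a `glyco_effect_model`.
#' @return one-row data frame with estimate, 95% CI and p for the PA vs
#'   matched non-PA contrast at the covariate means.
#' @export
condition_effect <- function(model) {
  model$fixed[model$fixed$term == "pa",
              c("estimate", "se", "ci_lo", "ci_hi", "p")]
}

#' Logistic mixed model of hypoglycaemia risk
#'
#' Models the hypoglycaemia indicator on condition, starting glucose,
#' duration, age, BMI, rate of change and insulin modality with a participant
#' random intercept, reporting odds ratios with Wald CIs. With sparse or
#' quasi-separated events (the usual situation: hypoglycaemia after short PA
#' is rare) the mixed fit is replaced by Firth-penalized logistic regression
#' on the fixed effects, flagged in the result. With zero events a structured
#' "no events" result is returned rather than an error.
#'
#' @param outcomes output of [build_outcomes()].
#' @param min_events_mixed minimum events per condition arm for the mixed fit.
#' @return object of class `glyco_hypo_model`: `fixed` (log-odds scale with
#'   `or`, `or_lo`, `or_hi`), `n_events`, `method`
#'   (`"glmer"`/`"firth"`/`"none"`) and `converged`.
#' @export
fit_hypo_model <- function(outcomes, min_events_mixed = 5L) {
  dat <- outcomes[!is.na(outcomes$hypo), , drop = FALSE]
  n_events <- sum(dat$hypo)
  if (n_events == 0L) {
    return(structure(list(fixed = NULL, n_events = 0L, method = "none",
                          converged = NA), class = "glyco_hypo_model"))
  }
  covs <- c("start_glucose", "duration", "age", "bmi", "roc")
  for (v in covs) dat[[paste0("c_", v)]] <- dat[[v]] - mean(dat[[v]])
  dat$pa <- as.integer(dat$condition == "PA")
  dat$modality <- factor(dat$modality)
  rhs <- c("pa", paste0("c_", covs),
           if (nlevels(dat$modality) > 1L) "modality")

  events_by_arm <- tapply(dat$hypo, dat$pa, sum)
  sparse <- length(events_by_arm) < 2L || any(events_by_arm <
                                                min_events_mixed)
  fit <- NULL
  if (!sparse) {
    fit <- tryCatch(
      suppressMessages(lme4::glmer(
        stats::reformulate(c(rhs, "(1 | participant_id)"), "hypo"),
        data = dat, family = stats::binomial,
        control = lme4::glmerControl(calc.derivs = FALSE, check.conv.singular = "ignore"))),
      error = function(e) NULL, warning = function(w) NULL)
  }
  if (!is.null(fit)) {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    method <- "glmer"
  } else {
    X <- stats::model.matrix(stats::reformulate(rhs), dat)
    fl <- firth_logistic(X, dat$hypo)
    est <- fl$coef; se <- fl$se
    method <- "firth"
  }
  fixed <- data.frame(
    term = names(est), estimate = as.numeric(est), se = as.numeric(se),
    or = exp(as.numeric(est)),
    or_lo = exp(as.numeric(est - 1.96 * se)),
    or_hi = exp(as.numeric(est + 1.96 * se)),
    p = 2 * stats::pnorm(-abs(as.numeric(est) / as.numeric(se))),
    row.names = NULL
  )
  structure(list(fixed = fixed, n_events = n_events, method = method,
                 converged = TRUE), class = "glyco_hypo_model")
}

#' @export
print.glyco_hypo_model <- function(x, ...) {
  cat(sprintf("<glyco_hypo_model> %d events, method %s\n", x$n_events,
              x$method))
  if (!is.null(x$fixed)) {
    pa <- x$fixed[x$fixed$term == "pa", ]
    if (nrow(pa)) {
      cat(sprintf("  PA log-odds %+.2f (OR %.1f [%.1f, %.1f])\n",
                  pa$estimate, pa$or, pa$or_lo, pa$or_hi))
    }
  }
  invisible(x)
}

#' Firth-penalized logistic regression
#'
#' Maximum penalized likelihood with Jeffreys-prior penalty, the standard
#' remedy for separation and rare events: the score is corrected by the hat
#' values, guaranteeing finite estimates even under complete separation.
#' Newton iterations on `X' (y - p + h (1/2 - p)) = 0` with Wald SEs from the
#' penalized information matrix.
#'
#' @param X model matrix (including intercept).
#' @param y 0/1 response.
#' @param max_iter,tol iteration controls.
#' @return list with `coef`, `se`, `iter`, `converged`.
#' @export
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) MASS_ginv(info))
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% score)
    # dampen huge steps for stability under separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(tryCatch(solve(info), error = function(e) MASS_ginv(info))))
  names(beta) <- names(se) <- colnames(X)
  list(coef = beta, se = se, iter = it, converged = it < max_iter)
}

# Moore-Penrose fallback without adding a MASS dependency at runtime.
#' @keywords internal
MASS_ginv <- function(m) {
  s <- svd(m)
  pos <- s$d > max(1e-12 * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Sensitivity analysis: refit after excluding treated PA windows
#'
#' Applies [sensitivity_filter()] and refits the primary model on the
#' remaining pairs.
#'
#' @inheritParams fit_primary_model
#' @param ... passed to [fit_primary_model()].
#' @return list with the filtered `outcomes`, the refitted `model` (`NULL`
#'   when the reduced sample cannot support the refit),
#'   `n_excluded_pairs` and `n_retained_pairs`.
#' @export
sensitivity_analysis <- function(outcomes, ...) {
  filtered <- sensitivity_filter(outcomes)
  model <- tryCatch(fit_primary_model(filtered, ...),
                    error = function(e) NULL)
  list(outcomes = filtered, model = model,
       n_excluded_pairs = attr(filtered, "n_excluded_pairs"),
       n_retained_pairs = length(unique(filtered$pair_id)))
}
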