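test_that("glucose change reads both anchors with the nearest-reading rule", {
  expect_equal(glucose_change(flat_trace(9, 100),
                              list(onset = 100, duration = 20)), 0)
  tr <- flat_trace(12, 100)
  tr$glucose[tr$time == 140] <- 9.8           # onset 100 + dur 20 + tail 20
  expect_equal(glucose_change(tr, list(onset = 100, duration = 20)), -2.2)
  trg <- tr[tr$time < 95 | tr$time > 105, ]   # onset anchor missing
  expect_true(is.na(glucose_change(trg, list(onset = 100, duration = 20))))
})

test_that("hypoglycaemia detection is strict at 3.9 and gap-aware", {
  tr <- flat_trace(10, 100)
  tr$glucose[30] <- 3.9
  expect_false(detect_hypo(tr, list(onset = tr$time[25], duration = 20)))
  tr$glucose[30] <- 3.8999
  expect_true(detect_hypo(tr, list(onset = tr$time[25], duration = 20)))
  # single low reading at end + 15
  tr2 <- flat_trace(10, 100)
  tr2$glucose[tr2$time == 135] <- 3.8
  expect_true(detect_hypo(tr2, list(onset = 100, duration = 20)))
  expect_false(detect_hypo(flat_trace(12, 100),
                           list(onset = 100, duration = 20)))
  # a >10-min coverage gap inside the interval is indeterminate
  tr3 <- flat_trace(10, 100)
  tr3 <- tr3[tr3$time < 110 | tr3$time > 125, ]
  expect_true(is.na(detect_hypo(tr3, list(onset = 100, duration = 20))))
})

test_that("duplicated pairs are rejected by the primary model", {
  ch <- generate_cohort(small_config(), seed = 61)
  res <- analyze_cohort(ch, fit_models = FALSE)
  out <- build_outcomes(res$pairs, res$eligible, res$control_covariates, ch)
  expect_error(fit_primary_model(rbind(out, out)), "duplicated pair_id")
})

test_that("the primary model recovers a known effect on a small cohort", {
  ch <- generate_cohort(small_config(n_participants = 25), seed = 62)
  res <- analyze_cohort(ch)
  m <- res$primary_model
  expect_true(m$converged)
  expect_equal(m$n_obs, 2 * m$n_pairs)
  ce <- condition_effect(m)
  expect_lt(ce$ci_lo, ce$estimate); expect_gt(ce$ci_hi, ce$estimate)
  expect_lt(abs(ce$estimate - ch$config$effect_intercept), 0.6)
  vc <- m$varcomp
  expect_true(all(vc$vcov >= 0))
})

test_that("with zero true effect the estimated condition effect is near 0", {
  ch <- generate_cohort(null_sim_config(n_participants = 40, n_days = 14),
                        seed = 63)
  res <- analyze_cohort(ch)
  ce <- condition_effect(res$primary_model)
  # within Monte-Carlo error of 0, far from the calibrated -1.9
  expect_lt(abs(ce$estimate), 3 * ce$se)
  expect_gt(abs(ce$estimate - (-1.9)) / ce$se, 3)
})

test_that("sensitivity filtering removes exactly the treated PA pairs", {
  base <- data.frame(
    pair_id = rep(sprintf("p%02d", 1:10), each = 2),
    condition = rep(c("PA", "control"), 10),
    delta_glucose = stats::rnorm(20),
    insulin_in_window = FALSE, carb_in_window = FALSE
  )
  expect_equal(sensitivity_filter(base)$pair_id, base$pair_id)
  flagged <- base
  flagged$insulin_in_window[flagged$condition == "PA" &
                              flagged$pair_id %in% c("p01", "p04")] <- TRUE
  flagged$carb_in_window[flagged$condition == "PA" &
                           flagged$pair_id == "p07"] <- TRUE
  # intake in a control window alone must not drop the pair
  flagged$carb_in_window[flagged$condition == "control" &
                           flagged$pair_id == "p09"] <- TRUE
  f <- sensitivity_filter(flagged)
  expect_equal(length(unique(f$pair_id)), 7)
  expect_equal(attr(f, "n_excluded_pairs"), 3)
  expect_false(any(c("p01", "p04", "p07") %in% f$pair_id))
})

test_that("drop-triggered rescue carbs attenuate the filtered estimate", {
  # a cohort whose only carbohydrate intake is rescue treatment of rapid
  # drops: excluding treated bouts removes the largest drops
  cfg <- sim_config(n_participants = 40, n_days = 14, meal_rate = 0,
                    bolus_prob = 0, correction_rate = 0,
                    effect_intercept = -3, effect_sd_within = 2.5,
                    rescue_enabled = TRUE, rescue_threshold = 6.5,
                    rescue_prob = 1)
  ch <- generate_cohort(cfg, seed = 64)
  res <- analyze_cohort(ch, test_poly = FALSE)
  expect_gt(res$sensitivity$n_excluded_pairs, 5)
  full <- condition_effect(res$primary_model)$estimate
  filt <- condition_effect(res$sensitivity$model)$estimate
  expect_gt(filt, full)   # attenuated: less negative after exclusion
})

test_that("Firth regression matches ML logistic where the MLE is stable", {
  set.seed(65)
  n <- 4000
  x <- stats::rnorm(n)
  p <- stats::plogis(-1 + 0.8 * x)
  y <- stats::rbinom(n, 1, p)
  X <- cbind(1, x)
  fl <- firth_logistic(X, y)
  ml <- stats::glm(y ~ x, family = stats::binomial)
  expect_true(fl$converged)
  expect_equal(unname(fl$coef), unname(stats::coef(ml)), tolerance = 0.02)
  expect_equal(unname(fl$se),
               unname(summary(ml)$coefficients[, 2]), tolerance = 0.02)
})

test_that("Firth regression stays finite under complete separation", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- c(rep(0, 20), rep(1, 20))
  fl <- firth_logistic(cbind(1, x), y)
  expect_true(all(is.finite(fl$coef)))
  expect_true(all(is.finite(fl$se)))
})

test_that("the hypoglycaemia model handles sparse and empty event patterns", {
  ch <- generate_cohort(small_config(), seed = 66)
  res <- analyze_cohort(ch, fit_models = FALSE)
  out <- build_outcomes(res$pairs, res$eligible, res$control_covariates, ch)

  # zero events: structured result, no crash
  none <- out; none$hypo <- FALSE
  m0 <- fit_hypo_model(none)
  expect_equal(m0$method, "none"); expect_equal(m0$n_events, 0L)

  # all events in the PA arm (quasi-separation): finite penalized estimates
  sep <- out; sep$hypo <- sep$condition == "PA" & sep$start_glucose <
    stats::quantile(sep$start_glucose, 0.1)
  m1 <- fit_hypo_model(sep)
  expect_equal(m1$method, "firth")
  expect_true(all(is.finite(m1$fixed$estimate)))
  pa_row <- m1$fixed[m1$fixed$term == "pa", ]
  expect_gt(pa_row$or, 1)
  # events were concentrated at low starting glucose: protective OR < 1
  sg <- m1$fixed[m1$fixed$term == "c_start_glucose", ]
  expect_lt(sg$or, 1)
})

test_that("odds ratios exponentiate the log-odds estimates", {
  ch <- generate_cohort(small_config(), seed = 67)
  res <- analyze_cohort(ch, fit_models = FALSE)
  out <- build_outcomes(res$pairs, res$eligible, res$control_covariates, ch)
  set.seed(1)
  out$hypo <- stats::runif(nrow(out)) < 0.05
  m <- fit_hypo_model(out)
  expect_equal(m$fixed$or, exp(m$fixed$estimate))
  expect_equal(m$fixed$or_lo, exp(m$fixed$estimate - 1.96 * m$fixed$se))
})
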