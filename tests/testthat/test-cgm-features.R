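test_that("starting glucose uses the nearest reading within tolerance", {
  tr <- make_trace(c(10, 11.7, 12), start = 0)      # readings at 0, 5, 10
  expect_equal(starting_glucose(tr, 5), 11.7)       # exact hit
  tr2 <- data.frame(time = c(8, 14), glucose = c(10.0, 12.0))
  expect_equal(starting_glucose(tr2, 10), 10.0)     # nearest rule (-2 vs +4)
  tr3 <- data.frame(time = c(0, 20), glucose = c(9, 9))
  expect_true(is.na(starting_glucose(tr3, 10)))     # nothing within 2.5 min
})

test_that("rate of change averages the three prior 5-min slopes", {
  tr <- make_trace(rep(8, 50))
  expect_equal(roc_at(tr, 100), 0)
  tr <- make_trace(c(10.0, 10.5, 11.0, 11.5), start = 0)
  expect_equal(roc_at(tr, 15), 0.1)                 # (11.5 - 10.0) / 15
  tr <- make_trace(c(13.0, 12.4, 11.8, 11.2), start = 0)
  expect_equal(roc_at(tr, 15), -0.12)               # (11.2 - 13.0) / 15
  # missing middle anchor: drop the reading at t0 - 5
  tr <- data.frame(time = c(0, 5, 15), glucose = c(13.0, 12.4, 11.2))
  expect_true(is.na(roc_at(tr, 15)))
})

test_that("rate of change telescopes on any gap-free grid", {
  set.seed(11)
  for (rep in 1:25) {
    g <- 8 + cumsum(stats::rnorm(60, 0, 0.4))
    tr <- make_trace(g)
    k <- sample(10:50, 1)
    t0 <- tr$time[k]
    expect_equal(roc_at(tr, t0), (g[k] - g[k - 3]) / 15, tolerance = 1e-12)
  }
})

test_that("prior-hour CV handles coverage thresholds", {
  tr <- make_trace(rep(10, 40))
  expect_equal(cv_prior_hour(tr, tr$time[20]), 0)
  # toy sparse window: {8, 10, 12} -> sd 2, mean 10 -> 20%
  tr2 <- data.frame(time = c(0, 25, 50), glucose = c(8, 10, 12))
  expect_equal(cv_prior_hour(tr2, 50, min_frac = 0), 20.0)
  # 9 of 12 expected readings computable, 8 of 12 missing
  g <- c(8, 9, 10, 11, 12, 11, 10, 9, 8, 9, 10, 11, 12)
  full <- make_trace(g)                             # t = 0..60
  keep9 <- full[c(1:8, 13), ]                       # 9 readings in window
  expect_false(is.na(cv_prior_hour(keep9, 60)))
  keep8 <- full[c(1:7, 13), ]                       # 8 readings
  expect_true(is.na(cv_prior_hour(keep8, 60)))
})

test_that("insulin on board follows the linear 4-h bolus decay", {
  expect_equal(iob_at(no_doses(), 80, 100), 0)
  d <- data.frame(time = 0, units = 4, kind = "bolus")
  expect_equal(iob_at(d, 80, 120), 0.025)           # 4 * 0.5 / 80
  d2 <- data.frame(time = c(120, 0), units = c(2, 1),
                   kind = c("bolus", "bolus"))
  expect_equal(iob_at(d2, 50, 180), 0.035)          # (2*.75 + 1*.25)/50
  basal <- data.frame(time = 0, units = 20, kind = "basal")
  expect_equal(iob_at(basal, 80, 60), 0)            # basal excluded
  future <- data.frame(time = 100, units = 5, kind = "bolus")
  expect_equal(iob_at(future, 80, 50), 0)           # dose after t ignored
  expect_equal(iob_at(d, 80, 240), 0)               # fully decayed at 240
})

test_that("IOB is bounded, non-negative and non-increasing between doses", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    d <- data.frame(time = sort(stats::runif(n, 0, 500)),
                    units = stats::runif(n, 0.5, 8),
                    kind = sample(c("bolus", "basal"), n, replace = TRUE))
    w <- stats::runif(1, 40, 100)
    ts <- seq(0, 800, by = 7)
    vals <- vapply(ts, function(t) iob_at(d, w, t), numeric(1))
    expect_true(all(vals >= 0))
    expect_true(all(vals <= sum(d$units[d$kind == "bolus"]) / w + 1e-12))
    between <- ts[-1][!vapply(ts[-1], function(t) {
      any(d$time > t - 7 & d$time <= t)
    }, logical(1))]
    idx <- match(between, ts)
    expect_true(all(vals[idx] <= vals[idx - 1] + 1e-12))
  }
})

test_that("glycaemic metrics partition time in range", {
  expect_equal(glycaemic_metrics(flat_trace(8))$tir, 100)
  m <- glycaemic_metrics(make_trace(c(3.0, 8.0, 12.0)))
  expect_equal(m$tbr, 100 / 3, tolerance = 1e-9)
  expect_equal(m$tir, 100 / 3, tolerance = 1e-9)
  expect_equal(m$tar, 100 / 3, tolerance = 1e-9)
  set.seed(4)
  m2 <- glycaemic_metrics(make_trace(stats::runif(500, 2.5, 20)))
  expect_equal(m2$tir + m2$tbr + m2$tar, 100, tolerance = 1e-9)
})

test_that("the vectorized covariate track equals the per-event functions", {
  ch <- generate_cohort(sim_config(n_participants = 1, n_days = 4,
                                   pa_per_participant = c(4L, 4L)),
                        seed = 8)
  tr <- data.frame(time = as.numeric(ch$cgm$time) / 60,
                   glucose = ch$cgm$glucose)
  tr$time <- tr$time - tr$time[1]
  doses <- data.frame(time = as.numeric(ch$doses$time) / 60 -
                        as.numeric(ch$cgm$time[1]) / 60,
                      units = ch$doses$units, kind = ch$doses$kind)
  w <- ch$profiles$weight[1]
  track <- glycomatch:::.covariate_track(tr, doses, w)
  idx <- seq(20, nrow(tr), by = 37)
  for (k in idx) {
    t0 <- tr$time[k]
    expect_equal(track$start_glucose[k], starting_glucose(tr, t0))
    expect_equal(track$roc[k], roc_at(tr, t0))
    expect_equal(track$cv_pre[k], cv_prior_hour(tr, t0), tolerance = 1e-8)
    expect_equal(track$iob[k], iob_at(doses, w, t0), tolerance = 1e-10)
  }
})

test_that("CGM availability counts readings against the expected cadence", {
  tr <- make_trace(rep(8, 100))
  expect_equal(cgm_availability(tr), 1)
  gap <- tr[-(30:59), ]
  expect_lt(cgm_availability(gap), 0.75)
  expect_gt(cgm_availability(gap), 0.65)
})

test_that("unit conversion is exact and invertible", {
  expect_equal(mmol_to_mgdl(10), 180.16)
  expect_equal(round(mmol_to_mgdl(3.9), 1), 70.3)
  x <- c(2.2, 5.5, 22.2)
  expect_equal(mgdl_to_mmol(mmol_to_mgdl(x)), x, tolerance = 1e-12)
})
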