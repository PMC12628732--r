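test_that("configuration invariants are enforced", {
  expect_error(sim_config(cgm_interval = 0), "cgm_interval")
  expect_error(sim_config(ou_sigma = -1), "SDs")
  expect_error(sim_config(pa_per_participant = c(5, 2)), "ordered")
  expect_error(sim_config(effect_slopes = c(roc_decline = 1)),
               "effect_slopes")
  # a single wear day cannot host many bouts with 5-h separation
  expect_error(sim_config(n_days = 1, pa_per_participant = c(8L, 8L)),
               "cannot host")
})

test_that("no-noise, no-effect configuration yields flat traces and zero truth", {
  cfg <- null_sim_config(n_participants = 3, n_days = 4, ou_sigma = 0,
                         sigma_noise = 0, meal_rate = 0, correction_rate = 0,
                         rescue_enabled = FALSE,
                         pa_per_participant = c(2L, 2L))
  ch <- generate_cohort(cfg, seed = 3)
  mu <- rep(ch$profiles$mu_glucose, each = nrow(ch$cgm) / 3)
  expect_equal(ch$cgm$glucose, mu, tolerance = 1e-12)
  expect_equal(ch$truth$delta, rep(0, nrow(ch$truth)))
})

test_that("identical seeds give identical cohorts", {
  cfg <- sim_config(n_participants = 4, n_days = 7)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$cgm$glucose, c$cgm$glucose))
})

test_that("bouts lie inside the CGM span, in daytime, separated by > 5 h", {
  ch <- generate_cohort(sim_config(n_participants = 8, n_days = 10),
                        seed = 9)
  expect_equal(nrow(ch$truth), nrow(ch$bouts))
  onset_min <- as.numeric(ch$bouts$onset) / 60 -
    as.numeric(ch$cgm$time[1]) / 60
  cgm_span <- range(as.numeric(ch$cgm$time) / 60 -
                      as.numeric(ch$cgm$time[1]) / 60)
  expect_true(all(onset_min >= cgm_span[1]))
  expect_true(all(onset_min + ch$bouts$duration + 20 <= cgm_span[2] + 2.5))
  clock <- onset_min %% 1440
  expect_true(all(clock >= 6 * 60))
  expect_true(all((clock + ch$bouts$duration) <= 23 * 60))
  expect_true(all(ch$bouts$duration >= 10 & ch$bouts$duration <= 30))
  for (pid in unique(ch$bouts$participant_id)) {
    b <- ch$bouts[ch$bouts$participant_id == pid, ]
    o <- sort(as.numeric(b$onset) / 60)
    d <- b$duration[order(as.numeric(b$onset))]
    if (length(o) > 1L) {
      gaps <- o[-1] - (o[-length(o)] + d[-length(d)])
      expect_true(all(gaps > 300))
    }
  }
})

test_that("mean realized effect over eligible bouts matches the intercept", {
  # >= 1000 eligible bouts; bout noise and moderator spread average out
  ch <- generate_cohort(sim_config(n_participants = 260, n_days = 14,
                                   pa_per_participant = c(13L, 13L)),
                        seed = 21)
  keep <- ch$truth$eligible_start
  d <- ch$truth$delta[keep]
  expect_gt(length(d), 1000)
  # the participant random effect clusters bouts, so use a cluster-level SE
  pmeans <- tapply(d, ch$truth$participant_id[keep], mean)
  se <- stats::sd(pmeans) / sqrt(length(pmeans))
  expect_lt(abs(mean(d) - ch$config$effect_intercept), 2 * se + 1e-12)
})

test_that("generated traces respect the sensor range and grid", {
  ch <- generate_cohort(sim_config(n_participants = 3, n_days = 5,
                                   pa_per_participant = c(5L, 5L)),
                        seed = 2)
  expect_true(all(ch$cgm$glucose >= 2.2 & ch$cgm$glucose <= 22.2))
  tm <- as.numeric(ch$cgm$time[ch$cgm$participant_id ==
                                 ch$profiles$participant_id[1]]) / 60
  expect_true(all(abs(diff(tm) - 5) < 1e-9))
})

test_that("descriptive calibration holds on a mid-size cohort", {
  ch <- generate_cohort(sim_config(n_participants = 100), seed = 5)
  gm <- glycaemic_metrics(ch$cgm)
  expect_gt(gm$cv, 28); expect_lt(gm$cv, 40)
  expect_gt(gm$mean, 7.7); expect_lt(gm$mean, 9.5)
  expect_gte(stats::median(ch$bouts$duration), 20)
  expect_lte(stats::median(ch$bouts$duration), 26)
})
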