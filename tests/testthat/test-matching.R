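test_that("standardized mean difference follows its definition", {
  x <- c(10, 11, 12)                       # mean 11, sd 1
  y <- c(9, 10, 11)                        # mean 10, sd 1
  expect_equal(smd(x, y), 1.0)
  expect_equal(smd(x, x), 0)
  expect_equal(smd(rep(5, 4), rep(5, 7)), 0)       # equal constant samples
  expect_identical(smd(rep(5, 4), rep(6, 3)), Inf) # zero variance, gap
  expect_error(smd(numeric(0), y), "non-empty")
})

test_that("weights are a normalized simplex over the matching variables", {
  set.seed(51)
  n <- 120
  pw <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:12), each = 10),
    start_glucose = stats::rnorm(n, 11.5, 1.3),
    roc = stats::rnorm(n, 0, 0.05), cv_pre = stats::rnorm(n, 20, 7),
    iob = abs(stats::rnorm(n, 0.02, 0.02)),
    clock_time = stats::runif(n, 360, 1380),
    duration = sample(10:30, n, replace = TRUE)
  )
  pool <- pw[sample(n, n, replace = TRUE), ]
  y <- -1 + 0.8 * pw$roc / 0.05 + stats::rnorm(n, 0, 0.1)
  w <- select_weights(pw, y, pool)
  expect_equal(sum(w$weights), 1)
  expect_true(all(w$weights >= 0))
  expect_true(all(w$calipers > 0))
  # outcome driven by ROC alone: ROC dominates the weights
  expect_gt(w$weights[["roc"]], 0.85)
  expect_false(w$fallback)
})

test_that("a pure-noise outcome falls back to equal weights over the four", {
  set.seed(52)
  n <- 60
  pw <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:6), each = 10),
    start_glucose = stats::rnorm(n, 11.5, 1.3),
    roc = stats::rnorm(n, 0, 0.05), cv_pre = stats::rnorm(n, 20, 7),
    iob = abs(stats::rnorm(n, 0.02, 0.02)),
    clock_time = stats::runif(n, 360, 1380),
    duration = sample(10:30, n, replace = TRUE)
  )
  w <- select_weights(pw, stats::rnorm(n), pw)
  expect_true(w$fallback)
  expect_equal(unname(w$weights),
               rep(0.25, 4))
  expect_setequal(w$variables, c("start_glucose", "roc", "cv_pre", "iob"))
})

test_that("kNN matching honours calipers and picks the nearest candidate", {
  inst <- local({set.seed(53); random_match_instance(n_bouts = 1,
                                                     n_cand = 5)})
  w <- inst$weights
  pw <- inst$pa_windows
  # shrink to a single decisive candidate inside all calipers
  cc <- inst$candidates[[pw$window_id[1]]]
  for (v in w$variables) cc[[v]] <- pw[[v]][1]
  cc$start_glucose[2:5] <- pw$start_glucose[1] +
    w$calipers[["start_glucose"]] * 1.05      # violates the caliper
  inst$candidates[[pw$window_id[1]]] <- cc
  res <- knn_match(pw, inst$candidates, w)
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$control_onset_min, cc$time_min[1])
  expect_equal(res$pairs$distance, 0)

  # a gap of 1.05 x caliper on one variable is inadmissible even when all
  # other variables agree exactly
  cc$start_glucose[1] <- pw$start_glucose[1] +
    w$calipers[["start_glucose"]] * 1.05
  inst$candidates[[pw$window_id[1]]] <- cc
  res2 <- knn_match(pw, inst$candidates, w)
  expect_equal(nrow(res2$pairs), 0)
  expect_equal(res2$dropped$reason, "insufficient_match_quality")
})

test_that("distance ties resolve to the earlier-onset candidate", {
  inst <- local({set.seed(54); random_match_instance(n_bouts = 1,
                                                     n_cand = 4)})
  pw <- inst$pa_windows
  cc <- inst$candidates[[pw$window_id[1]]]
  for (v in inst$weights$variables) cc[[v]] <- pw[[v]][1]  # all distance 0
  inst$candidates[[pw$window_id[1]]] <- cc
  res <- knn_match(pw, inst$candidates, inst$weights)
  expect_equal(res$pairs$control_onset_min, min(cc$time_min))
})

test_that("matching equals the brute-force oracle on random small instances", {
  set.seed(55)
  for (case in 1:60) {
    inst <- random_match_instance()
    res <- knn_match(inst$pa_windows, inst$candidates, inst$weights)
    orc <- oracle_knn(inst$pa_windows, inst$candidates, inst$weights)
    expect_equal(nrow(res$pairs), nrow(orc))
    expect_equal(res$pairs$window_id, orc$window_id)
    expect_equal(res$pairs$control_onset_min, orc$control_onset_min)
    expect_equal(res$pairs$distance, orc$distance, tolerance = 1e-10)
  }
})

test_that("matching is invariant to input row order", {
  inst <- local({set.seed(56); random_match_instance(n_bouts = 6,
                                                     n_cand = 20)})
  res1 <- knn_match(inst$pa_windows, inst$candidates, inst$weights)
  perm <- c(4, 1, 6, 2, 5, 3)
  res2 <- knn_match(inst$pa_windows[perm, ], inst$candidates, inst$weights)
  expect_equal(res1$pairs, res2$pairs)
})

test_that("selected controls of one participant stay 40 min apart", {
  set.seed(57)
  for (case in 1:20) {
    inst <- random_match_instance(n_bouts = 6, n_cand = 15)
    res <- knn_match(inst$pa_windows, inst$candidates, inst$weights)
    p <- res$pairs
    for (pid in unique(p$participant_id)) {
      pp <- p[p$participant_id == pid, ]
      if (nrow(pp) < 2) next
      o <- order(pp$control_onset_min)
      s <- pp$control_onset_min[o]; e <- s + pp$duration[o]
      expect_true(all(s[-1] >= e[-length(e)] + 40))
    }
  }
})

test_that("balance reporting conserves counts and improves balance", {
  ch <- generate_cohort(small_config(), seed = 58)
  res <- analyze_cohort(ch, fit_models = FALSE)
  b <- res$balance
  expect_equal(b$n_matched + b$n_dropped, nrow(res$eligible))
  expect_true(all(is.finite(b$smd$before)))
  expect_true(all(abs(b$smd$after) <= abs(b$smd$before)))
  # every matched pair satisfies the calipers
  gaps <- res$pairs[, paste0("gap_", res$weights$variables), drop = FALSE]
  for (v in res$weights$variables) {
    expect_true(all(gaps[[paste0("gap_", v)]] <=
                      res$weights$calipers[[v]] + 1e-12))
  }
})

test_that("an empty match yields an explicit zero-pair report", {
  inst <- local({set.seed(59); random_match_instance(n_bouts = 2,
                                                     n_cand = 0)})
  res <- knn_match(inst$pa_windows, inst$candidates, inst$weights)
  expect_equal(nrow(res$pairs), 0)
  expect_equal(nrow(res$dropped), 2)
})
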