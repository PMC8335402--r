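test_that("degenerate and invalid RR simulation inputs are handled", {
  rr <- simulate_rr(50, mean = 800, sd = 0, lag1 = 0.3, seed = 1)
  expect_equal(sdnn(rr), 0)
  expect_equal(rmssd(rr), 0)
  expect_error(simulate_rr(50, sd = -1, lag1 = 0, seed = 1), "sd")
  expect_error(simulate_rr(50, sd = 10, lag1 = 1, seed = 1), "lag1")
})

test_that("the AR(1) generator hits its target moments", {
  rr <- simulate_rr(20000, mean = 800, sd = 50, lag1 = 0.5, seed = 2)
  expect_lt(abs(sdnn(rr) - 50) / 50, 0.03)
  # expected RMSSD = sd * sqrt(2 * (1 - lag1)) = 50 for lag1 = 0.5
  expect_lt(abs(rmssd(rr) - 50) / 50, 0.03)
  expect_lt(abs(avnn(rr) - 800), 3)
  rr2 <- simulate_rr(20000, mean = 800, sd = 40, lag1 = 0.8, seed = 3)
  expect_lt(abs(rmssd(rr2) - 40 * sqrt(2 * 0.2)) / (40 * sqrt(0.4)), 0.05)
})

test_that("raising the autocorrelation lowers RMSSD at fixed SDNN", {
  set.seed(4)
  lo <- sapply(1:25, function(i) {
    rmssd(simulate_rr(400, sd = 50, lag1 = 0.2, seed = 100 + i))
  })
  hi <- sapply(1:25, function(i) {
    rmssd(simulate_rr(400, sd = 50, lag1 = 0.8, seed = 200 + i))
  })
  expect_gt(mean(lo), mean(hi))
})

test_that("simulated series are seed-reproducible and window-bounded", {
  a <- simulate_rr(300, seed = 5)
  b <- simulate_rr(300, seed = 5)
  expect_identical(unclass(a), unclass(b))
  c2 <- simulate_rr(300, seed = 6)
  expect_false(identical(unclass(a), unclass(c2)))
  narrow <- simulate_rr(2000, mean = 800, sd = 120, lag1 = 0, seed = 7,
                        window = c(600, 1000))
  expect_gte(min(narrow), 600)
  expect_lte(max(narrow), 1000)
})

test_that("simulated Stroop sessions obey their parameters", {
  fixed <- simulate_stroop(rt_log_sd = 0, rt_log_mean = log(420), seed = 8)
  expect_equal(fixed$rt_ms, rep(420, 35))
  perfect <- simulate_stroop(accuracy_p = 1, seed = 9)
  expect_equal(stroop_accuracy(perfect), 1)
  expect_error(simulate_stroop(accuracy_p = 1.5, seed = 1), "accuracy_p")

  # a generator centred well below the cutoff classifies fast most times
  fast_rate <- mean(sapply(1:40, function(i) {
    classify_speed(mean_rt(simulate_stroop(rt_log_mean = log(400),
                                           seed = 300 + i))) == "fast"
  }))
  expect_gt(fast_rate, 0.9)
})

test_that("cohort covariates stay inside their configured ranges", {
  spec <- cohort_spec(n_participants = 20, uses_range = c(3, 5), rr_n = 80,
                      seed = 10)
  cohort <- simulate_cohort(spec)
  f <- cohort$features
  expect_true(all(f$age >= 17 & f$age <= 69))
  expect_true(all(f$bmi >= 16.4 & f$bmi <= 31.4))
  expect_true(all(f$hours_awake >= 0 & f$hours_awake <= 10))
  expect_true(all(f$epworth >= 0 & f$epworth <= 14))
  expect_true(all(f$female %in% c(0, 1)))
  expect_true(all(table(f$participant_id) >= 3 & table(f$participant_id) <= 5))
})

test_that("cohorts are byte-identical per seed and differ across seeds", {
  spec <- cohort_spec(n_participants = 8, uses_range = c(2, 3), rr_n = 60,
                      seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(spec, keep_raw = TRUE), d1)
  write_cohort(simulate_cohort(spec, keep_raw = TRUE), d2)
  for (fn in c("features.csv", "labels.csv", "covariates.csv")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
  rr1 <- list.files(file.path(d1, "rr"))
  expect_identical(readLines(file.path(d1, "rr", rr1[1])),
                   readLines(file.path(d2, "rr", rr1[1])))
  other <- simulate_cohort(cohort_spec(n_participants = 8,
                                       uses_range = c(2, 3), rr_n = 60,
                                       seed = 12))
  expect_false(identical(as.character(other$labels),
                         as.character(simulate_cohort(spec)$labels)))
})

test_that("a null coefficient matrix gives near-uniform labels", {
  zero <- matrix(0, 12, 3)
  spec <- cohort_spec(n_participants = 63, uses_range = c(10, 20), rr_n = 60,
                      true_beta = zero, seed = 13)
  cohort <- simulate_cohort(spec)
  counts <- table(cohort$labels)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("pipeline-mode fast/slow proportion tracks the RT placement", {
  # session log-mean RT below the cutoff with small spread -> mostly fast
  spec <- cohort_spec(n_participants = 15, uses_range = c(4, 6), rr_n = 60,
                      rt_log_mean = log(430), rt_session_spread = 0.02,
                      seed = 14)
  cohort <- simulate_cohort(spec)
  frac_fast <- mean(grepl("^fast", cohort$labels))
  # lognormal tail: P(session mean > 500) is small when exp(mu) = 430
  expect_gt(frac_fast, 0.8)
  spec2 <- cohort_spec(n_participants = 15, uses_range = c(4, 6), rr_n = 60,
                       rt_log_mean = log(580), rt_session_spread = 0.02,
                       seed = 15)
  expect_lt(mean(grepl("^fast", simulate_cohort(spec2)$labels)), 0.2)
})

test_that("model-based labels let the fit recover the coefficients", {
  # moderate effects on covariate scales (stress ~ 1e2, rmssd ~ 50 ...)
  B <- matrix(0, 12, 3)
  rownames(B) <- c("(Intercept)", "stress", "age17_21", "age22_30", "rmssd",
                   "hr", "avnn", "alimentation", "female", "epworth", "bmi",
                   "hours_awake")
  B["stress", ] <- c(0.004, -0.003, 0.002)
  B["rmssd", ] <- c(0.01, -0.012, 0.006)
  B["female", ] <- c(0.5, -0.4, 0.3)
  spec <- cohort_spec(n_participants = 63, uses_range = c(14, 18), rr_n = 80,
                      true_beta = B, seed = 16)
  cohort <- simulate_cohort(spec)
  fit <- fit_quadrant_model(cohort$features, cohort$labels)
  se <- matrix(sqrt(diag(fit$vcov)), nrow(fit$beta), ncol(fit$beta))
  cover <- abs(fit$beta - B) <= 3 * se
  expect_gte(mean(cover), 0.9)
})

test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(), "seed")
  expect_error(cohort_spec(true_beta = matrix(0, 2, 2), seed = 1), "true_beta")
})
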