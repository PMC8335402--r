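test_that("a saturated 2x2 fit recovers the log cross-ratio exactly", {
  # x = 0: 30 a, 10 b;  x = 1: 20 a, 40 b
  x <- cbind(z = c(rep(0, 40), rep(1, 60)))
  y <- factor(c(rep("a", 30), rep("b", 10), rep("a", 20), rep("b", 40)))
  fit <- mlr_fit(x, y, reference = "a")
  expect_equal(unname(fit$beta["(Intercept)", "b"]), log(10 / 30),
               tolerance = 1e-8)
  expect_equal(unname(fit$beta["z", "b"]), log((40 * 30) / (10 * 20)),
               tolerance = 1e-8)
})

test_that("labels independent of the predictors give near-zero slopes", {
  set.seed(61)
  x <- cbind(a = rnorm(800), b = rnorm(800))
  y <- factor(sample(c("p", "q", "r"), 800, replace = TRUE))
  fit <- mlr_fit(x, y, reference = "p")
  w <- wald_tests(fit)
  slopes <- w[w$term != "(Intercept)", ]
  expect_true(all(abs(slopes$estimate) < 0.3))
  expect_true(all(abs(slopes$z) < 4))
})

test_that("Newton estimates match an independent optimizer of the likelihood", {
  set.seed(62)
  for (i in 1:8) {
    K <- sample(2:4, 1)
    lev <- letters[1:K]
    beta <- matrix(runif((2 + 1) * (K - 1), -1, 1), 3, K - 1)
    d <- sim_multinom(160, beta, lev, reference = lev[1])
    if (length(unique(d$y)) < K) next
    fit <- mlr_fit(d$x, d$y, reference = lev[1])
    ora <- oracle_mlr(d$x, d$y, reference = lev[1])
    expect_lt(max(abs(fit$beta - ora)) / (1 + max(abs(ora))), 1e-5)
  }
})

test_that("estimates and SEs agree with nnet::multinom", {
  skip_if_not_installed("nnet")
  set.seed(63)
  beta <- matrix(c(0.3, -0.8, 0.5, -0.2, 0.6, 0.9), 3, 2)
  d <- sim_multinom(500, beta, c("a", "b", "c"), reference = "a")
  fit <- mlr_fit(d$x, d$y, reference = "a")
  ref <- nnet::multinom(y ~ x1 + x2, data = data.frame(y = d$y, d$x),
                        trace = FALSE, reltol = 1e-14)
  expect_equal(unname(t(coef(ref))), unname(fit$beta), tolerance = 1e-4)
  se_ref <- t(summary(ref)$standard.errors)
  w <- wald_tests(fit)
  expect_equal(unname(matrix(w$se, 3, 2)), unname(se_ref), tolerance = 1e-3)
})

test_that("predicted probabilities behave like a softmax", {
  lev <- quadrant_levels()
  model <- structure(list(beta = matrix(0, 3, 3,
                            dimnames = list(c("(Intercept)", "u", "v"),
                                            lev[-2])),
                          levels = lev, reference = "fast_high"),
                     class = "mlr_model")
  p <- predict_proba(model, cbind(u = c(1, -2), v = c(0, 5)))
  expect_equal(unname(p), matrix(0.25, 2, 4))   # all-zero coefficients

  set.seed(64)
  B <- matrix(rnorm(9), 3, 3,
              dimnames = list(c("(Intercept)", "u", "v"), lev[-2]))
  model$beta <- B
  x <- cbind(u = rnorm(50), v = rnorm(50))
  p <- predict_proba(model, x)
  expect_true(all(abs(rowSums(p) - 1) < 1e-12))
  expect_true(all(p >= 0))
  # brute-force exp/normalize, reference gets a zero linear predictor
  eta <- cbind(1, x) %*% B
  full <- cbind(fast_low = eta[, 1], fast_high = 0,
                slow_low = eta[, 2], slow_high = eta[, 3])
  expect_equal(unname(p), unname(exp(full) / rowSums(exp(full))),
               tolerance = 1e-12)
})

test_that("refitting with another reference leaves probabilities unchanged", {
  set.seed(65)
  beta <- matrix(runif(12, -0.8, 0.8), 4, 3)
  d <- sim_multinom(600, beta, quadrant_levels(), reference = "fast_high")
  f1 <- mlr_fit(d$x, d$y, reference = "fast_high")
  f2 <- mlr_fit(d$x, d$y, reference = "slow_low")
  p1 <- predict_proba(f1, d$x)
  p2 <- predict_proba(f2, d$x)
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("odds ratios are exp(beta)", {
  expect_equal(odds_ratios(0), 1)
  expect_equal(round(odds_ratios(c(0.417, -0.922)), 2), c(1.52, 0.40))
  set.seed(66)
  d <- sim_multinom(300, matrix(0.5, 3, 1), c("a", "b"), reference = "a")
  fit <- mlr_fit(d$x, d$y, reference = "a")
  expect_equal(odds_ratios(fit), exp(fit$beta))
})

test_that("Nagelkerke matches an independent evaluation and its bounds", {
  set.seed(67)
  beta <- matrix(c(0.4, 1.2, -0.9), 3, 1)
  d <- sim_multinom(400, beta, c("a", "b"), reference = "a")
  fit <- mlr_fit(d$x, d$y, reference = "a")
  # independent Cox-Snell / rescaling computation
  n <- fit$n
  cs <- 1 - (exp(fit$loglik_null) / exp(fit$loglik))^(2 / n)
  expect_equal(nagelkerke(fit), cs / (1 - exp(fit$loglik_null)^(2 / n)))
  expect_gt(nagelkerke(fit), 0)
  expect_lt(nagelkerke(fit), 1)
  # no improvement -> 0; perfect fit (loglik -> 0) -> 1
  base <- list(loglik = fit$loglik_null, loglik_null = fit$loglik_null, n = n)
  expect_equal(nagelkerke(base), 0)
  perfect <- list(loglik = 0, loglik_null = fit$loglik_null, n = n)
  expect_equal(nagelkerke(perfect), 1)
  # monotone in loglik for fixed loglik_null and n
  lls <- seq(fit$loglik_null, 0, length.out = 20)
  vals <- sapply(lls, function(l) {
    nagelkerke(list(loglik = l, loglik_null = fit$loglik_null, n = n))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("an exactly duplicated predictor raises a collinearity error", {
  set.seed(68)
  x <- cbind(a = rnorm(200))
  x <- cbind(x, a_copy = x[, 1])
  y <- factor(sample(c("u", "v"), 200, replace = TRUE))
  expect_error(mlr_fit(x, y, reference = "u"), "a_copy|collinear")
})

test_that("complete separation is detected and ridge rescues it", {
  # perfectly separated with a tiny margin, so no finite maximizer exists
  x <- cbind(z = rep(c(-0.1, 0.1), each = 50))
  y <- factor(rep(c("lo", "hi"), each = 50), levels = c("lo", "hi"))
  expect_error(mlr_fit(x, y, reference = "lo"), "ridge")
  fit <- mlr_fit(x, y, reference = "lo", ridge = 1)
  expect_true(fit$converged)
})

test_that("null-model Wald p-values are approximately uniform", {
  set.seed(69)
  pvals <- replicate(400, {
    x <- cbind(z = rnorm(150))
    y <- factor(sample(c("a", "b"), 150, replace = TRUE))
    w <- wald_tests(mlr_fit(x, y, reference = "a"))
    w$p[w$term == "z"]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the Wald statistic of a real effect grows with n", {
  set.seed(70)
  beta <- matrix(c(0, 0.6), 2, 1)
  mean_wald <- sapply(c(100, 400, 1600), function(n) {
    mean(replicate(10, {
      d <- sim_multinom(n, beta, c("a", "b"), reference = "a")
      w <- wald_tests(mlr_fit(d$x, d$y, reference = "a"))
      w$wald[w$term == "x1"]
    }))
  })
  expect_true(all(diff(mean_wald) > 0))
})

test_that("classification table bookkeeping is exact", {
  set.seed(71)
  beta <- matrix(runif(12, -1, 1), 4, 3)
  d <- sim_multinom(500, beta, quadrant_levels(), reference = "fast_high")
  fit <- mlr_fit(d$x, d$y, reference = "fast_high")
  rep_ <- classification_report(fit, d$x, d$y)
  tab <- rep_$classification_table
  expect_equal(as.vector(rowSums(tab)), as.vector(table(d$y)))
  probs <- predict_proba(fit, d$x)
  pred <- quadrant_levels()[max.col(probs, ties.method = "first")]
  expect_equal(as.vector(colSums(tab)),
               as.vector(table(factor(pred, quadrant_levels()))))
  # brute-force recount of the success rate
  expect_equal(rep_$success_rate, mean(pred == as.character(d$y)))
  expect_equal(rep_$success_rate, sum(diag(tab)) / sum(tab))
})

test_that("an intercept-only predictor set predicts the majority class", {
  set.seed(72)
  x <- cbind(noise = rnorm(300) * 0)   # constant column has no information
  y <- factor(sample(c("maj", "min"), 300, replace = TRUE, prob = c(0.7, 0.3)))
  fit <- mlr_fit(cbind(z = rnorm(300)), y, reference = "maj", ridge = 1e8)
  rep_ <- classification_report(fit, cbind(z = rnorm(300)), y)
  expect_equal(rep_$success_rate, max(table(y)) / 300)
})

test_that("perfectly separable classes reach success rate 1 with ridge", {
  x <- cbind(z = c(rnorm(60, -4), rnorm(60, 4)))
  y <- factor(rep(c("lo", "hi"), each = 60), levels = c("lo", "hi"))
  fit <- mlr_fit(x, y, reference = "lo", ridge = 0.05)
  rep_ <- classification_report(fit, x, y)
  expect_equal(rep_$success_rate, 1)
})

test_that("parameter recovery holds across seeded replicates", {
  set.seed(73)
  beta <- matrix(c(0.2, 0.8, -0.5, -0.3, 0.4, 0.7,
                   0.1, -0.6, 0.9, 0, 0.5, -0.4), 4, 3)
  hits <- 0L; total <- 0L
  for (r in 1:20) {
    d <- sim_multinom(2000, beta, quadrant_levels(), reference = "fast_high")
    fit <- mlr_fit(d$x, d$y, reference = "fast_high")
    se <- matrix(sqrt(diag(fit$vcov)), 4, 3)
    hits <- hits + sum(abs(fit$beta - beta) <= 3 * se)
    total <- total + 12L
  }
  expect_gte(hits / total, 0.95)
})

test_that("predictor ranking finds dominant effects and ignores column order", {
  set.seed(74)
  beta <- matrix(c(0.1, 1.6, 0.05, -0.1, -1.4, 0.02), 3, 2)  # x1 dominates
  d <- sim_multinom(800, beta, c("a", "b", "c"), reference = "a")
  fit <- mlr_fit(d$x, d$y, reference = "a")
  rk <- rank_predictors(fit)
  expect_equal(rk$term[1], "x1")
  # permuting predictor columns leaves the ranking unchanged
  x2 <- d$x[, c(2, 1)]
  fit2 <- mlr_fit(x2, d$y, reference = "a")
  rk2 <- rank_predictors(fit2)
  expect_equal(rk2$term, rk$term)
  expect_equal(rk2$max_wald, rk$max_wald, tolerance = 1e-6)
  # brute-force: recompute the summary and sort
  w <- wald_tests(fit)
  w <- w[w$term != "(Intercept)", ]
  o <- sort(tapply(w$wald, w$term, max), decreasing = TRUE)
  expect_equal(rk$term, names(o))
})

test_that("grouped dummies rank as one predictor and p-values format", {
  set.seed(75)
  x <- cbind(d1 = rbinom(400, 1, 0.3), d2 = rbinom(400, 1, 0.3), z = rnorm(400))
  attr(x, "term") <- c("band", "band", "z")
  eta <- 1.5 * x[, "d1"] + 1.2 * x[, "d2"]
  y <- factor(ifelse(runif(400) < 1 / (1 + exp(-eta)), "b", "a"))
  fit <- mlr_fit(x, y, reference = "a")
  rk <- rank_predictors(fit)
  expect_setequal(rk$term, c("band", "z"))
  expect_equal(rk$term[1], "band")
  expect_identical(format_p(c(0.5004, 1e-9, 0.0094)),
                   c("0.500", "0.000", "0.009"))
})

test_that("models survive a JSON round-trip", {
  set.seed(76)
  beta <- matrix(runif(6, -1, 1), 3, 2)
  d <- sim_multinom(300, beta, c("a", "b", "c"), reference = "a")
  fit <- mlr_fit(d$x, d$y, reference = "a")
  p <- withr::local_tempfile(fileext = ".json")
  save_mlr_model(fit, p)
  back <- load_mlr_model(p)
  expect_equal(back$beta, fit$beta)
  expect_equal(predict_proba(back, d$x), predict_proba(fit, d$x))
  expect_equal(nagelkerke(back), nagelkerke(fit))
})
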