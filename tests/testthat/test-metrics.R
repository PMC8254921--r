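test_that("calibration is (slope 1, intercept 0) for self-generated outcomes", {
  set.seed(71)
  n <- 1e5
  lp <- rnorm(n, -0.5, 1.2)
  y <- rbinom(n, 1, plogis(lp))
  # 3 Monte-Carlo SEs from the information of the recalibration models
  expect_equal(calibration_slope(lp, y), 1, tolerance = 0.03)
  expect_equal(calibration_in_the_large(lp, y), 0, tolerance = 0.03)
})

test_that("calibration recovers generative distortions of the linear predictor", {
  set.seed(72)
  n <- 1e5
  lp <- rnorm(n, 0, 0.8)
  y2 <- rbinom(n, 1, plogis(2 * lp))       # outcomes twice as steep
  expect_equal(calibration_slope(lp, y2), 2, tolerance = 0.06)
  yshift <- rbinom(n, 1, plogis(lp + 0.7)) # evaluated predictions run low
  expect_equal(calibration_in_the_large(lp, yshift), 0.7, tolerance = 0.03)
  # constant predictions at the event rate calibrate exactly in the large
  rate <- mean(yshift)
  expect_equal(calibration_in_the_large(rep(qlogis(rate), n), yshift), 0,
               tolerance = 0.02)
})

test_that("calibration rejects degenerate inputs", {
  expect_error(calibration_slope(rep(0.3, 10), rep(c(0, 1), 5)), "constant")
  expect_error(calibration_slope(rnorm(10), rep(1, 10)), "single-class")
  expect_error(calibration_in_the_large(rnorm(10), rep(0, 10)), "single-class")
  expect_error(calibration_slope(rnorm(5), c(0, 1, 2, 0, 1)), "binary")
})

test_that("the C-statistic equals brute-force pair enumeration", {
  expect_equal(c_statistic(c(0.2, 0.4, 0.4, 0.9), c(0, 0, 1, 1)), 3.5 / 4)
  # random vectors against the O(n1 n0) oracle
  set.seed(73)
  for (k in 1:5) {
    n <- 60
    s <- round(runif(n), 2)  # ties on purpose
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
    oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                          ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
    expect_equal(c_statistic(s, y), oracle, tolerance = 1e-12)
  }
})

test_that("the C-statistic has its boundary and invariance properties", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(c_statistic(y, y), 1)
  set.seed(74)
  s <- runif(5000)
  y2 <- rbinom(5000, 1, 0.5)
  expect_equal(c_statistic(s, y2), 0.5, tolerance = 0.03)
  # invariant under strictly increasing transforms
  expect_equal(c_statistic(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y2),
               c_statistic(s, y2), tolerance = 1e-12)
  expect_error(c_statistic(s[1:5], rep(0, 5)), "single-class")
})

test_that("RPMSE and Brier match their definitions", {
  set.seed(75)
  p <- runif(500, 0.05, 0.85)
  expect_equal(rpmse(p, p), 0)
  expect_equal(rpmse(p, p + 0.1), 0.1, tolerance = 1e-12)
  q <- runif(500)
  expect_equal(rpmse(p, q), sqrt(sum((p - q)^2) / 500), tolerance = 1e-12)
  y <- rbinom(500, 1, p)
  b <- brier(y, q)
  expect_equal(b$brier, sum((y - q)^2) / 500, tolerance = 1e-12)
  expect_equal(b$root_brier, sqrt(b$brier))
  expect_equal(brier(y, y)$brier, 0)
  expect_equal(brier(y, rep(0.5, 500))$brier, 0.25)
  expect_error(rpmse(p, q[1:10]), "length mismatch")
  expect_error(brier(y[1:10], q), "length mismatch")
})

test_that("performance_summary assembles every measure with tags", {
  pair <- quick_pair("S1", K = 15, a0 = 2.5, seed = 76)
  fit <- fit_iee(pair$training)
  pred <- predict_from_marginal_fit(fit, pair$validation)
  perf <- performance_summary(pred, pair$validation,
                              tags = list(scenario = "NONE", replicate = 1L))
  expect_s3_class(perf, "performance_summary")
  expect_equal(perf$method, "iee")
  expect_equal(perf$n_members, nrow(pair$validation))
  expect_false(is.na(perf$rpmse))
  expect_equal(perf$scenario, "NONE")
  # rpmse is NA when the truth is unavailable
  v2 <- pair$validation
  v2$p_true <- NULL
  expect_true(is.na(performance_summary(pred, v2)$rpmse))
})
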