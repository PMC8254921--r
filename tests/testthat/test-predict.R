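test_that("conditional prediction modes and errors behave as defined", {
  pair <- quick_pair("S1", K = 20, a0 = 3, seed = 61)
  fit <- fit_glmm(pair$training)
  known <- predict_conditional(fit, pair$validation, "known_u")
  zero <- predict_conditional(fit, pair$validation, "u_zero")
  u <- empirical_bayes(fit)[as.character(pair$validation$cluster_id)]
  expect_equal(known$linear_predictor, zero$linear_predictor + unname(u),
               tolerance = 1e-10)
  expect_equal(known$probability, plogis(known$linear_predictor))
  nd <- pair$validation[1:5, ]
  nd$cluster_id <- 999L
  expect_error(predict_conditional(fit, nd, "known_u"), "marginal predictions")
  expect_error(predict_conditional(fit_iee(pair$training), pair$validation),
               "GLMM")
})

test_that("quadrature marginalisation matches Monte-Carlo integration", {
  pair <- quick_pair("S1", K = 20, a0 = 3, seed = 62)
  fit <- fit_glmm(pair$training)
  nd <- pair$validation[round(seq(1, nrow(pair$validation), length.out = 40)), ]
  pm <- predict_marginal_glmm(fit, nd, "integrate")
  eta0 <- fixed_lp_for_test(fit, nd)
  set.seed(1)
  u <- stats::rnorm(1e6, 0, sqrt(fit$sigma_u2_hat))
  u <- c(u, -u)  # antithetic pairs sharpen the million-draw oracle
  pmc <- vapply(eta0, function(e) mean(plogis(e + u)), 0)
  expect_lt(max(abs(pm$probability - pmc)), 1e-4)
})

test_that("the attenuation approximation tracks exact integration", {
  pair <- quick_pair("S2", K = 25, a0 = 3.5, seed = 63)
  fit <- fit_glmm(pair$training)
  expect_gt(fit$sigma_u2_hat, 0.2)
  grid <- pair$validation[order(pair$validation$eta_true), ]
  grid <- grid[seq(1, nrow(grid), length.out = 200), ]
  pi_ <- predict_marginal_glmm(fit, grid, "integrate")
  pz <- predict_marginal_glmm(fit, grid, "zeger")
  expect_lt(max(abs(pi_$probability - pz$probability)), 0.01)
  # the attenuation factor at sigma_u2 = 0.82
  cz <- 16 * sqrt(3) / (15 * pi)
  expect_equal(1 / sqrt(1 + cz^2 * 0.82), 0.883, tolerance = 1e-3)
})

test_that("marginalisation contracts the linear predictor toward zero", {
  pair <- quick_pair("S1", K = 25, a0 = 3, seed = 64)
  fit <- fit_glmm(pair$training)
  nd <- pair$validation
  pm <- predict_marginal_glmm(fit, nd, "integrate")
  pc <- predict_conditional(fit, nd, "u_zero")
  expect_true(all(abs(pm$linear_predictor) <= abs(pc$linear_predictor) + 1e-8))
  expect_true(all(pm$probability > 0 & pm$probability < 1))
  expect_true(all(pc$probability > 0 & pc$probability < 1))
})

test_that("with vanishing variance all prediction routes coincide", {
  d <- independent_data(n = 3000, seed = 65)
  fit <- fit_glmm(d, nAGQ = 11)
  expect_lt(fit$sigma_u2_hat, 0.01)
  pc <- predict_conditional(fit, d, "u_zero")
  pi_ <- predict_marginal_glmm(fit, d, "integrate")
  pz <- predict_marginal_glmm(fit, d, "zeger")
  expect_equal(pi_$probability, pc$probability, tolerance = 1e-3)
  expect_equal(pz$probability, pc$probability, tolerance = 1e-3)
})

test_that("marginal-model predictions use the marginal coefficients directly", {
  pair <- quick_pair("S2", K = 20, a0 = 3, seed = 66)
  iee <- fit_iee(pair$training)
  p <- predict_from_marginal_fit(iee, pair$validation)
  des <- build_design(pair$validation, iee$spec)
  expect_equal(p$linear_predictor,
               drop(des$x %*% coef(iee)), tolerance = 1e-12)
  # all-zero coefficients give probability one half
  iee0 <- iee
  iee0$coefficients[] <- 0
  p0 <- predict_from_marginal_fit(iee0, pair$validation)
  expect_equal(p0$probability, rep(0.5, nrow(pair$validation)))
  expect_error(predict_from_marginal_fit(iee, pair$validation[, -3]),
               "missing columns")
})

test_that("population fallback supplies average cluster-level covariates", {
  pair <- quick_pair("S2", K = 20, a0 = 3, seed = 67)
  iee <- fit_iee(pair$training, model_spec("iee", adjustment = "rbar"))
  one <- pair$validation[1, ]
  pf <- predict_from_marginal_fit(iee, one, fallback = "population")
  expect_identical(attr(pf, "fallback"), "population")
  # reproduces the "average exposure level" recipe by hand
  des <- build_design(one, iee$spec)
  x <- des$x; x[, "rbar"] <- iee$training_rbar
  expect_equal(pf$linear_predictor, drop(x %*% coef(iee)), tolerance = 1e-12)
})
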