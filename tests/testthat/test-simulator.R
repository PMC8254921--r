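test_that("cluster effects have the configured variances and correlations", {
  cfg <- scenario_config(K = 60000, sigma_u2 = 0.82, sigma_v2 = 0.82,
                         sigma_w2 = 0.41, rho_uv = 0.7, rho_uw = 0.7,
                         rho_vw = 0.5)
  set.seed(1)
  eff <- draw_cluster_effects(cfg)
  expect_equal(stats::var(eff$u), 0.82, tolerance = 0.02)
  expect_equal(stats::var(eff$v), 0.82, tolerance = 0.02)
  expect_equal(stats::var(eff$w), 0.41, tolerance = 0.02)
  expect_equal(stats::cor(eff$Z[, "u"], eff$Z[, "v"]), 0.7, tolerance = 0.01)
  expect_equal(stats::cor(eff$Z[, "u"], eff$Z[, "w"]), 0.7, tolerance = 0.01)
  expect_equal(stats::cor(eff$Z[, "v"], eff$Z[, "w"]), 0.5, tolerance = 0.02)
})

test_that("independent or degenerate channels behave as configured", {
  cfg <- scenario_config(K = 50000, sigma_v2 = 0.82, sigma_w2 = 0)
  set.seed(2)
  eff <- draw_cluster_effects(cfg)
  expect_lt(abs(stats::cor(eff$u, eff$v)), 0.02)
  expect_identical(unname(eff$w), rep(0, cfg$K))
})

test_that("a rho = 0.7 channel explains about half the between-cluster variance", {
  cfg <- scenario_config(K = 10000, sigma_v2 = 0.82, rho_uv = 0.7)
  set.seed(3)
  eff <- draw_cluster_effects(cfg)
  r2 <- summary(stats::lm(eff$u ~ eff$v))$r.squared
  expect_equal(r2, 0.49, tolerance = 0.03)
})

test_that("training sizes are Poisson(exp(a0) + 5) when the size channel is off", {
  cfg <- scenario_config(K = 10000, a0 = 4.5)
  set.seed(4)
  eff <- draw_cluster_effects(cfg)
  n <- draw_cluster_sizes(eff, cfg, "training")
  expect_true(all(n >= 1))
  expect_equal(mean(n), exp(4.5) + 5, tolerance = 0.01)
  # "approximately 100" at the default settings
  expect_equal(mean(n) / 100, 1, tolerance = 0.1)
})

test_that("the ICS channel couples cluster size to the outcome intercept", {
  cfg <- scenario_config(K = 10000, sigma_w2 = 0.41, rho_uw = 0.7)
  set.seed(5)
  eff <- draw_cluster_effects(cfg)
  n <- draw_cluster_sizes(eff, cfg, "training")
  expect_gt(stats::cor(n, eff$u), 0.4)
})

test_that("non-ICS validation sizes follow the lognormal-mean Poisson law", {
  cfg <- scenario_config(K = 10000)
  set.seed(6)
  eff <- draw_cluster_effects(cfg)
  n <- draw_cluster_sizes(eff, cfg, "validation")
  # E exp(alpha) = exp(5.7 + 0.3^2/2) ~ 313, independent of u
  expect_equal(mean(n), exp(5.7 + 0.09 / 2), tolerance = 0.05)
  expect_lt(abs(stats::cor(n, eff$u)), 0.05)
})

test_that("covariates have the stated moments and are independent of the cluster", {
  cfg <- scenario_config(K = 5000, sigma_w2 = 0.41, rho_uw = 0.7)
  set.seed(7)
  eff <- draw_cluster_effects(cfg)
  sizes <- draw_cluster_sizes(eff, cfg, "training")
  X <- draw_covariates(sizes)
  v <- apply(X, 2, stats::var)
  expect_equal(unname(v[1:3]), c(0.09, 0.16, 0.25), tolerance = 0.01)
  expect_equal(unname(colMeans(X)[4:5]), c(0.1, 0.2), tolerance = 0.02)
  u_member <- rep(eff$u, sizes)
  for (j in 1:5) expect_lt(abs(stats::cor(X[, j], u_member)), 0.01)
})

test_that("exposure prevalence and its CBC coupling are as configured", {
  # no CBC: i.i.d. Bernoulli(plogis(gamma0))
  cfg0 <- scenario_config(K = 2000, sigma_v2 = 0)
  set.seed(8)
  eff0 <- draw_cluster_effects(cfg0)
  sizes0 <- draw_cluster_sizes(eff0, cfg0, "training")
  r0 <- draw_exposure(eff0, sizes0, cfg0)
  expect_equal(mean(r0), 0.4, tolerance = 0.01)

  # CBC: cluster-mean exposure tracks u
  cfg1 <- scenario_config(K = 10000, a0 = 3, sigma_v2 = 0.82, rho_uv = 0.7)
  set.seed(9)
  eff1 <- draw_cluster_effects(cfg1)
  sizes1 <- draw_cluster_sizes(eff1, cfg1, "training")
  r1 <- draw_exposure(eff1, sizes1, cfg1)
  rbar <- vapply(split(r1, rep(seq_len(cfg1$K), sizes1)), mean, 0)
  expect_gt(stats::cor(eff1$u, rbar), 0.5)
})

test_that("outcomes follow the random-intercepts model", {
  cfg <- scenario_config(K = 4, beta0 = 0)
  eff <- list(u = rep(0, 4), v = rep(0, 4), w = rep(0, 4))
  sizes <- rep(2L, 4)
  X <- matrix(0, 8, 5, dimnames = list(NULL, paste0("x", 1:5)))
  set.seed(10)
  out <- draw_outcomes(X, rep(0L, 8), eff, sizes, cfg)
  expect_equal(out$p, rep(0.5, 8))
  expect_equal(out$eta, rep(0, 8))

  # monotone in any covariate with positive slope
  X2 <- X; X2[, "x1"] <- seq(-1, 1, length.out = 8)
  out2 <- draw_outcomes(X2, rep(0L, 8), eff, sizes, cfg)
  expect_true(all(diff(out2$p) > 0))

  expect_error(draw_outcomes(X[, 1:3], rep(0L, 8), eff, sizes, cfg),
               "coefficient vector")
})

test_that("outcome prevalence matches the quadrature-implied marginal value", {
  # E plogis(-1.5 + gaussian(0, 0.5 + 0.82) + Bern(.1) + Bern(.2) + Bern(.4))
  # = 0.3540 by 41-node quadrature; the generator must agree within MC error
  cfg <- scenario_config(K = 2000)
  set.seed(11)
  d <- simulate_dataset(draw_cluster_effects(cfg), cfg, "training")
  expect_lt(abs(mean(d$y) - 0.3540), 0.015)
})

test_that("paired generation shares effects and is deterministic", {
  cfg <- scenario_preset("S2", icc = 0.2, K = 10, a0 = 3)
  p1 <- generate_pair(cfg, 123)
  p2 <- generate_pair(cfg, 123)
  expect_identical(p1$training, p2$training)
  expect_identical(p1$validation, p2$validation)
  expect_identical(attr(p1$training, "cluster_effects")$u,
                   attr(p1$validation, "cluster_effects")$u)
  p3 <- generate_pair(cfg, 124)
  expect_false(identical(p1$training$y, p3$training$y))
  # the truth columns are consistent
  expect_equal(p1$training$p_true, plogis(p1$training$eta_true))
  # member counts match the size column
  counts <- as.vector(table(p1$training$cluster_id)[
    as.character(p1$training$cluster_id)])
  expect_identical(counts == p1$training$n, rep(TRUE, nrow(p1$training)))
})

test_that("scenario NONE has no CBC or ICS by construction", {
  cfg <- scenario_preset("S1", icc = 0.2, K = 2500, a0 = 2.5)
  set.seed(12)
  eff <- draw_cluster_effects(cfg)
  sizes <- draw_cluster_sizes(eff, cfg, "training")
  r <- draw_exposure(eff, sizes, cfg)
  rbar <- vapply(split(r, rep(seq_len(cfg$K), sizes)), mean, 0)
  expect_lt(abs(stats::cor(eff$u, rbar)), 0.05)
  expect_lt(abs(stats::cor(eff$u, sizes)), 0.05)
})

test_that("datasets round-trip through CSV", {
  pair <- quick_pair(K = 6, a0 = 2, seed = 55)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clustered_data(pair$training, path, replicate = 3L)
  back <- read_clustered_data(path)
  expect_s3_class(back, "clustered_data")
  expect_equal(back$replicate, rep(3L, nrow(pair$training)))
  expect_equal(back$y, pair$training$y)
  expect_equal(back$eta_true, pair$training$eta_true, tolerance = 1e-12)
})
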