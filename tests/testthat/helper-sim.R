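# shared fixtures: everything is generated in code under fixed seeds

# a compact scenario for fast fits: fewer, smaller clusters
quick_config <- function(scenario = "S1", icc = 0.2, K = 30, a0 = 3, ...) {
  scenario_preset(scenario, icc = icc, K = K, a0 = a0, ...)
}

# one small training/validation pair
quick_pair <- function(scenario = "S1", seed = 101, ...) {
  generate_pair(quick_config(scenario, ...), seed)
}

# independent-data generator (no clustering): logistic outcomes from a
# linear predictor built on the standard covariate set
independent_data <- function(n = 4000, K = 20, beta0 = -1.5,
                             beta = rep(1, 6), seed = 1) {
  set.seed(seed)
  X <- draw_covariates(rep(ceiling(n / K), K))[seq_len(n), , drop = FALSE]
  r <- stats::rbinom(n, 1, 0.4)
  eta <- beta0 + drop(cbind(X, r) %*% beta)
  data.frame(cluster_id = rep(seq_len(K), length.out = n),
             member_id = seq_len(n), X, r = r,
             eta_true = eta, p_true = plogis(eta),
             y = stats::rbinom(n, 1, plogis(eta)))
}

# fixed-effect linear predictor of a fit on data (internal helper)
fixed_lp_for_test <- function(fit, d) clustpred:::fixed_lp(fit, d)

# brute-force conditional log-likelihood by enumerating every
# within-cluster event configuration (oracle for the CML recursion)
brute_conditional_loglik <- function(beta, data, predictors) {
  x <- as.matrix(data[predictors])
  ll <- 0
  for (cl in split(seq_len(nrow(data)), data$cluster_id)) {
    eta <- drop(x[cl, , drop = FALSE] %*% beta)
    y <- data$y[cl]
    m <- sum(y)
    if (m == 0 || m == length(cl)) next
    sets <- utils::combn(length(cl), m)
    denom <- sum(apply(sets, 2, function(s) exp(sum(eta[s]))))
    ll <- ll + sum(eta[y == 1]) - log(denom)
  }
  ll
}
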