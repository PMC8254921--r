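#' Draw the correlated cluster effects (u, v, w)
#'
#' Step one of the generator: K triples of standard normals
#' (Z_u, Z_v, Z_w) with the configured pairwise correlations, scaled by the
#' corresponding standard deviations to give the outcome random intercept
#' u, the exposure-propensity effect v and the cluster-size effect w.
#' The correlation matrix is factorised by its symmetric eigen square root
#' (order fixed as u, v, w) so that exactly singular but valid matrices are
#' accepted. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config A [scenario_config()].
#' @return A list of class `cluster_effects` with elements `u`, `v`, `w`
#'   (length-K effect vectors) and `Z` (the K x 3 latent standard normals).
#' @export
draw_cluster_effects <- function(config) {
  C <- effect_correlation_matrix(config)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(sprintf(paste0("correlation triple (rho_uv = %g, rho_uw = %g, ",
                        "rho_vw = %g) is not positive semi-definite"),
                 config$rho_uv, config$rho_uw, config$rho_vw))
  }
  A <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  Z <- matrix(stats::rnorm(3 * config$K), config$K, 3) %*% A
  colnames(Z) <- c("u", "v", "w")
  out <- list(u = sqrt(config$sigma_u2) * Z[, "u"],
              v = sqrt(config$sigma_v2) * Z[, "v"],
              w = sqrt(config$sigma_w2) * Z[, "w"],
              Z = Z)
  class(out) <- "cluster_effects"
  out
}

#' Draw cluster sizes
#'
#' Training sizes follow Poisson(exp(a0 + a1 w_i) + 5): when the ICS
#' channel is off (`sigma_w2 = 0`) this is i.i.d. Poisson(exp(a0) + 5).
#' Validation sizes follow the same law when ICS is on; otherwise they are
#' drawn larger and independent of (u, v), as
#' Poisson(exp(alpha_i)) with alpha_i ~ Normal(mean, sd^2) from the
#' `validation_alpha_*` fields. A draw of zero is redrawn (its probability
#' is negligible at the default settings but a cluster must have at least
#' one member).
#'
#' @param effects A `cluster_effects`.
#' @param config A [scenario_config()].
#' @param role `"training"` or `"validation"`.
#' @return Integer vector of K sizes, all at least 1.
#' @export
draw_cluster_sizes <- function(effects, config, role = c("training", "validation")) {
  role <- match.arg(role)
  K <- config$K
  if (role == "training" || config$sigma_w2 > 0) {
    lambda <- exp(config$a0 + config$a1 * effects$w) + 5
  } else {
    lambda <- exp(stats::rnorm(K, config$validation_alpha_mean,
                               config$validation_alpha_sd))
  }
  n <- stats::rpois(K, lambda)
  while (any(n < 1)) {
    i <- which(n < 1)
    n[i] <- stats::rpois(length(i), lambda[i])
  }
  n
}

#' Draw member-level covariates
#'
#' Three continuous covariates, Normal with mean zero and SDs 0.3, 0.4 and
#' 0.5, and two binary covariates with prevalence 0.1 and 0.2, all
#' independent of the cluster effects and of cluster size.
#'
#' @param sizes Integer vector of cluster sizes.
#' @return A numeric matrix with `sum(sizes)` rows and columns `x1`..`x5`.
#' @export
draw_covariates <- function(sizes) {
  stopifnot(all(sizes >= 1))
  n <- sum(sizes)
  X <- cbind(x1 = stats::rnorm(n, 0, 0.3),
             x2 = stats::rnorm(n, 0, 0.4),
             x3 = stats::rnorm(n, 0, 0.5),
             x4 = stats::rbinom(n, 1, 0.1),
             x5 = stats::rbinom(n, 1, 0.2))
  X
}

#' Draw the binary exposure
#'
#' Member j of cluster i is exposed with probability
#' plogis(gamma0 + v_i). When `sigma_v2 = 0` the exposure is i.i.d.
#' Bernoulli(plogis(gamma0)); when the CBC channel is on, the
#' within-cluster exposure prevalence varies with v and hence correlates
#' with the outcome random intercept u when `rho_uv > 0` — this is the
#' confounding-by-cluster mechanism.
#'
#' @inheritParams draw_cluster_sizes
#' @param sizes Integer vector of cluster sizes.
#' @return 0/1 vector of length `sum(sizes)`.
#' @export
draw_exposure <- function(effects, sizes, config) {
  p <- stats::plogis(config$gamma0 + rep(effects$v, sizes))
  stats::rbinom(length(p), 1, p)
}

#' Draw binary outcomes from the random-intercepts model
#'
#' The true linear predictor is
#' eta_ij = beta0 + (x_ij, r_ij)' beta + u_i and
#' Y_ij ~ Bernoulli(plogis(eta_ij)). Both eta and the true probability are
#' returned so that the root predictive mean squared error can later be
#' computed against the truth.
#'
#' @inheritParams draw_exposure
#' @param covariates Matrix from [draw_covariates()].
#' @param exposure 0/1 vector from [draw_exposure()].
#' @return A list with `y`, `eta` and `p`.
#' @export
draw_outcomes <- function(covariates, exposure, effects, sizes, config) {
  Xr <- cbind(covariates, r = exposure)
  if (ncol(Xr) != length(config$beta)) {
    stop(sprintf("coefficient vector has length %d but design has %d columns",
                 length(config$beta), ncol(Xr)))
  }
  eta <- config$beta0 + drop(Xr %*% config$beta) + rep(effects$u, sizes)
  p <- stats::plogis(eta)
  list(y = stats::rbinom(length(p), 1, p), eta = eta, p = p)
}

#' Assemble one clustered dataset for a given role
#'
#' Runs the size, covariate, exposure and outcome steps for an existing set
#' of cluster effects and returns a long-format data frame, one row per
#' member, of class `clustered_data`.
#'
#' @inheritParams draw_cluster_sizes
#' @return A data frame with columns `cluster_id`, `member_id`, `x1`..`x5`,
#'   `r` (exposure), `n` (cluster size), `eta_true`, `p_true`, `y`, and the
#'   generating effects attached as attribute `"cluster_effects"`.
#' @export
simulate_dataset <- function(effects, config, role = c("training", "validation")) {
  role <- match.arg(role)
  sizes <- draw_cluster_sizes(effects, config, role)
  X <- draw_covariates(sizes)
  r <- draw_exposure(effects, sizes, config)
  out <- draw_outcomes(X, r, effects, sizes, config)
  d <- data.frame(
    cluster_id = rep(seq_len(config$K), sizes),
    member_id = sequence(sizes),
    X, r = r, n = rep(sizes, sizes),
    eta_true = out$eta, p_true = out$p, y = out$y
  )
  attr(d, "cluster_effects") <- effects
  attr(d, "role") <- role
  class(d) <- c("clustered_data", "data.frame")
  d
}

#' Generate a paired training and validation dataset
#'
#' One replicate of the study design: the same set of cluster effects
#' underlies both datasets (so cluster-specific predictions for "new
#' members of existing clusters" are meaningful on the validation data),
#' while covariates, exposures, sizes and outcomes are freshly drawn.
#' Validation cluster sizes follow the validation law of
#' [draw_cluster_sizes()].
#'
#' @param config A [scenario_config()].
#' @param replicate_seed Integer seed for this replicate; identical seeds
#'   give bitwise-identical pairs.
#' @return A list with elements `training`, `validation` (both
#'   `clustered_data`) and `effects`.
#' @export
generate_pair <- function(config, replicate_seed) {
  set.seed(as.integer(replicate_seed))
  effects <- draw_cluster_effects(config)
  list(training = simulate_dataset(effects, config, "training"),
       validation = simulate_dataset(effects, config, "validation"),
       effects = effects)
}

#' Read / write clustered datasets as CSV
#'
#' Long-format delimited text, one row per member, with a mandatory
#' header: `replicate, cluster_id, member_id, x1..x5, r, n, eta_true,
#' p_true, y`. The truth columns are optional on input (absent for real
#' data).
#'
#' @param data A `clustered_data` (or plain data frame with the same
#'   columns).
#' @param path File path.
#' @param replicate Replicate index written alongside the data.
#' @export
write_clustered_data <- function(data, path, replicate = 1L) {
  out <- data.frame(replicate = replicate, as.data.frame(data))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_clustered_data
#' @return For `read_clustered_data`, a `clustered_data` data frame.
#' @export
read_clustered_data <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  req <- c("cluster_id", "y")
  if (!all(req %in% names(d))) {
    stop("file must contain at least columns: ", paste(req, collapse = ", "))
  }
  if (!all(d$y %in% 0:1)) stop("`y` must be binary 0/1")
  if (!"n" %in% names(d)) {
    sz <- table(d$cluster_id)
    d$n <- as.integer(sz[as.character(d$cluster_id)])
  }
  class(d) <- c("clustered_data", "data.frame")
  d
}

#' @export
print.clustered_data <- function(x, ...) {
  K <- length(unique(x$cluster_id))
  cat(sprintf("clustered_data: %d members in %d clusters (mean size %.1f), outcome prevalence %.3f\n",
              nrow(x), K, nrow(x) / K, mean(x$y)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
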