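#' Scenario configuration for the clustered-data generator
#'
#' Bundles every parameter of the data-generating mechanism for one
#' simulation scenario: the number of clusters, the variances and pairwise
#' correlations of the three latent cluster effects (u drives the outcome
#' random intercept, v the exposure propensity, w the cluster size), the
#' cluster-size model, the exposure and outcome models, and the
#' validation-set cluster-size law used when cluster size is
#' non-informative.
#'
#' The three latent effects regulate the complications:
#' confounding by cluster (CBC) is on when `sigma_v2 > 0` and `rho_uv > 0`;
#' informative cluster size (ICS) is on when `sigma_w2 > 0` and
#' `rho_uw > 0`.
#'
#' @param K Number of clusters.
#' @param sigma_u2 Variance of the outcome random intercept u (logit scale).
#' @param sigma_v2 Variance of the exposure-propensity effect v.
#' @param sigma_w2 Variance of the cluster-size effect w.
#' @param rho_uv,rho_uw,rho_vw Pairwise correlations of the latent standard
#'   normals behind (u, v, w).
#' @param a0,a1 Cluster-size model parameters: sizes are
#'   Poisson(exp(a0 + a1 w) + 5).
#' @param gamma0 Exposure intercept on the logit scale; exposure is
#'   Bernoulli(plogis(gamma0 + v)).
#' @param beta0 Outcome intercept (logit scale).
#' @param beta Coefficient vector for (x1, x2, x3, x4, x5, r) in the outcome
#'   linear predictor.
#' @param validation_alpha_mean,validation_alpha_sd When ICS is off,
#'   validation cluster sizes are Poisson(exp(alpha)) with
#'   alpha ~ Normal(validation_alpha_mean, validation_alpha_sd^2), giving
#'   the larger validation clusters needed for stable performance measures.
#' @param n_reps Default replication count for study runs.
#' @param master_seed Default master seed for study runs.
#' @param scenario_tag Label: one of `"NONE"`, `"CBC"`, `"ICS"`,
#'   `"ICS+CBC-indep"`, `"ICS+CBC-related"`.
#' @return An object of class `scenario_config` (a named list).
#' @seealso [scenario_preset()] for the named study scenarios.
#' @export
scenario_config <- function(K = 30,
                            sigma_u2 = 0.82,
                            sigma_v2 = 0,
                            sigma_w2 = 0,
                            rho_uv = 0,
                            rho_uw = 0,
                            rho_vw = 0,
                            a0 = 4.5,
                            a1 = 1,
                            gamma0 = stats::qlogis(0.4),
                            beta0 = -1.5,
                            beta = rep(1, 6),
                            validation_alpha_mean = 5.7,
                            validation_alpha_sd = 0.3,
                            n_reps = 500L,
                            master_seed = 1L,
                            scenario_tag = NULL) {
  cfg <- list(
    K = as.integer(K), sigma_u2 = sigma_u2, sigma_v2 = sigma_v2,
    sigma_w2 = sigma_w2, rho_uv = rho_uv, rho_uw = rho_uw, rho_vw = rho_vw,
    a0 = a0, a1 = a1, gamma0 = gamma0, beta0 = beta0, beta = as.numeric(beta),
    validation_alpha_mean = validation_alpha_mean,
    validation_alpha_sd = validation_alpha_sd,
    n_reps = as.integer(n_reps), master_seed = as.integer(master_seed),
    scenario_tag = if (is.null(scenario_tag)) infer_scenario_tag(
      sigma_v2, sigma_w2, rho_uv, rho_uw, rho_vw) else scenario_tag
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

infer_scenario_tag <- function(sigma_v2, sigma_w2, rho_uv, rho_uw, rho_vw) {
  cbc <- sigma_v2 > 0 && rho_uv > 0
  ics <- sigma_w2 > 0 && rho_uw > 0
  if (cbc && ics) {
    if (rho_vw > 0) "ICS+CBC-related" else "ICS+CBC-indep"
  } else if (cbc) "CBC" else if (ics) "ICS" else "NONE"
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$K >= 1)
  for (v in c("sigma_u2", "sigma_v2", "sigma_w2")) {
    if (cfg[[v]] < 0) stop(sprintf("`%s` must be non-negative", v))
  }
  rho <- c(cfg$rho_uv, cfg$rho_uw, cfg$rho_vw)
  if (any(abs(rho) > 1)) stop("correlations must lie in [-1, 1]")
  ev <- eigen(effect_correlation_matrix(cfg), symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(paste0("correlation triple (rho_uv = %g, rho_uw = %g, ",
                        "rho_vw = %g) is not positive semi-definite"),
                 cfg$rho_uv, cfg$rho_uw, cfg$rho_vw))
  }
  if (length(cfg$beta) < 1) stop("`beta` must be a non-empty vector")
  # tag must be consistent with the effective CBC/ICS channels
  implied <- infer_scenario_tag(cfg$sigma_v2, cfg$sigma_w2,
                                cfg$rho_uv, cfg$rho_uw, cfg$rho_vw)
  if (!identical(cfg$scenario_tag, implied)) {
    stop(sprintf("scenario_tag '%s' inconsistent with parameters (implied '%s')",
                 cfg$scenario_tag, implied))
  }
  invisible(cfg)
}

effect_correlation_matrix <- function(cfg) {
  matrix(c(1, cfg$rho_uv, cfg$rho_uw,
           cfg$rho_uv, 1, cfg$rho_vw,
           cfg$rho_uw, cfg$rho_vw, 1), 3, 3,
         dimnames = list(c("u", "v", "w"), c("u", "v", "w")))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario '%s': K = %d clusters, sigma_u2 = %.3g (ICC %.3f)\n",
              x$scenario_tag, x$K, x$sigma_u2, variance_to_icc(x$sigma_u2)))
  cat(sprintf("  CBC channel: sigma_v2 = %.3g, rho_uv = %.2f\n",
              x$sigma_v2, x$rho_uv))
  cat(sprintf("  ICS channel: sigma_w2 = %.3g, rho_uw = %.2f (rho_vw = %.2f)\n",
              x$sigma_w2, x$rho_uw, x$rho_vw))
  cat(sprintf("  sizes ~ Poisson(exp(%.3g + %.3g w) + 5); gamma0 = %.3g; beta0 = %.3g\n",
              x$a0, x$a1, x$gamma0, x$beta0))
  invisible(x)
}

#' Named simulation-study scenarios
#'
#' Returns the configuration of the four study scenarios at a chosen degree
#' of clustering:
#' \describe{
#'   \item{S1}{no CBC, no ICS ("NONE"); both auxiliary channels fully off.}
#'   \item{S2}{CBC only: `sigma_v2 = sigma_u2`, `rho_uv = 0.7`.}
#'   \item{S3}{ICS only: `sigma_w2 = sigma_u2 / 2`, `rho_uw = 0.7`.}
#'   \item{S4-indep / S4-related}{both complications, with the two
#'     mechanisms independent (`rho_vw = 0`) or related (`rho_vw = 0.5`).}
#' }
#' The degree of clustering is set through `icc`: 0.2 maps to
#' `sigma_u2 = 0.82` and 0.1 to `sigma_u2 = 0.37`. With `rho = 0.7`,
#' roughly half of the between-cluster variance of u is linearly explained
#' by the active channel. Defaults give 30 clusters of average size
#' exp(4.5) + 5 (about 100), exposure prevalence about 40% and outcome
#' prevalence about 40%.
#'
#' @param scenario One of `"S1"`, `"S2"`, `"S3"`, `"S4-indep"`,
#'   `"S4-related"`.
#' @param icc Target intra-cluster correlation, 0.2 or 0.1 (other values
#'   are mapped through [icc_to_variance()]).
#' @param small_sample If `TRUE`, the supplementary small-sample variant:
#'   15 clusters, average size 50 (`a0 = log(45)`), outcome prevalence 15%
#'   with the intercept solved numerically by
#'   [solve_intercept_for_prevalence()].
#' @param ... Overrides passed on to [scenario_config()].
#' @return A `scenario_config`.
#' @export
scenario_preset <- function(scenario = c("S1", "S2", "S3", "S4-indep", "S4-related"),
                            icc = 0.2, small_sample = FALSE, ...) {
  scenario <- match.arg(scenario)
  sigma_u2 <- if (isTRUE(all.equal(icc, 0.2))) 0.82
  else if (isTRUE(all.equal(icc, 0.1))) 0.37
  else icc_to_variance(icc)
  args <- list(
    K = 30L, sigma_u2 = sigma_u2,
    sigma_v2 = 0, sigma_w2 = 0, rho_uv = 0, rho_uw = 0, rho_vw = 0
  )
  if (scenario %in% c("S2", "S4-indep", "S4-related")) {
    args$sigma_v2 <- sigma_u2
    args$rho_uv <- 0.7
  }
  if (scenario %in% c("S3", "S4-indep", "S4-related")) {
    args$sigma_w2 <- sigma_u2 / 2
    args$rho_uw <- 0.7
  }
  if (scenario == "S4-related") args$rho_vw <- 0.5
  if (small_sample) {
    args$K <- 15L
    args$a0 <- log(45)       # exp(a0) + 5 = 50 members on average
    args$a1 <- if (scenario %in% c("S3", "S4-indep", "S4-related")) 1 else 0
  }
  dots <- list(...)
  args[names(dots)] <- dots
  cfg <- do.call(scenario_config, args)
  if (small_sample && is.null(dots$beta0)) {
    cfg$beta0 <- solve_intercept_for_prevalence(cfg, target = 0.15)
  }
  cfg
}

#' Solve the outcome intercept for a target marginal prevalence
#'
#' Computes, by deterministic quadrature, the marginal outcome prevalence
#' implied by a configuration as a function of the intercept, and inverts
#' it with [stats::uniroot()]. The Gaussian part of the linear predictor
#' (three continuous covariates plus the random intercept) is integrated by
#' Gauss-Hermite quadrature and the three binary terms (two binary
#' covariates and the exposure) are enumerated. The exposure prevalence is
#' taken at `plogis(gamma0)`; the exposure-propensity effect v is averaged
#' out only through its marginal effect on prevalence, which is adequate
#' for the configurations this is used for (correlation between v and u is
#' ignored, so for strong-CBC configurations the result is approximate).
#'
#' @param config A `scenario_config`.
#' @param target Desired marginal outcome prevalence in (0, 1).
#' @param nodes Number of Gauss-Hermite nodes.
#' @return The intercept `beta0` achieving the target prevalence.
#' @export
solve_intercept_for_prevalence <- function(config, target, nodes = 41) {
  stopifnot(target > 0, target < 1)
  b <- config$beta
  # Gaussian variance: continuous covariates (fixed SDs 0.3, 0.4, 0.5) + u
  gvar <- sum((b[1:3] * c(0.3, 0.4, 0.5))^2) + config$sigma_u2
  gh <- pracma::gaussHermite(nodes)
  z <- sqrt(2 * gvar) * gh$x
  w <- gh$w / sqrt(pi)
  # enumerate the binary part: x4 ~ Bern(0.1), x5 ~ Bern(0.2), r ~ Bern(pr)
  pr <- stats::plogis(config$gamma0)
  combos <- expand.grid(x4 = 0:1, x5 = 0:1, r = 0:1)
  pcomb <- with(combos,
                ifelse(x4 == 1, 0.1, 0.9) * ifelse(x5 == 1, 0.2, 0.8) *
                  ifelse(r == 1, pr, 1 - pr))
  shift <- as.matrix(combos) %*% b[4:6]
  prev <- function(beta0) {
    m <- outer(drop(shift) + beta0, z, "+")
    sum(pcomb * (stats::plogis(m) %*% w))
  }
  stats::uniroot(function(b0) prev(b0) - target, lower = -20, upper = 20,
                 tol = 1e-10)$root
}

#' Derive reproducible per-replicate seeds from a master seed
#'
#' One master seed spawns a vector of independent replicate seeds so that
#' replicates are reproducible individually and can be distributed.
#'
#' @param master_seed Integer master seed.
#' @param n_reps Number of replicate seeds to derive.
#' @return Integer vector of length `n_reps`.
#' @export
replicate_seeds <- function(master_seed, n_reps) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n_reps)
}

#' Read / write a scenario configuration as YAML
#'
#' The file is a flat key/value mapping mirroring the `scenario_config`
#' field names (`beta` is a sequence).
#'
#' @param path File path.
#' @return For `read_scenario_config`, a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(scenario_config, raw)
}

#' @rdname read_scenario_config
#' @param config A `scenario_config` to serialise.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
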