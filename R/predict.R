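LP_CLAMP <- 35  # plogis(+/-35) stays strictly inside (0, 1) in double precision

new_prediction_set <- function(newdata, lp, type, fit, fallback = "none") {
  lp <- pmin(pmax(lp, -LP_CLAMP), LP_CLAMP)
  out <- data.frame(cluster_id = newdata$cluster_id,
                    member_id = if (!is.null(newdata$member_id))
                      newdata$member_id else seq_len(nrow(newdata)),
                    linear_predictor = lp,
                    probability = plogis(lp))
  attr(out, "type") <- type
  attr(out, "method") <- fit$spec$method
  attr(out, "adjustment") <- fit$spec$adjustment
  attr(out, "fallback") <- fallback
  class(out) <- c("prediction_set", "data.frame")
  out
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("prediction_set (%s, %s/%s): %d members, mean probability %.3f\n",
              attr(x, "type"), attr(x, "method"), attr(x, "adjustment"),
              nrow(x), mean(x$probability)))
  invisible(x)
}

# fixed-effect linear predictor of a fit on new data; cluster-level
# covariates (rbar, cluster size) are recomputed from the new data unless
# the population fallback is requested
fixed_lp <- function(fit, newdata, fallback = c("none", "population")) {
  fallback <- match.arg(fallback)
  des <- build_design(newdata, fit$spec)
  if (fallback == "population") {
    if ("rbar" %in% colnames(des$x)) des$x[, "rbar"] <- fit$training_rbar
    for (v in names(fit$terms)[fit$terms == "cluster_size"]) {
      des$data$nsize <- fit$training_n
      des$x[, v] <- g_n_columns(des$data, fit$spec)[[v]]
    }
  }
  need <- names(fit$coefficients)
  if (!all(need %in% colnames(des$x))) {
    stop("new data cannot supply design column(s): ",
         paste(setdiff(need, colnames(des$x)), collapse = ", "))
  }
  drop(des$x[, need, drop = FALSE] %*% fit$coefficients)
}

#' Conditional (cluster-specific) predictions from a GLMM fit
#'
#' Predicted probability plogis(alpha + u_i + x' beta) using the empirical
#' Bayes estimate of the cluster's random effect (`mode = "known_u"`), or
#' with the random effect set to zero (`mode = "u_zero"`), the latter
#' representing an average-risk cluster.
#'
#' @param fit A `glmm_fit`.
#' @param newdata Data frame of new members; under `known_u` every cluster
#'   must have been present in the training data.
#' @param mode `"known_u"` or `"u_zero"`.
#' @return A `prediction_set`.
#' @export
predict_conditional <- function(fit, newdata, mode = c("known_u", "u_zero")) {
  mode <- match.arg(mode)
  if (!inherits(fit, "glmm_fit")) {
    stop("conditional predictions require a GLMM fit")
  }
  lp <- fixed_lp(fit, newdata)
  if (mode == "known_u") {
    u <- fit$u_hat[as.character(newdata$cluster_id)]
    if (anyNA(u)) {
      stop("cluster(s) ",
           paste(unique(newdata$cluster_id[is.na(u)]), collapse = ", "),
           " were not in the training data; no random-effect estimate is ",
           "available - use marginal predictions for new clusters")
    }
    lp <- lp + unname(u)
  }
  new_prediction_set(newdata, lp,
                     if (mode == "known_u") "conditional_known_u"
                     else "conditional_u0", fit)
}

gh_scheme <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Marginal predictions from a GLMM fit
#'
#' Population-average probabilities for members without an assumed
#' cluster. `method = "integrate"` computes
#' p = Int plogis(eta + u) dN(u; 0, sigma_u2_hat) by Gauss-Hermite
#' quadrature. `method = "zeger"` uses the attenuation approximation: the
#' conditional linear predictor is scaled by
#' (1 + c^2 sigma_u2_hat)^(-1/2) with c = 16 sqrt(3) / (15 pi), avoiding
#' numerical integration; the two agree closely across the probability
#' range.
#'
#' @param fit A `glmm_fit`.
#' @param newdata Data frame of new members.
#' @param method `"integrate"` or `"zeger"`.
#' @param nodes Quadrature nodes for `"integrate"`.
#' @param fallback `"none"` (cluster-level covariates computed from
#'   `newdata`) or `"population"` (use the training-population mean of
#'   rbar and median cluster size, for members whose cluster information
#'   is unavailable; recorded in the prediction attributes).
#' @return A `prediction_set` with the marginal linear predictor
#'   (logit of the marginal probability).
#' @export
predict_marginal_glmm <- function(fit, newdata, method = c("integrate", "zeger"),
                                  nodes = 21, fallback = c("none", "population")) {
  method <- match.arg(method)
  fallback <- match.arg(fallback)
  if (!inherits(fit, "glmm_fit")) stop("requires a GLMM fit")
  eta0 <- fixed_lp(fit, newdata, fallback)
  s2 <- fit$sigma_u2_hat
  if (method == "integrate") {
    gh <- gh_scheme(nodes)
    p <- drop(plogis(outer(eta0, sqrt(s2) * gh$z, "+")) %*% gh$w)
    lp <- qlogis(pmin(pmax(p, 1e-15), 1 - 1e-15))
    type <- "marginal_integrated"
  } else {
    cz <- 16 * sqrt(3) / (15 * pi)
    lp <- eta0 / sqrt(1 + cz^2 * s2)
    type <- "marginal_zeger"
  }
  new_prediction_set(newdata, lp, type, fit, fallback)
}

#' Marginal predictions from a marginal (GEE/IEE) fit
#'
#' p = plogis(alpha_M + x' beta_M) using the estimated marginal
#' coefficients directly.
#'
#' @param fit A `marginal_fit` from [fit_gee()] or [fit_iee()].
#' @inheritParams predict_marginal_glmm
#' @return A `prediction_set`.
#' @export
predict_from_marginal_fit <- function(fit, newdata,
                                      fallback = c("none", "population")) {
  fallback <- match.arg(fallback)
  if (!inherits(fit, "marginal_fit")) stop("requires a GEE/IEE fit")
  lp <- fixed_lp(fit, newdata, fallback)
  new_prediction_set(newdata, lp, "marginal_model", fit, fallback)
}

#' Marginal log-likelihood of one cluster by quadrature
#'
#' log of Int prod_j p_j(u)^{y_j} (1 - p_j(u))^{1 - y_j} dN(u; 0, sigma_u^2)
#' with p_j(u) = plogis(eta_j + u), computed by Gauss-Hermite quadrature.
#' This is the single-cluster contribution to the random-intercept
#' marginal likelihood and is used to validate the quadrature scheme
#' against Monte-Carlo integration.
#'
#' @param y Binary outcomes of the cluster's members.
#' @param eta_fixed Fixed-effect linear predictors of the members.
#' @param sigma_u Random-intercept standard deviation.
#' @param nodes Number of quadrature nodes.
#' @return The log marginal likelihood contribution (a scalar).
#' @export
cluster_marginal_loglik <- function(y, eta_fixed, sigma_u, nodes = 21) {
  stopifnot(length(y) == length(eta_fixed), all(y %in% 0:1))
  gh <- gh_scheme(nodes)
  u <- sigma_u * gh$z
  # log-integrand at each node, summed over members
  lli <- vapply(u, function(ui) {
    eta <- eta_fixed + ui
    sum(ifelse(y == 1, plogis(eta, log.p = TRUE), plogis(-eta, log.p = TRUE)))
  }, 0)
  m <- max(lli + log(gh$w))
  m + log(sum(exp(lli + log(gh$w) - m)))
}
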