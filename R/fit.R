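#' @importFrom stats coef vcov plogis qlogis
NULL

new_cluster_fit <- function(subclass, spec, coefficients, se, vcov, terms,
                            cluster_ids, loglik = NA_real_, converged = TRUE,
                            n_iter = NA_integer_, ...) {
  out <- list(spec = spec, coefficients = coefficients, se = se, vcov = vcov,
              terms = terms, cluster_ids = cluster_ids, loglik = loglik,
              converged = converged, n_iter = n_iter, ...)
  class(out) <- c(subclass, "cluster_fit")
  out
}

#' @export
coef.cluster_fit <- function(object, ...) object$coefficients

#' @export
vcov.cluster_fit <- function(object, ...) object$vcov

#' @export
logLik.cluster_fit <- function(object, ...) object$loglik

#' @export
print.cluster_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s adjustment)%s\n",
              toupper(x$spec$method), x$spec$adjustment,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  print(round(tab, 4))
  if (!is.null(x$sigma_u2_hat)) {
    cat(sprintf("sigma_u2_hat = %.4f (ICC %.3f)\n", x$sigma_u2_hat,
                variance_to_icc(x$sigma_u2_hat)))
  }
  invisible(x)
}

check_binary_outcome <- function(y) {
  if (is.null(y)) stop("data must contain an outcome column `y`")
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
}

# complete-separation guard: a huge coefficient on the standardised design
check_separation <- function(est, x, threshold = 15) {
  sds <- apply(x, 2, stats::sd)
  sds[colnames(x) == "(Intercept)"] <- 0   # intercept exempt
  bad <- which(abs(est * sds) > threshold)
  if (length(bad)) {
    stop("apparent complete separation: coefficient for column(s) ",
         paste(colnames(x)[bad], collapse = ", "),
         " diverges on the standardised design")
  }
}

#' Fit the random-intercept logistic model (GLMM)
#'
#' Maximum likelihood via [lme4::glmer()] with adaptive Gauss-Hermite
#' quadrature (21 nodes by default) for the single random intercept.
#' Standard errors come from the observed information at the ML solution.
#' Cluster-level adjustments (cluster mean of the exposure, functions of
#' cluster size) are added according to the [model_spec()].
#'
#' @param data A `clustered_data` with outcome column `y`.
#' @param spec A [model_spec()] with `method = "glmm"`.
#' @param nAGQ Number of adaptive quadrature nodes (1 = Laplace).
#' @return A `glmm_fit` with coefficients, SEs, `sigma_u2_hat` (estimated
#'   random-intercept variance), `u_hat` (empirical Bayes cluster effects,
#'   posterior modes), log-likelihood and a convergence flag.
#' @export
fit_glmm <- function(data, spec = model_spec("glmm"), nAGQ = 21) {
  stopifnot(spec$method == "glmm")
  des <- build_design(data, spec)
  check_binary_outcome(des$y)
  if (length(unique(des$cluster_id)) < 2) stop("need at least 2 clusters")
  preds <- setdiff(colnames(des$x), "(Intercept)")
  df <- data.frame(y = des$y, cluster_id = des$cluster_id,
                   des$x[, preds, drop = FALSE])
  fml <- stats::reformulate(c(preds, "(1 | cluster_id)"), response = "y")
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::glmer(fml, data = df, family = stats::binomial(), nAGQ = nAGQ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est <- lme4::fixef(fit)
  check_separation(est, des$x)
  V <- as.matrix(vcov(fit))
  re <- lme4::ranef(fit)$cluster_id
  u_hat <- stats::setNames(re[, 1], rownames(re))
  conv <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  new_cluster_fit(
    "glmm_fit", spec, est, sqrt(diag(V)), V, des$terms,
    cluster_ids = sort(unique(des$cluster_id)),
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv, n_iter = as.integer(fit@optinfo$feval),
    sigma_u2_hat = as.numeric(lme4::VarCorr(fit)$cluster_id),
    u_hat = u_hat, nAGQ = nAGQ, lme4_fit = fit,
    training_rbar = mean(des$data$rbar), training_n = stats::median(des$data$nsize),
    warnings = msgs)
}

#' Empirical Bayes estimates of the cluster random effects
#'
#' Returns the posterior modes of the cluster random intercepts given the
#' cluster data and the ML parameter estimates. These shrink toward zero
#' as the cluster carries less information and as the estimated
#' random-intercept variance shrinks.
#'
#' @param fit A `glmm_fit`.
#' @return Named numeric vector of per-cluster effects.
#' @export
empirical_bayes <- function(fit) {
  if (!inherits(fit, "glmm_fit")) {
    stop("empirical Bayes effects are only defined for GLMM fits")
  }
  fit$u_hat
}

#' Fit the marginal logistic model by pooled ML with robust SEs (IEE)
#'
#' Independence estimating equations: the point estimates are those of
#' ordinary logistic regression ignoring clustering, and the standard
#' errors are cluster-robust (sandwich) so that inference accounts for the
#' within-cluster correlation.
#'
#' @inheritParams fit_glmm
#' @param spec A [model_spec()] with `method = "iee"`.
#' @return A `marginal_fit`.
#' @export
fit_iee <- function(data, spec = model_spec("iee")) {
  stopifnot(spec$method == "iee")
  des <- build_design(data, spec)
  check_binary_outcome(des$y)
  df <- data.frame(y = des$y,
                   des$x[, setdiff(colnames(des$x), "(Intercept)"), drop = FALSE])
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
  V <- sandwich::vcovCL(fit, cluster = des$cluster_id)
  est <- coef(fit)
  names(est) <- colnames(des$x)
  dimnames(V) <- list(names(est), names(est))
  new_cluster_fit(
    "marginal_fit", spec, est, sqrt(diag(V)), V, des$terms,
    cluster_ids = sort(unique(des$cluster_id)),
    loglik = as.numeric(stats::logLik(fit)),
    converged = fit$converged, n_iter = fit$iter,
    working = "independence", alpha_hat = 0,
    training_rbar = mean(des$data$rbar), training_n = stats::median(des$data$nsize))
}

#' Fit the marginal logistic model by GEE
#'
#' Solves the generalised estimating equations for a logistic marginal
#' model under an exchangeable (or independence) working correlation.
#' The exchangeable correlation parameter is estimated by the standard
#' moment (Pearson-residual) equations, alternating with Fisher-scoring
#' updates of the regression coefficients until joint convergence; the
#' scale parameter is fixed at 1 as usual for binary outcomes. Standard
#' errors are robust (sandwich). The compound-symmetry working inverse is
#' applied in closed form, so large clusters cost no matrix factorisation.
#'
#' @inheritParams fit_glmm
#' @param spec A [model_spec()] with `method = "gee"`.
#' @param working Working correlation structure.
#' @param tol Joint convergence tolerance on coefficient and alpha updates.
#' @param max_iter Maximum number of outer iterations.
#' @return A `marginal_fit` with `alpha_hat`, robust `vcov` and a
#'   convergence flag.
#' @export
fit_gee <- function(data, spec = model_spec("gee"),
                    working = c("exchangeable", "independence"),
                    tol = 1e-6, max_iter = 100) {
  stopifnot(spec$method %in% c("gee", "iee"))
  working <- match.arg(working)
  des <- build_design(data, spec)
  check_binary_outcome(des$y)
  x <- des$x
  y <- des$y
  idx <- split(seq_along(y), des$cluster_id)
  p <- ncol(x)

  beta <- coef(stats::glm.fit(x, y, family = stats::binomial()))
  alpha <- 0
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    sdv <- sqrt(mu * (1 - mu))
    e <- (y - mu) / sdv
    if (working == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        ni <- length(ix)
        if (ni < 2) next
        s <- sum(e[ix])
        num <- num + (s^2 - sum(e[ix]^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      alpha_new <- num / (den - p)
      alpha_new <- max(min(alpha_new, 0.95), -0.05)
    } else alpha_new <- 0
    B <- matrix(0, p, p)
    g <- numeric(p)
    for (ix in idx) {
      ni <- length(ix)
      U <- x[ix, , drop = FALSE] * sdv[ix]
      c1 <- 1 / (1 - alpha_new)
      c2 <- alpha_new / (1 + (ni - 1) * alpha_new)
      u1 <- colSums(U)
      B <- B + c1 * (crossprod(U) - c2 * tcrossprod(u1))
      g <- g + c1 * (drop(crossprod(U, e[ix])) - c2 * sum(e[ix]) * u1)
    }
    step <- solve(B, g)
    beta <- beta + step
    delta <- max(abs(step), abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # robust sandwich at the solution
  eta <- drop(x %*% beta)
  mu <- plogis(eta)
  sdv <- sqrt(mu * (1 - mu))
  e <- (y - mu) / sdv
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ix in idx) {
    ni <- length(ix)
    U <- x[ix, , drop = FALSE] * sdv[ix]
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 + (ni - 1) * alpha)
    u1 <- colSums(U)
    B <- B + c1 * (crossprod(U) - c2 * tcrossprod(u1))
    gi <- c1 * (drop(crossprod(U, e[ix])) - c2 * sum(e[ix]) * u1)
    M <- M + tcrossprod(gi)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  est <- stats::setNames(drop(beta), colnames(x))
  dimnames(V) <- list(names(est), names(est))
  new_cluster_fit(
    "marginal_fit", spec, est, sqrt(diag(V)), V, des$terms,
    cluster_ids = sort(unique(des$cluster_id)),
    converged = converged, n_iter = iter,
    working = working, alpha_hat = alpha,
    training_rbar = mean(des$data$rbar), training_n = stats::median(des$data$nsize))
}

# log(exp(a) + exp(b)) elementwise, tolerating -Inf
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  lo <- pmin(a, b)
  out <- m + log1p(exp(lo - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# log of the elementary symmetric function e_m(exp(eta)) via the standard
# two-term recurrence, entirely in log space so clusters of size 100 with
# large totals cannot underflow or overflow
log_esym <- function(eta, m) {
  if (m == 0) return(0)
  logE <- c(0, rep(-Inf, m))
  for (e1 in eta) {
    logE[-1] <- log_add_exp(logE[-1], logE[-(m + 1)] + e1)
  }
  logE[m + 1]
}

cml_loglik <- function(beta, ylist, xlist) {
  ll <- 0
  for (i in seq_along(ylist)) {
    eta <- drop(xlist[[i]] %*% beta)
    yi <- ylist[[i]]
    ll <- ll + sum(eta[yi == 1]) - log_esym(eta, sum(yi))
  }
  ll
}

#' Fit within-cluster effects by conditional maximum likelihood
#'
#' Conditions on the cluster event totals, eliminating all cluster-level
#' information (including the random intercepts, whatever their
#' relationship with the exposure), and maximises the resulting
#' conditional likelihood for the member-level coefficients. The
#' denominator (an elementary symmetric function over all within-cluster
#' event configurations) is computed by the standard recurrence in log
#' space. Clusters whose outcomes are all 0 or all 1 contribute a constant
#' factor and are dropped. Because the cluster is conditioned out, CML is
#' immune to confounding by cluster and serves as the reference
#' within-cluster estimate in the CBC diagnostic.
#'
#' @param data A `clustered_data` with outcome `y`.
#' @param predictors Member-level columns to include (no intercept; it is
#'   not identified). Cluster-constant columns are rejected.
#' @return A `cml_fit` with coefficients, observed-information SEs and the
#'   maximised conditional log-likelihood.
#' @export
fit_cml <- function(data, predictors = c(paste0("x", 1:5), "r")) {
  data <- as.data.frame(data)
  miss <- setdiff(c("cluster_id", "y", predictors), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  check_binary_outcome(data$y)
  x <- as.matrix(data[predictors])
  idx <- split(seq_len(nrow(data)), data$cluster_id)
  # reject columns that are constant within every cluster
  wvar <- vapply(predictors, function(v) {
    max(vapply(idx, function(ix) stats::var(data[[v]][ix]), 0), na.rm = TRUE)
  }, 0)
  if (any(wvar == 0)) {
    stop("cluster-constant column(s) supplied to CML: ",
         paste(predictors[wvar == 0], collapse = ", "),
         " (conditioned out, not estimable)")
  }
  keep <- vapply(idx, function(ix) {
    s <- sum(data$y[ix]); s > 0 && s < length(ix)
  }, TRUE)
  if (!any(keep)) {
    stop("no information after conditioning: every cluster is concordant ",
         "(all events or all non-events)")
  }
  idx <- idx[keep]
  ylist <- lapply(idx, function(ix) data$y[ix])
  xlist <- lapply(idx, function(ix) x[ix, , drop = FALSE])
  p <- length(predictors)
  opt <- stats::optim(rep(0, p), function(b) -cml_loglik(b, ylist, xlist),
                      method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  V <- solve(opt$hessian)
  est <- stats::setNames(opt$par, predictors)
  check_separation(est, x)
  dimnames(V) <- list(predictors, predictors)
  new_cluster_fit(
    "cml_fit", model_spec("cml"), est, sqrt(diag(V)), V,
    terms = stats::setNames(rep("covariate", p), predictors),
    cluster_ids = sort(unique(data$cluster_id[unlist(idx)])),
    loglik = -opt$value, converged = opt$convergence == 0,
    n_iter = as.integer(opt$counts[1]),
    n_informative_clusters = sum(keep))
}

#' Serialise a fit result to delimited text
#'
#' Writes a metadata block (`# key: value` comment lines: method,
#' adjustment, sigma_u2_hat, loglik, converged) followed by a CSV table
#' with columns term, estimate, se, z.
#'
#' @param fit A `cluster_fit`.
#' @param path Output path.
#' @export
write_fit_result <- function(fit, path) {
  meta <- c(method = fit$spec$method, adjustment = fit$spec$adjustment,
            sigma_u2_hat = if (is.null(fit$sigma_u2_hat)) NA else fit$sigma_u2_hat,
            loglik = fit$loglik, converged = fit$converged)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = fit$coefficients, se = fit$se,
                    z = fit$coefficients / fit$se)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}
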