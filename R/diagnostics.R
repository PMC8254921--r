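#' Per-cluster summary statistics
#'
#' One row per cluster with size, event proportion and exposure
#' proportion. Plotting the event proportion against the exposure
#' proportion (or against the size) is the exploratory first look for
#' confounding by cluster (or informative cluster size).
#'
#' @param data A `clustered_data`.
#' @param exposure Name of the exposure column (NULL to skip).
#' @return Data frame with columns `cluster_id`, `n`, `event_prop`,
#'   `exposure_prop`.
#' @export
cluster_summaries <- function(data, exposure = "r") {
  data <- as.data.frame(data)
  cl <- split(seq_len(nrow(data)), data$cluster_id)
  out <- data.frame(
    cluster_id = names(cl),
    n = vapply(cl, length, 0L),
    event_prop = vapply(cl, function(ix) mean(data$y[ix]), 0),
    exposure_prop = if (!is.null(exposure) && exposure %in% names(data)) {
      vapply(cl, function(ix) mean(data[[exposure]][ix]), 0)
    } else NA_real_,
    row.names = NULL
  )
  out
}

#' Diagnose confounding by cluster
#'
#' Fits the exposure effect three ways — conditional maximum likelihood
#' (immune to CBC), the basic GLMM and the basic IEE — and compares the
#' estimates. Without CBC the marginal (IEE) coefficient is attenuated
#' toward zero relative to the cluster-specific ones; a marginal estimate
#' that instead exceeds the CML estimate in magnitude beyond the margin is
#' the classic distortion suggestive of CBC. The between-cluster
#' variation in the exposure proportion and in the event proportion
#' (necessary conditions for CBC) is also reported.
#'
#' @param data A `clustered_data`.
#' @param predictors Member-level covariate columns.
#' @param exposure Exposure column; must vary within at least one cluster.
#' @param margin_factor The distortion flag fires when
#'   |beta_IEE| - |beta_CML| exceeds `margin_factor` times the larger of
#'   the two standard errors. The comparison is informal; the margin is a
#'   configurable implementation choice (default one half).
#' @param nAGQ Quadrature nodes for the GLMM fit.
#' @return A `cbc_diagnostic` list: `coefficients` (CML/GLMM/IEE exposure
#'   estimate and SE), `distortion` (signed magnitude
#'   |beta_IEE| - |beta_CML|), `flag`, `margin`, `cluster_table`, and the
#'   SDs of the per-cluster exposure and event proportions.
#' @export
cbc_diagnostic <- function(data, predictors = paste0("x", 1:5), exposure = "r",
                           margin_factor = 0.5, nAGQ = 21) {
  data <- as.data.frame(data)
  wvar <- stats::ave(data[[exposure]], data$cluster_id, FUN = stats::var)
  if (all(wvar == 0)) {
    stop("CBC undefined for cluster-constant exposure: '", exposure,
         "' does not vary within any cluster")
  }
  spec_args <- list(covariates = predictors, exposure = exposure)
  cml <- fit_cml(data, predictors = c(predictors, exposure))
  glmm <- fit_glmm(data, do.call(model_spec,
                                 c(list(method = "glmm"), spec_args)), nAGQ = nAGQ)
  iee <- fit_iee(data, do.call(model_spec, c(list(method = "iee"), spec_args)))
  pick <- function(f) c(est = unname(coef(f)[exposure]),
                        se = unname(f$se[exposure]))
  tab <- rbind(cml = pick(cml), glmm = pick(glmm), iee = pick(iee))
  distortion <- abs(tab["iee", "est"]) - abs(tab["cml", "est"])
  margin <- margin_factor * max(tab["iee", "se"], tab["cml", "se"])
  cs <- cluster_summaries(data, exposure)
  out <- list(coefficients = tab,
              distortion = distortion,
              flag = distortion > margin,
              margin = margin,
              margin_factor = margin_factor,
              exposure_prop_sd = stats::sd(cs$exposure_prop),
              event_prop_sd = stats::sd(cs$event_prop),
              cluster_table = cs)
  class(out) <- "cbc_diagnostic"
  out
}

#' @export
print.cbc_diagnostic <- function(x, ...) {
  cat("Confounding-by-cluster diagnostic\n")
  cat(sprintf("  exposure coefficient: CML %.3f (SE %.3f), GLMM %.3f (SE %.3f), IEE %.3f (SE %.3f)\n",
              x$coefficients["cml", "est"], x$coefficients["cml", "se"],
              x$coefficients["glmm", "est"], x$coefficients["glmm", "se"],
              x$coefficients["iee", "est"], x$coefficients["iee", "se"]))
  cat(sprintf("  |IEE| - |CML| = %.3f (margin %.3f): %s\n",
              x$distortion, x$margin,
              if (x$flag) "DISTORTION - suggestive of CBC"
              else "no distortion beyond margin"))
  cat(sprintf("  between-cluster SD: exposure proportion %.3f, event proportion %.3f\n",
              x$exposure_prop_sd, x$event_prop_sd))
  invisible(x)
}

#' Test for informative cluster size
#'
#' Adds g(N) to the random-intercept model alongside the other predictors
#' and Wald-tests its coefficient: a significant cluster-size effect
#' indicates that the size is informative and worth keeping in the risk
#' model.
#'
#' @param data A `clustered_data`; cluster size must vary.
#' @param predictors Member-level covariate columns.
#' @param exposure Exposure column included among the predictors.
#' @param g_n Transform of cluster size passed to [model_spec()].
#' @param nAGQ Quadrature nodes for the GLMM fit.
#' @return A list of class `ics_test` with `delta_hat`, `se`, `statistic`,
#'   `p_value` (two-sided Wald; for multi-column g a joint chi-squared
#'   test) and the underlying `fit`.
#' @export
ics_test <- function(data, predictors = paste0("x", 1:5), exposure = "r",
                     g_n = "identity", nAGQ = 21) {
  data <- as.data.frame(data)
  sizes <- table(data$cluster_id)
  if (length(unique(as.integer(sizes))) < 2) {
    stop("ICS does not arise when the cluster size is constant")
  }
  spec <- model_spec("glmm", adjustment = "size", g_n = g_n,
                     covariates = predictors, exposure = exposure)
  fit <- fit_glmm(data, spec, nAGQ = nAGQ)
  sz <- names(fit$terms)[fit$terms == "cluster_size"]
  est <- coef(fit)[sz]
  if (length(sz) == 1) {
    z <- est / fit$se[sz]
    p <- 2 * stats::pnorm(-abs(z))
    stat <- unname(z)
  } else {
    V <- vcov(fit)[sz, sz]
    stat <- drop(t(est) %*% solve(V, est))
    p <- stats::pchisq(stat, df = length(sz), lower.tail = FALSE)
  }
  out <- list(delta_hat = est, se = fit$se[sz], statistic = stat,
              p_value = unname(p), g_n = g_n, fit = fit)
  class(out) <- "ics_test"
  out
}

#' @export
print.ics_test <- function(x, ...) {
  cat(sprintf("Informative-cluster-size test (g = %s)\n", x$g_n))
  cat(sprintf("  delta_hat = %s, SE = %s, p = %.4g: %s\n",
              paste(signif(x$delta_hat, 3), collapse = ", "),
              paste(signif(x$se, 3), collapse = ", "), x$p_value,
              if (x$p_value < 0.05) "evidence of ICS" else "no evidence of ICS"))
  invisible(x)
}
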