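fit_for_spec <- function(data, spec, nAGQ = 21) {
  switch(spec$method,
    glmm = fit_glmm(data, spec, nAGQ = nAGQ),
    gee = fit_gee(data, spec, working = "exchangeable"),
    iee = fit_iee(data, spec),
    cml = stop("CML provides within-cluster effects, not risk predictions; ",
               "use it through cbc_diagnostic()"))
}

predict_for_spec <- function(fit, newdata, prediction_type,
                             marginal_method = "integrate") {
  if (prediction_type == "conditional") {
    if (!inherits(fit, "glmm_fit")) {
      stop("conditional predictions require a GLMM fit")
    }
    predict_conditional(fit, newdata, mode = "known_u")
  } else if (inherits(fit, "glmm_fit")) {
    predict_marginal_glmm(fit, newdata, method = marginal_method)
  } else {
    predict_from_marginal_fit(fit, newdata)
  }
}

#' Run one cell of the simulation study
#'
#' For each replicate: generate a paired training/validation dataset under
#' the scenario, fit the requested model on the training data, predict on
#' the validation data, and evaluate calibration, discrimination, RPMSE
#' and Brier score. Replicates whose fit throws an error are excluded and
#' counted, never silently averaged; the convergence flag of retained
#' fits is carried in the results.
#'
#' @param config A [scenario_config()].
#' @param spec A [model_spec()] (method `"glmm"`, `"gee"` or `"iee"`).
#' @param prediction_type `"marginal"` or `"conditional"` (GLMM only).
#' @param n_reps Number of replicates.
#' @param master_seed Master seed; per-replicate seeds are derived with
#'   [replicate_seeds()], so any cell rerun with the same master seed is
#'   identical.
#' @param nAGQ Quadrature nodes for GLMM fits.
#' @param marginal_method Marginalisation route for GLMM marginal
#'   predictions: `"integrate"` (default) or `"zeger"`.
#' @param progress Print per-replicate progress to stderr.
#' @return A list of class `cell_result`: `results` (one row per retained
#'   replicate with the performance measures and, for GLMM, the estimated
#'   random-intercept variance), `summary` (across-replicate means and
#'   Monte-Carlo SEs from [aggregate_results()]), `n_failed`, `failures`.
#' @export
run_cell <- function(config, spec, prediction_type = c("marginal", "conditional"),
                     n_reps = 100, master_seed = 1L, nAGQ = 21,
                     marginal_method = "integrate", progress = FALSE) {
  prediction_type <- match.arg(prediction_type)
  if (spec$method == "cml") {
    stop("CML provides within-cluster effects, not risk predictions; ",
         "use it through cbc_diagnostic()")
  }
  if (prediction_type == "conditional" && spec$method != "glmm") {
    stop("conditional predictions are only available for GLMM")
  }
  seeds <- replicate_seeds(master_seed, n_reps)
  rows <- vector("list", n_reps)
  failures <- character()
  for (i in seq_len(n_reps)) {
    res <- tryCatch({
      pair <- generate_pair(config, seeds[i])
      fit <- fit_for_spec(pair$training, spec, nAGQ = nAGQ)
      pred <- predict_for_spec(fit, pair$validation, prediction_type,
                               marginal_method)
      perf <- performance_summary(pred, pair$validation, tags = list(
        scenario = config$scenario_tag,
        icc = variance_to_icc(config$sigma_u2),
        replicate = i, seed = seeds[i]))
      perf$sigma_u2_hat <- if (!is.null(fit$sigma_u2_hat))
        fit$sigma_u2_hat else NA_real_
      perf$converged <- fit$converged
      perf
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("replicate %d: %s", i, res))
    } else {
      rows[[i]] <- res
    }
    if (progress) {
      message(sprintf("replicate %d/%d %s", i, n_reps,
                      if (is.character(res)) "FAILED" else "done"))
    }
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out <- list(results = results,
              summary = if (!is.null(results)) aggregate_results(results),
              n_failed = length(failures), failures = failures,
              config = config, spec = spec,
              prediction_type = prediction_type)
  class(out) <- "cell_result"
  out
}

#' @export
print.cell_result <- function(x, ...) {
  cat(sprintf("cell_result: %s %s/%s, %s predictions; %d replicates kept, %d failed\n",
              x$config$scenario_tag, x$spec$method, x$spec$adjustment,
              x$prediction_type,
              if (is.null(x$results)) 0L else nrow(x$results), x$n_failed))
  if (!is.null(x$summary)) print(x$summary, digits = 3)
  invisible(x)
}

#' Aggregate per-replicate performance rows
#'
#' Long-format study table keyed by (scenario, icc, method, adjustment,
#' prediction_type, metric) with the across-replicate mean, Monte-Carlo
#' standard error (sd / sqrt(n)) and the number of replicates entering
#' each mean.
#'
#' @param results Per-replicate rows as produced by [run_cell()] (possibly
#'   rbind-ed across cells).
#' @param metrics Metric columns to aggregate.
#' @return A long-format data frame with columns `mean`, `mc_se`,
#'   `n_effective`.
#' @export
aggregate_results <- function(results,
                              metrics = c("calibration_intercept",
                                          "calibration_slope", "c_statistic",
                                          "rpmse", "brier", "sigma_u2_hat")) {
  if (is.null(results) || nrow(results) == 0) stop("no results to aggregate")
  metrics <- intersect(metrics, names(results))
  keys <- intersect(c("scenario", "icc", "method", "adjustment",
                      "prediction_type"), names(results))
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(results[keys], metric = m, value = results[[m]])
  }))
  long <- long[!is.na(long$value), , drop = FALSE]
  if (nrow(long) == 0) stop("no non-missing metric values to aggregate")
  mu <- stats::aggregate(value ~ ., data = long, FUN = mean)
  se <- stats::aggregate(value ~ ., data = long,
                         FUN = function(v) stats::sd(v) / sqrt(length(v)))
  nn <- stats::aggregate(value ~ ., data = long, FUN = length)
  names(mu)[names(mu) == "value"] <- "mean"
  mu$mc_se <- se$value
  mu$n_effective <- nn$value
  mu
}

#' Run a grid of study cells
#'
#' Convenience wrapper looping [run_cell()] over scenarios, methods,
#' adjustments and prediction types. Cells that are not computable
#' (conditional predictions from a marginal method) are skipped.
#'
#' @param scenarios Character vector of [scenario_preset()] names.
#' @param icc Intra-cluster correlation for the presets.
#' @param methods Subset of `c("glmm", "gee", "iee")`.
#' @param adjustments Subset of `c("basic", "rbar", "size", "both")`.
#' @param prediction_types Subset of `c("marginal", "conditional")`.
#' @param n_reps,master_seed,nAGQ,marginal_method Passed to [run_cell()].
#' @param ... Overrides passed to [scenario_preset()].
#' @return A list with `results` (all per-replicate rows), `summary`
#'   (aggregated long table) and `cells` (the individual `cell_result`s).
#' @export
run_study <- function(scenarios = c("S1", "S2", "S3"), icc = 0.2,
                      methods = c("glmm", "gee", "iee"),
                      adjustments = "basic",
                      prediction_types = c("marginal", "conditional"),
                      n_reps = 100, master_seed = 1L, nAGQ = 21,
                      marginal_method = "integrate", ...) {
  cells <- list()
  for (sc in scenarios) {
    config <- scenario_preset(sc, icc = icc, ...)
    for (m in methods) for (a in adjustments) for (pt in prediction_types) {
      if (pt == "conditional" && m != "glmm") next
      spec <- model_spec(m, adjustment = a)
      key <- paste(sc, m, a, pt, sep = ".")
      cells[[key]] <- run_cell(config, spec, pt, n_reps = n_reps,
                               master_seed = master_seed, nAGQ = nAGQ,
                               marginal_method = marginal_method)
    }
  }
  results <- do.call(rbind, lapply(cells, `[[`, "results"))
  list(results = results, summary = aggregate_results(results), cells = cells)
}

#' Optimism-corrected performance by cluster bootstrap
#'
#' Internal validation of a model on a single dataset: clusters (not
#' members) are resampled with replacement to respect the correlation
#' structure, the model is refitted on each resample, and the optimism
#' (bootstrap-apparent minus original-data performance, averaged over
#' resamples) is subtracted from the apparent C-statistic and Brier
#' score.
#'
#' @param data A `clustered_data` with at least 5 clusters.
#' @param spec A [model_spec()]; marginal prediction types only (`"gee"`,
#'   `"iee"`, or `"glmm"` evaluated through its marginal predictions).
#' @param n_boot Number of bootstrap resamples (at least 50 recommended).
#' @param seed Seed controlling the resampling.
#' @param nAGQ Quadrature nodes for GLMM fits.
#' @return A data frame with rows `c_statistic` and `brier` and columns
#'   `apparent`, `optimism`, `corrected`, plus attribute `n_failed`.
#' @export
internal_validation_bootstrap <- function(data, spec, n_boot = 100,
                                          seed = 1L, nAGQ = 21) {
  data <- as.data.frame(data)
  ids <- unique(data$cluster_id)
  if (length(ids) < 5) stop("cluster bootstrap needs at least 5 clusters")
  fit <- fit_for_spec(data, spec, nAGQ = nAGQ)
  pred <- predict_for_spec(fit, data, "marginal")
  apparent <- c(c_statistic = c_statistic(pred$probability, data$y),
                brier = brier(data$y, pred$probability)$brier)
  set.seed(as.integer(seed))
  opt <- matrix(NA_real_, n_boot, 2,
                dimnames = list(NULL, c("c_statistic", "brier")))
  n_failed <- 0
  rows_by_cluster <- split(seq_len(nrow(data)), data$cluster_id)
  for (b in seq_len(n_boot)) {
    take <- sample(ids, replace = TRUE)
    rows <- unlist(rows_by_cluster[as.character(take)], use.names = FALSE)
    boot <- data[rows, , drop = FALSE]
    # re-label so repeated clusters stay distinct
    boot$cluster_id <- rep(seq_along(take),
                           lengths(rows_by_cluster[as.character(take)]))
    res <- tryCatch({
      bfit <- fit_for_spec(boot, spec, nAGQ = nAGQ)
      bpred <- predict_for_spec(bfit, boot, "marginal")
      opred <- predict_for_spec(bfit, data, "marginal")
      c(c_statistic(bpred$probability, boot$y) -
          c_statistic(opred$probability, data$y),
        brier(boot$y, bpred$probability)$brier -
          brier(data$y, opred$probability)$brier)
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1 else opt[b, ] <- res
  }
  optimism <- colMeans(opt, na.rm = TRUE)
  out <- data.frame(apparent = apparent, optimism = optimism,
                    corrected = apparent - optimism)
  attr(out, "n_failed") <- n_failed
  out
}
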