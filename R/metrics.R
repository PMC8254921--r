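check_calibration_inputs <- function(lp, y) {
  if (length(lp) != length(y)) stop("length mismatch")
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2) {
    stop("outcome is single-class; calibration is undefined")
  }
  if (any(!is.finite(lp))) stop("linear predictor must be finite")
}

#' Calibration slope
#'
#' The slope of a univariate logistic regression of the outcome on the
#' estimated linear predictor. A perfectly calibrated model gives slope 1;
#' a slope below 1 indicates overfitting (predictions too extreme), above
#' 1 a too-narrow range of predictions.
#'
#' @param linear_predictor Estimated linear predictor (logit scale).
#' @param outcome Binary 0/1 outcome.
#' @return The estimated slope.
#' @export
calibration_slope <- function(linear_predictor, outcome) {
  check_calibration_inputs(linear_predictor, outcome)
  if (stats::var(linear_predictor) == 0) {
    stop("constant linear predictor; calibration slope is unidentified")
  }
  fit <- stats::glm(outcome ~ linear_predictor, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10))
  unname(coef(fit)[2])
}

#' Calibration in the large
#'
#' The intercept of a logistic model for the outcome with the estimated
#' linear predictor included as an offset (coefficient fixed at 1). Zero
#' means the average predicted probability matches the event rate;
#' positive values mean predictions run low.
#'
#' @inheritParams calibration_slope
#' @return The estimated intercept.
#' @export
calibration_in_the_large <- function(linear_predictor, outcome) {
  check_calibration_inputs(linear_predictor, outcome)
  fit <- stats::glm(outcome ~ 1 + offset(linear_predictor),
                    family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-10))
  unname(coef(fit)[1])
}

#' C-statistic (concordance probability)
#'
#' The probability that a randomly chosen case receives a higher score
#' than a randomly chosen control, with ties counted one half. Computed
#' through the rank (Wilcoxon) formulation, which is exactly equivalent to
#' enumerating all case-control pairs.
#'
#' @param score Predicted probabilities (or any risk score; the statistic
#'   is invariant to strictly increasing transforms).
#' @param outcome Binary 0/1 outcome; both classes must be present.
#' @return Concordance in \[0, 1\].
#' @export
c_statistic <- function(score, outcome) {
  if (length(score) != length(outcome)) stop("length mismatch")
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  n1 <- sum(outcome == 1)
  n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) {
    stop("outcome is single-class; the C-statistic is undefined")
  }
  r <- rank(score)   # midranks handle ties as 1/2
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Root predictive mean squared error against true probabilities
#'
#' sqrt(mean((p_true - p_hat)^2)); available only in simulation settings
#' where the true event probabilities are known.
#'
#' @param true_p True event probabilities.
#' @param est_p Estimated probabilities.
#' @return The RPMSE.
#' @export
rpmse <- function(true_p, est_p) {
  if (length(true_p) != length(est_p)) stop("length mismatch")
  sqrt(mean((true_p - est_p)^2))
}

#' Brier score
#'
#' Mean squared difference between the binary outcome and the estimated
#' probability. Both the conventional (un-rooted) Brier score and its
#' square root are returned; the conventional score is the default
#' report, the root variant is kept for comparability with definitions
#' that take the square root.
#'
#' @param outcome Binary 0/1 outcome.
#' @param est_p Estimated probabilities.
#' @return A list with `brier` and `root_brier`.
#' @export
brier <- function(outcome, est_p) {
  if (length(outcome) != length(est_p)) stop("length mismatch")
  if (!all(outcome %in% 0:1)) stop("outcome must be binary 0/1")
  b <- mean((outcome - est_p)^2)
  list(brier = b, root_brier = sqrt(b))
}

#' Summarise the predictive performance of a prediction set
#'
#' Computes calibration in the large, calibration slope, C-statistic,
#' Brier score (and its root), and — when true probabilities are available
#' — the RPMSE, for one prediction set against the outcomes of the
#' evaluation data.
#'
#' @param pred A `prediction_set`.
#' @param data The evaluation `clustered_data` (must align row-wise with
#'   `pred`); uses `y` and, when present, `p_true`.
#' @param tags Optional named list of labels (scenario, replicate, ...)
#'   appended as columns.
#' @return A one-row data frame (a `performance_summary`).
#' @export
performance_summary <- function(pred, data, tags = list()) {
  stopifnot(nrow(pred) == nrow(data))
  y <- data$y
  out <- data.frame(
    method = attr(pred, "method") %||% NA_character_,
    adjustment = attr(pred, "adjustment") %||% NA_character_,
    prediction_type = attr(pred, "type") %||% NA_character_,
    calibration_intercept = calibration_in_the_large(pred$linear_predictor, y),
    calibration_slope = calibration_slope(pred$linear_predictor, y),
    c_statistic = c_statistic(pred$probability, y),
    rpmse = if (!is.null(data$p_true)) rpmse(data$p_true, pred$probability)
            else NA_real_,
    brier = brier(y, pred$probability)$brier,
    root_brier = brier(y, pred$probability)$root_brier,
    n_members = length(y)
  )
  for (nm in names(tags)) out[[nm]] <- tags[[nm]]
  class(out) <- c("performance_summary", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
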