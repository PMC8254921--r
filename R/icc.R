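#' Intra-cluster correlation implied by a random-intercept variance
#'
#' For a logistic random-intercepts model the latent-variable ICC is
#' \deqn{ICC = \sigma_u^2 / (\pi^2/3 + \sigma_u^2),}
#' where \eqn{\pi^2/3} is the variance of the standard logistic
#' distribution attributed to the member level.
#'
#' @param sigma_u2 Non-negative random-intercept variance (logit scale).
#' @return ICC in \[0, 1).
#' @seealso [icc_to_variance()] for the inverse mapping.
#' @examples
#' variance_to_icc(0.82) # ~0.2
#' variance_to_icc(0.37) # ~0.1
#' @export
variance_to_icc <- function(sigma_u2) {
  if (!is.numeric(sigma_u2) || any(!is.finite(sigma_u2)) || any(sigma_u2 < 0)) {
    stop("`sigma_u2` must be a finite non-negative number")
  }
  sigma_u2 / (pi^2 / 3 + sigma_u2)
}

#' Random-intercept variance implied by an ICC
#'
#' Inverse of [variance_to_icc()]: \eqn{\sigma_u^2 = ICC \cdot (\pi^2/3) / (1 - ICC)}.
#'
#' @param icc Intra-cluster correlation in \[0, 1).
#' @return Random-intercept variance on the logit scale.
#' @export
icc_to_variance <- function(icc) {
  if (!is.numeric(icc) || any(!is.finite(icc)) || any(icc < 0) || any(icc >= 1)) {
    stop("`icc` must lie in [0, 1)")
  }
  icc * (pi^2 / 3) / (1 - icc)
}
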