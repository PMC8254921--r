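#' Model specification
#'
#' Describes which estimation method and which CBC/ICS adjustment set to
#' use. The adjustments follow the recommended strategy for risk
#' prediction on clustered data: adding the cluster mean of the exposure
#' (handles confounding by cluster) and/or a function of the cluster size
#' (handles informative cluster size) to the basic predictor set.
#'
#' @param method `"glmm"` (random-intercept logistic model),
#'   `"gee"` (exchangeable working correlation), `"iee"` (independence
#'   working correlation, i.e. pooled ML with robust SEs) or `"cml"`
#'   (conditional maximum likelihood).
#' @param adjustment `"basic"` (covariates plus exposure only),
#'   `"rbar"` (add f(cluster mean of exposure)), `"size"` (add g(cluster
#'   size)), or `"both"`. CML cannot carry cluster-constant adjustments
#'   (they are conditioned out).
#' @param exposure_param `"raw_plus_mean"` keeps the raw exposure r next to
#'   the cluster mean rbar; `"centered_plus_mean"` uses the within/between
#'   decomposition (r - rbar, rbar). The two span the same column space
#'   and give identical fitted probabilities; the decomposition makes the
#'   within- and between-cluster effects directly readable.
#' @param f_rbar Transform of the cluster-mean exposure (`"identity"`).
#' @param g_n Transform of cluster size: `"identity"`, `"log"`,
#'   `"quadratic"` (N and N^2) or `"categorical"` (quantile bins).
#' @param n_bins Number of bins when `g_n = "categorical"` (at least 2).
#' @param covariates Names of the member-level covariate columns.
#' @param exposure Name of the exposure column.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("glmm", "gee", "iee", "cml"),
                       adjustment = c("basic", "rbar", "size", "both"),
                       exposure_param = c("raw_plus_mean", "centered_plus_mean"),
                       f_rbar = c("identity"),
                       g_n = c("identity", "log", "quadratic", "categorical"),
                       n_bins = 3L,
                       covariates = paste0("x", 1:5),
                       exposure = "r") {
  spec <- list(method = match.arg(method),
               adjustment = match.arg(adjustment),
               exposure_param = match.arg(exposure_param),
               f_rbar = match.arg(f_rbar),
               g_n = match.arg(g_n),
               n_bins = as.integer(n_bins),
               covariates = covariates,
               exposure = exposure)
  if (spec$method == "cml" && spec$adjustment != "basic") {
    stop("CML conditions out all cluster-level information; ",
         "cluster-constant adjustments (rbar, size) cannot be carried")
  }
  if (spec$g_n == "categorical" && spec$n_bins < 2) {
    stop("categorical g_n requires at least 2 bins")
  }
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec: method = %s, adjustment = %s (%s; g_n = %s)\n",
              x$method, x$adjustment, x$exposure_param, x$g_n))
  invisible(x)
}

# add cluster-level summary columns: rbar (cluster mean of exposure) and
# cluster size (recomputed from the data, not trusted from a column)
augment_cluster_covariates <- function(data, spec) {
  cl <- data$cluster_id
  r <- data[[spec$exposure]]
  if (is.null(r)) stop(sprintf("exposure column '%s' not found", spec$exposure))
  rbar <- stats::ave(r, cl, FUN = mean)
  nsize <- stats::ave(rep(1, nrow(data)), cl, FUN = sum)
  data$rbar <- rbar
  data$nsize <- nsize
  data$r_w <- r - rbar
  data
}

g_n_columns <- function(data, spec) {
  n <- data$nsize
  switch(spec$g_n,
    identity = data.frame(g_n = n),
    log = data.frame(g_n = log(n)),
    quadratic = data.frame(g_n1 = n, g_n2 = n^2),
    categorical = {
      br <- unique(stats::quantile(n, probs = seq(0, 1, length.out = spec$n_bins + 1)))
      if (length(br) < 3) stop("too few distinct cluster sizes for categorical bins")
      f <- cut(n, breaks = br, include.lowest = TRUE)
      m <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(m) <- paste0("g_n_bin", seq_len(ncol(m)))
      as.data.frame(m)
    })
}

#' Build the design matrix for a model specification
#'
#' Assembles the fixed-effect design implied by a [model_spec()]: an
#' intercept (except for CML), the member-level covariates, the exposure
#' term(s) in the requested parameterisation, and the optional cluster
#' mean of exposure f(rbar) and cluster-size term g(N), both replicated
#' within cluster. The cluster mean and size are always recomputed from
#' the supplied data.
#'
#' @param data A `clustered_data` (or data frame with `cluster_id`, the
#'   covariates and the exposure).
#' @param spec A [model_spec()].
#' @return A list with `x` (design matrix with named columns), `y`
#'   (outcome, or NULL if absent), `cluster_id`, `terms` (a column map
#'   naming the role of each coefficient) and `data` (the augmented data).
#' @export
build_design <- function(data, spec) {
  data <- as.data.frame(data)
  miss <- setdiff(c("cluster_id", spec$covariates, spec$exposure), names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- augment_cluster_covariates(data, spec)

  cols <- list()
  terms <- character()
  if (spec$method != "cml") {
    cols[["(Intercept)"]] <- rep(1, nrow(data))
    terms["(Intercept)"] <- "intercept"
  }
  for (v in spec$covariates) {
    cols[[v]] <- data[[v]]
    terms[v] <- "covariate"
  }
  use_rbar <- spec$adjustment %in% c("rbar", "both")
  use_size <- spec$adjustment %in% c("size", "both")
  if (use_rbar && spec$exposure_param == "centered_plus_mean") {
    cols[["r_w"]] <- data$r_w
    terms["r_w"] <- "exposure_within"
  } else {
    cols[[spec$exposure]] <- data[[spec$exposure]]
    terms[spec$exposure] <- "exposure"
  }
  if (use_rbar) {
    cols[["rbar"]] <- data$rbar   # f_rbar identity
    terms["rbar"] <- "exposure_cluster_mean"
  }
  if (use_size) {
    if (stats::var(data$nsize) == 0) {
      warning("cluster size is constant across clusters; ",
              "the ICS adjustment g(N) is unidentifiable")
    }
    gn <- g_n_columns(data, spec)
    for (v in names(gn)) {
      cols[[v]] <- gn[[v]]
      terms[v] <- "cluster_size"
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  list(x = x, y = data$y, cluster_id = data$cluster_id,
       terms = terms, data = data)
}
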