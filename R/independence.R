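#' Estimate the independence model of a view
#'
#' The independence model is the baseline in which every sample carries the
#' same feature composition and samples differ only by their overall
#' intensity.  For count views the per-sample intensities are the observed
#' sequencing depths (row totals over observed cells, treated as ancillary
#' constants), the baseline composition is the vector of feature totals
#' divided by the grand total, and the offset is its clr.  For gaussian
#' views the identity link makes the offset simply the per-feature observed
#' mean, with unit intensities.
#'
#' @param view a [view_data()] object with at least 2 samples and 3
#'   features, each feature having at least one observed positive entry.
#' @return list of class `independence_model` with elements `offset`,
#'   `pi_indep` (count views), `depths`, `family`.
#' @export
independence_model <- function(view) {
  stopifnot(inherits(view, "view_data"))
  x <- view$x
  if (nrow(x) < 2L || ncol(x) < 3L)
    stop("need at least 2 samples and 3 features")
  if (view$family == "count") {
    totals <- colSums(x, na.rm = TRUE)
    if (any(totals <= 0))
      stop("feature(s) with zero total observed count: ",
           paste(utils::head(colnames(x)[totals <= 0], 5L), collapse = ", "),
           ". Remove them first, e.g. with filter_features().")
    depths <- rowSums(x, na.rm = TRUE)
    if (any(depths <= 0)) stop("sample(s) with zero observed depth")
    pi_indep <- totals / sum(totals)
    out <- list(offset = clr(pi_indep), pi_indep = pi_indep,
                depths = depths, family = "count")
  } else {
    out <- list(offset = colMeans(x, na.rm = TRUE), pi_indep = NULL,
                depths = rep(1, nrow(x)), family = "gaussian")
  }
  class(out) <- "independence_model"
  out
}

# Linear predictor of one fitted view at dimensions 1..m:
# offset + confounder term + Z[, 1:m] %*% Gamma[1:m, ].
linear_predictor <- function(vf, Z, dims) {
  n <- nrow(Z)
  eta <- matrix(vf$indep$offset, n, length(vf$indep$offset), byrow = TRUE)
  if (!is.null(vf$conf_design))
    eta <- eta + vf$conf_design %*% vf$conf_coefs
  if (dims >= 1L)
    eta <- eta + Z[, seq_len(dims), drop = FALSE] %*%
      vf$loadings[seq_len(dims), , drop = FALSE]
  eta
}

#' Expected values under the fitted mean model
#'
#' For count views, row i is the softmax of the linear predictor
#' (offset + confounder term + score-weighted loadings over the first
#' `dims` dimensions) scaled by the sample depth, so each row sums to the
#' sample's sequencing depth.  For gaussian views the identity link returns
#' the linear predictor itself.  The same code path produces the means used
#' inside the estimating equations.
#'
#' @param fit a fitted [compint()] model.
#' @param view view index or name.
#' @param dims number of latent dimensions to include (default: all fitted).
#' @return n-by-p matrix of expected values.
#' @export
mean_matrix <- function(fit, view = 1L, dims = NULL) {
  stopifnot(inherits(fit, "compint"))
  vf <- fit$views[[view]]
  dims <- dims %||% fit$M
  if (dims > fit$M) stop("dims exceeds the number of fitted dimensions")
  eta <- linear_predictor(vf, fit$scores, dims)
  if (vf$family == "count") softmax_rows(eta) * vf$indep$depths else eta
}
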