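#' Feature-wise weighted variances around the current mean model
#'
#' For each feature, the squared residuals about the modelled means are
#' divided by the sample depths (putting them on a per-depth-unit scale)
#' and averaged with denominator `n_j - 1`, where `n_j` counts the observed
#' cells of that feature.  Missing cells contribute nothing.  These are the
#' raw material of the abundance-variance trend and are re-estimated as the
#' model gains dimensions.
#'
#' @param x observed matrix (NA = missing).
#' @param expected matrix of modelled means at the current dimension.
#' @param depths per-sample intensities `s_i`.
#' @return numeric vector of per-feature variances; features with fewer
#'   than two observed cells get `NA`.
#' @export
feature_weighted_variance <- function(x, expected, depths) {
  stopifnot(all(dim(x) == dim(expected)), nrow(x) == length(depths))
  obs <- !is.na(x)
  r2 <- (x - expected)^2 / depths
  r2[!obs] <- 0
  nj <- colSums(obs)
  out <- colSums(r2) / (nj - 1)
  out[nj < 2L] <- NA_real_
  out
}

#' Fit the abundance-variance trend of a count view
#'
#' Fits a cubic smoothing spline (smoothness chosen by generalized
#' cross-validation) of log variance on log relative abundance, describing
#' how a feature's per-depth-unit variance grows with its abundance.  Two
#' restrictions encode the Poisson heuristic: predictions are floored at
#' the Poisson line `v(pi) = pi` everywhere (the variance can never drop
#' below the mean), and below the low-abundance cutoff (the 10th abundance
#' percentile by default) the trend *is* the Poisson line, because sparse
#' low-abundance features carry too little replication to estimate extra
#' dispersion.
#'
#' Below the low-abundance cutoff (the 10th abundance percentile by
#' default) the trend equals the Poisson line exactly; between the cutoff
#' and twice its quantile the prediction blends geometrically from the
#' Poisson line into the spline, so the trend is continuous everywhere (a
#' discontinuous variance model would leave the estimating equations
#' without a stable root).
#'
#' @param pi_indep per-feature relative abundances under the independence
#'   model (the x-axis of the trend).
#' @param variances per-feature weighted variances from
#'   [feature_weighted_variance()].
#' @param low_quantile abundance quantile below which the pure Poisson line
#'   is used.
#' @return object of class `variance_trend`.
#' @export
fit_variance_trend <- function(pi_indep, variances, low_quantile = 0.1) {
  stopifnot(length(pi_indep) == length(variances))
  ok <- is.finite(variances) & variances > 0 & is.finite(pi_indep) &
    pi_indep > 0
  pos <- is.finite(pi_indep) & pi_indep > 0
  pi_low <- stats::quantile(pi_indep[pos], low_quantile, names = FALSE)
  pi_hi <- stats::quantile(pi_indep[pos], min(2 * low_quantile, 0.5),
                           names = FALSE)
  if (pi_hi <= pi_low) pi_hi <- pi_low * 1.5
  use <- ok & pi_indep > pi_low
  if (sum(ok) < 10L || length(unique(pi_indep[use])) < 8L) {
    warning("fewer than 10 usable features; falling back to Poisson trend")
    out <- list(type = "poisson", pi_low = pi_low)
  } else {
    sp <- stats::smooth.spline(log(pi_indep[use]), log(variances[use]),
                               cv = FALSE)
    out <- list(type = "spline", spline = sp, pi_low = pi_low,
                pi_hi = pi_hi, range = range(log(pi_indep[use])))
  }
  class(out) <- "variance_trend"
  out
}

# v_m(pi): per-depth-unit variance at modelled proportion pi (vectorized).
# Pure Poisson below pi_low, geometric Poisson->spline blend on
# [pi_low, pi_hi], spline above; floored at the Poisson line throughout.
trend_value <- function(trend, pi) {
  if (any(pi <= 0 | pi >= 1)) stop("proportions must lie in (0, 1)")
  if (trend$type == "poisson") return(pi)
  lp <- log(pi)
  vsp <- stats::predict(trend$spline, lp)$y
  w <- pmin(pmax((lp - log(trend$pi_low)) /
                   (log(trend$pi_hi) - log(trend$pi_low)), 0), 1)
  pmax(exp((1 - w) * lp + w * vsp), pi)
}

#' Predict the variance of a count observation
#'
#' Evaluates the abundance-variance trend at a modelled proportion and
#' scales by the sample depth: `Var = v_m(pi) * s`.  Queries outside the
#' fitted abundance range are extrapolated linearly (on the log scale) from
#' the boundary, still floored at the Poisson line.
#'
#' @param trend a [fit_variance_trend()] object.
#' @param pi modelled proportion(s) in (0, 1).
#' @param s sequencing depth(s).
#' @return predicted variance(s).
#' @export
predict_variance <- function(trend, pi, s) {
  stopifnot(inherits(trend, "variance_trend"), all(s > 0))
  trend_value(trend, pi) * s
}

#' Shrink gaussian feature variances by empirical Bayes
#'
#' Raw per-feature variances are squeezed towards a common prior value
#' `s0^2` with prior degrees of freedom `d0`:
#' `(d0 * s0^2 + d_j * s_j^2) / (d0 + d_j)`.  When the prior is not
#' supplied it is estimated by moment-matching on the log variances (the
#' standard squeeze procedure, via `limma::fitFDist`).  An infinite `d0`
#' collapses every variance to `s0^2`.
#'
#' @param variances raw per-feature variances.
#' @param df residual degrees of freedom per feature (recycled).
#' @param prior_df,prior_var optional known prior; estimated when `NULL`.
#' @return list of class `gaussian_variances` with `post_var`, `prior_df`,
#'   `prior_var`.
#' @export
shrink_variances <- function(variances, df, prior_df = NULL,
                             prior_var = NULL) {
  if (all(!is.finite(variances) | variances == 0))
    stop("all raw variances are zero: degenerate view")
  df <- rep_len(df, length(variances))
  if (any(df < 1, na.rm = TRUE)) stop("residual df must be >= 1")
  if (is.null(prior_df) || is.null(prior_var)) {
    ok <- is.finite(variances) & variances > 0
    fd <- limma::fitFDist(variances[ok], df1 = df[ok])
    prior_var <- prior_var %||% fd$scale
    prior_df <- prior_df %||% fd$df2
  }
  post <- if (is.infinite(prior_df)) rep(prior_var, length(variances)) else
    (prior_df * prior_var + df * variances) / (prior_df + df)
  structure(list(post_var = post, prior_df = prior_df,
                 prior_var = prior_var),
            class = "gaussian_variances")
}
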