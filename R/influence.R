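#' Per-observation influence on the latent scores
#'
#' Because the model is defined by explicit estimating equations, the
#' contribution of each observed cell to the estimation of a sample's
#' latent score (or, in a constrained fit, of the environmental gradient)
#' can be read off directly: the influence of observation (i, j) on the
#' score `Z[i, m]` is its estimating-function contribution divided by the
#' (negative) derivative of the per-sample score equation, i.e. a one-step
#' leave-one-out approximation.  Summing absolute influences per view
#' reveals which dataset drives the estimation.  The derivative is computed
#' analytically for gaussian views; for count views (where the softmax
#' Jacobian is error-prone) it is obtained by central finite differences on
#' the score equation, with relative step 1e-6.
#'
#' @param fit a converged [compint()] fit.
#' @param view view index or name whose observations to tabulate.
#' @param dimension latent dimension.
#' @return data.frame of class `influence_table` with columns `view`,
#'   `sample`, `feature`, `dimension`, `contribution` (estimating-function
#'   term), `influence`.  Missing cells have zero influence.
#' @seealso [influence_by_view()]
#' @export
influence_scores <- function(fit, view = 1L, dimension = 1L) {
  stopifnot(inherits(fit, "compint"))
  m <- dimension
  if (m > fit$M) stop("dimension out of range")
  if (!all(fit$convergence$converged))
    stop("influence requires a converged fit")
  n <- nrow(fit$scores)

  # total information of the per-sample score equation, across all views
  info <- numeric(n)
  for (vf in fit$views) {
    vf <- dim_variance(vf, m)
    if (vf$family == "gaussian") {
      eta <- linear_predictor(vf, fit$scores, m)
      info <- info + gauss_z_block(vf, eta, vf$loadings[m, ])$info
    } else {
      h <- 1e-6 * max(1, stats::sd(fit$scores[, m]))
      sc <- function(zv) {
        Z2 <- fit$scores; Z2[, m] <- zv
        st <- count_state(vf, linear_predictor(vf, Z2, m))
        count_z_block(vf, st, vf$loadings[m, ])$score
      }
      z0 <- fit$scores[, m]
      info <- info - (sc(z0 + h) - sc(z0 - h)) / (2 * h)
    }
  }

  vf <- dim_variance(fit$views[[view]], m)
  eta <- linear_predictor(vf, fit$scores, m)
  if (vf$family == "count") {
    st <- count_state(vf, eta)
    pg <- as.vector(st$P %*% vf$loadings[m, ])
    D <- vf$indep$depths *
      (sweep(st$P, 2L, vf$loadings[m, ], `*`) - st$P * pg)
    contrib <- D * st$RW
  } else {
    r <- vf$x0 - eta
    r[!vf$obs] <- 0
    contrib <- sweep(r, 2L, vf$loadings[m, ] / vf$sigma2, `*`)
  }
  infl_sample <- contrib / info   # recycles info down columns

  if (!is.null(fit$gradient)) {
    # influence on Z[i, m] = c_i' lambda_m via the gradient equations:
    # IF(z_im) = c_i' (C' diag(info) C)^{-1} c_i * contribution
    C <- fit$gradient$design
    Jl <- crossprod(C, info * C)
    hi <- rowSums(C * t(solve(Jl, t(C))))   # c_i' Jl^{-1} c_i
    infl_sample <- contrib * hi
  }

  out <- data.frame(
    view = if (is.character(view)) view else names(fit$views)[view],
    sample = rep(fit$sample_ids, ncol(contrib)),
    feature = rep(vf$feature_ids, each = n),
    dimension = m,
    contribution = as.vector(contrib),
    influence = as.vector(infl_sample))
  class(out) <- c("influence_table", "data.frame")
  out
}

#' Total absolute influence per view
#'
#' Sums absolute influences over each view's features, per sample, giving
#' the view-wise contribution to the estimation of the latent variables
#' (the quantity usually displayed as boxplots over samples).
#'
#' @param fit a converged [compint()] fit.
#' @param dimension latent dimension.
#' @return data.frame with columns `view`, `sample`, `total_abs_influence`.
#' @export
influence_by_view <- function(fit, dimension = 1L) {
  do.call(rbind, lapply(seq_along(fit$views), function(k) {
    tab <- influence_scores(fit, view = k, dimension = dimension)
    agg <- stats::aggregate(abs(tab$influence),
                            by = list(sample = tab$sample), FUN = sum)
    data.frame(view = names(fit$views)[k], sample = agg$sample,
               total_abs_influence = agg$x)
  }))
}
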