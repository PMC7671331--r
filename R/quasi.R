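# Internal quasi-likelihood building blocks.
#
# Count views: mean model E_ij = softmax(eta_i)_j * s_i with eta the clr-scale
# linear predictor; variance model V_ij = v_m(pi_ij) * s_i from the
# abundance-variance trend.  All estimating-equation sums run over observed
# cells only: residual and weight matrices are zeroed at missing cells, and
# every score term carries one of them as a factor.
#
# Gaussian views: identity link, V_ij = shrunken feature variance.

# Softmax-model state at the current linear predictor.
count_state <- function(vf, eta) {
  P <- softmax_rows(eta)
  s <- vf$indep$depths
  E <- P * s
  V <- matrix(trend_value(vf$trend, as.numeric(P)), nrow(P)) * s
  W <- vf$obs / V                      # 0 at missing cells
  R <- vf$x0 - E                       # x0 has 0 at missing cells
  R[!vf$obs] <- 0
  list(P = P, E = E, W = W, RW = R * W)
}

# Per-sample score and Fisher information for the score (or gradient) block.
# D_ij = dE_ij/dz_i = s_i P_ij (gamma_j - <P_i, gamma>).
count_z_block <- function(vf, st, gamma) {
  s <- vf$indep$depths
  pg <- as.vector(st$P %*% gamma)
  D <- s * (sweep(st$P, 2L, gamma, `*`) - st$P * pg)
  list(score = rowSums(D * st$RW), info = rowSums(D * D * st$W))
}

gauss_z_block <- function(vf, eta, theta) {
  r <- vf$x0 - eta
  r[!vf$obs] <- 0
  wth <- theta / vf$sigma2
  list(score = as.vector(r %*% wth),
       info = as.vector(vf$obs %*% (theta * wth)))
}

# Newton/Gauss-Newton step restricted to the tangent space of linear(ized)
# restrictions with gradient matrix C, via the KKT system
#   [J C; C' 0] [delta; mu] = [score; 0].
# J may be a diagonal (vector) or a full matrix.  This is the step of the
# restricted estimating equations in the information metric; taking it (and
# then retracting exactly onto the restriction manifold) keeps block
# updates from fighting the normalization.
kkt_step <- function(J, score, C = NULL) {
  if (is.null(C) || !NCOL(C)) {
    if (is.matrix(J)) return(solve(J, score))
    return(ifelse(J > 0, score / J, 0))
  }
  C <- cbind(C)
  if (!is.matrix(J)) {
    Jin <- ifelse(J > 0, 1 / J, 0)
    t1 <- Jin * score
    M <- crossprod(C, Jin * C)
    diag(M) <- diag(M) + 1e-12 * max(diag(M), 1)
    mu <- solve(M, crossprod(C, t1))
    return(as.vector(t1 - Jin * (C %*% mu)))
  }
  k <- ncol(C); p <- nrow(C)
  A <- rbind(cbind(J, C), cbind(t(C), matrix(0, k, k)))
  as.vector(solve(A, c(score, numeric(k)))[seq_len(p)])
}

# One Gauss-Newton step for a count-view loading row gamma_m given scores z,
# restricted to the tangent space of the loading restrictions (columns of
# C).  Score over features: sum_i z_i s_i P_ij (RW_ij - <P_i, RW_i>); the
# GN matrix is sum_i (z_i s_i)^2 A_i W_i A_i with A_i = diag(P_i) -
# P_i P_i^T, assembled from a diagonal plus low-rank crossproducts.  The
# all-ones direction is null (softmax shift invariance); it is removed by
# the sum-zero restriction in C (or a ridge when C is absent).
count_gamma_score <- function(vf, st, z) {
  zs <- z * vf$indep$depths
  rs <- rowSums(st$P * st$RW)
  colSums(zs * (st$P * (st$RW - rs)))
}

count_gamma_step <- function(vf, st, z, C = NULL, max_step = 2) {
  zs <- z * vf$indep$depths
  score <- count_gamma_score(vf, st, z)
  A2 <- zs^2 * st$P^2 * st$W
  dg <- colSums(A2)
  Tm <- crossprod(A2, st$P)
  GN <- -(Tm + t(Tm)) + crossprod(st$P, rowSums(A2) * st$P)
  diag(GN) <- diag(GN) + dg
  p <- length(dg); tr <- mean(dg)
  diag(GN) <- diag(GN) + 1e-10 * tr
  if (is.null(C)) GN <- GN + tr / p          # 11'/p ridge for the null dir
  delta <- tryCatch(kkt_step(GN, score, C),
                    error = function(e) score / (dg + tr))
  cap <- max(abs(delta))
  if (is.finite(cap) && cap > max_step) delta <- delta * (max_step / cap)
  list(delta = delta, score = score, info = dg)
}

# Score and information of a gaussian loading row at the current linear
# predictor (which includes the row's own term).  The equations are linear
# in theta, so a single KKT Newton step solves the restricted weighted
# least-squares problem exactly.
gauss_theta_block <- function(vf, eta, z) {
  r <- vf$x0 - eta
  r[!vf$obs] <- 0
  list(score = as.vector(crossprod(r, z)) / vf$sigma2,
       info = as.vector(crossprod(vf$obs, z^2)) / vf$sigma2)
}

# --- restriction projections -------------------------------------------------

# Center, then orthogonalize against previously fitted (centered) columns.
project_scores <- function(z, Zprev) {
  z <- z - mean(z)
  if (!is.null(Zprev) && ncol(Zprev))
    for (k in seq_len(ncol(Zprev))) {
      q <- Zprev[, k]
      z <- z - sum(z * q) / sum(q * q) * q
    }
  z
}

# Sum-zero (count views only: the clr scale fixes loading rows up to an
# additive constant), then Omega-orthogonal to previous loading rows;
# returns the projected row and its Omega-norm.
project_loading <- function(g, prev, omega, center = TRUE) {
  if (center) g <- g - mean(g)
  if (!is.null(prev) && nrow(prev))
    for (k in seq_len(nrow(prev))) {
      q <- prev[k, ]
      g <- g - sum(g * omega * q) / sum(q * omega * q) * q
    }
  list(g = g, norm = sqrt(sum(g * g * omega)))
}

# Zero-sum within each categorical dummy block, orthogonal to previous
# gradient columns, then unit Euclidean norm.
project_gradient <- function(l, prev, blocks) {
  for (idx in blocks) l[idx] <- l[idx] - mean(l[idx])
  if (!is.null(prev) && ncol(prev))
    for (k in seq_len(ncol(prev))) {
      q <- prev[, k]
      l <- l - sum(l * q) * q
    }
  nrm <- sqrt(sum(l * l))
  list(l = if (nrm > 0) l / nrm else l, norm = nrm)
}

# Projection of a raw score vector onto the orthogonal complement of the
# restriction gradients in `basis` (columns): the estimating equation of the
# identified model, which is what vanishes at a constrained solution.
project_out <- function(score, basis) {
  if (is.null(basis) || !NCOL(basis)) return(score)
  qb <- qr.Q(qr(basis))
  score - qb %*% crossprod(qb, score)
}

#' Quasi-likelihood score vectors of a fitted model
#'
#' Recomputes, from the stored data, the estimating-function values for the
#' score (latent variable) block or a view's loading block of one fitted
#' dimension, using that dimension's variance model and the mean model of
#' dimensions 1..m (the model the dimension was fitted under).  Because the
#' fit carries identifiability restrictions (centering, orthogonality,
#' normalization, zero-sum blocks), the raw per-parameter scores contain
#' Lagrange components along the restriction gradients; `projected = TRUE`
#' (default) removes these, yielding the estimating equations of the
#' identified model, which vanish at a converged solution.
#'
#' @param fit a [compint()] fit.
#' @param view view index (loading block) .
#' @param dimension which latent dimension.
#' @param block `"scores"` for the latent-variable (or gradient) equations,
#'   `"loadings"` for the view's loading-row equations.
#' @param projected drop components along restriction gradients.
#' @param standardized express the score on the natural parameter scale by
#'   dividing by the Fisher information: the standardized (and, with
#'   `projected`, restricted) score is the size of the Newton step it would
#'   trigger, and vanishes exactly when the raw score is a linear
#'   combination of restriction gradients (a solved restricted estimating
#'   equation).  Raw scores are in data units and scale with sequencing
#'   depth, so convergence contracts are stated on the standardized ones.
#' @return numeric vector of score values.
#' @export
quasi_score <- function(fit, view = 1L, dimension = 1L,
                        block = c("scores", "loadings"), projected = TRUE,
                        standardized = TRUE) {
  stopifnot(inherits(fit, "compint"))
  block <- match.arg(block)
  m <- dimension
  if (m > fit$M) stop("dimension exceeds fitted dimensions")
  Z <- fit$scores
  sc <- NULL
  if (block == "scores") {
    tot_score <- 0; tot_info <- 0
    for (vf in fit$views) {
      vf <- dim_variance(vf, m)
      eta <- linear_predictor(vf, Z, m)
      bl <- if (vf$family == "count")
        count_z_block(vf, count_state(vf, eta), vf$loadings[m, ])
      else gauss_z_block(vf, eta, vf$loadings[m, ])
      tot_score <- tot_score + bl$score
      tot_info <- tot_info + bl$info
    }
    if (!is.null(fit$gradient)) {
      C <- fit$gradient$design
      sc <- as.vector(crossprod(C, tot_score))
      basis <- cbind(block_basis(fit$gradient),
                     fit$gradient$Lambda[, seq_len(m), drop = FALSE])
      info <- pmax(diag(crossprod(C, tot_info * C)), 1e-300)
      sc <- score_scale(sc, info, basis, projected, standardized)
    } else {
      basis <- cbind(rep(1, nrow(Z)),
                     if (m > 1L) Z[, seq_len(m - 1L)])
      sc <- score_scale(tot_score, pmax(tot_info, 1e-300), basis,
                        projected, standardized)
    }
  } else {
    vf <- dim_variance(fit$views[[view]], m)
    eta <- linear_predictor(vf, Z, m)
    z <- Z[, m]
    if (vf$family == "count") {
      st <- count_state(vf, eta)
      gs <- count_gamma_step(vf, st, z)
      sc <- gs$score
      info <- gs$info
    } else {
      bl <- gauss_theta_block(vf, eta, z)
      sc <- bl$score
      info <- bl$info
    }
    rows <- seq_len(if (is.null(fit$gradient)) m else m - 1L)
    basis <- vf$omega * t(vf$loadings[rows, , drop = FALSE])
    if (vf$family == "count") basis <- cbind(rep(1, ncol(vf$x0)), basis)
    sc <- score_scale(sc, pmax(info, 1e-300), basis, projected,
                      standardized)
  }
  sc
}

# Turn a raw score vector into the reported scale: standardized ->
# KKT Newton step (zero iff the raw score lies in the span of the
# restriction gradients), projected -> components along restriction
# gradients removed.
score_scale <- function(sc, info, basis, projected, standardized) {
  if (standardized && projected) as.vector(kkt_step(info, sc, basis))
  else if (standardized) sc / info
  else if (projected) as.vector(project_out(sc, basis))
  else sc
}

# restriction-gradient basis of the categorical zero-sum blocks
block_basis <- function(gradient) {
  d <- nrow(gradient$Lambda)
  if (!length(gradient$blocks)) return(matrix(numeric(0), d, 0))
  vapply(gradient$blocks, function(idx) {
    b <- numeric(d); b[idx] <- 1; b
  }, numeric(d))
}

# install the variance model that dimension m was fitted under
dim_variance <- function(vf, m) {
  if (vf$family == "count") vf$trend <- vf$trends[[m]]
  else vf$sigma2 <- vf$sigma2_dims[[m]]
  vf
}

#' Single-feature quasi-likelihood count fit
#'
#' Fits the one-feature log-link mean model `E(x_i) = s_i exp(a + b z_i)`
#' by solving the same estimating equations used throughout the package
#' (sum of `dE/dkappa (x - E)/V`), with Poisson variance `V = E` or a
#' supplied abundance-variance trend.  This is the scalar reduction of the
#' count-view machinery, useful for understanding and for checking against
#' standard Poisson regression.
#'
#' @param x observed counts.
#' @param z fixed covariate (e.g. a latent score column).
#' @param depths per-sample intensities `s_i`.
#' @param trend optional [fit_variance_trend()] object; Poisson when `NULL`.
#' @param tol,max_iter Newton control.
#' @return list with `coef` (a, b), `fitted`, `iterations`, `score`.
#' @export
fit_feature_ql <- function(x, z, depths, trend = NULL, tol = 1e-10,
                           max_iter = 100L) {
  stopifnot(length(x) == length(z), length(x) == length(depths))
  a <- log(sum(x) / sum(depths)); b <- 0
  for (it in seq_len(max_iter)) {
    mu <- depths * exp(a + b * z)
    V <- if (is.null(trend)) mu else
      predict_variance(trend, pmin(pmax(mu / depths, 1e-12), 1 - 1e-12),
                       depths)
    # dE/da = mu, dE/db = mu z
    u <- c(sum(mu * (x - mu) / V), sum(mu * z * (x - mu) / V))
    J <- matrix(c(sum(mu^2 / V), sum(mu^2 * z / V),
                  sum(mu^2 * z / V), sum(mu^2 * z^2 / V)), 2L)
    step <- solve(J, u)
    a <- a + step[1L]; b <- b + step[2L]
    if (max(abs(step)) < tol) break
  }
  mu <- depths * exp(a + b * z)
  V <- if (is.null(trend)) mu else
    predict_variance(trend, pmin(pmax(mu / depths, 1e-12), 1 - 1e-12), depths)
  list(coef = c(a = a, b = b), fitted = mu, iterations = it,
       score = c(sum(mu * (x - mu) / V), sum(mu * z * (x - mu) / V)))
}
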