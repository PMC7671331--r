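#' Joint latent-variable integration of multiple omics views
#'
#' Fits a set of view-specific mean models sharing latent sample scores:
#' count views use a clr link (each sample's expected composition is the
#' softmax of offset + confounder term + score-weighted loadings, scaled by
#' its sequencing depth) and are estimated by quasi-likelihood with a
#' nonparametric abundance-variance trend; gaussian views use an identity
#' link with empirical-Bayes-shrunken feature variances.  Dimensions are
#' fitted sequentially, so lower dimensions do not depend on how many are
#' requested.  Identifiability restrictions: score columns are centered and
#' mutually orthogonal (`Z'Z` diagonal); loading rows are sum-zero and
#' orthonormal in the view's diagonal weight metric; in a constrained fit
#' the scores are `Z = c Lambda` with orthonormal gradient columns and
#' zero-sum entries within each categorical dummy block (loadings then
#' carry the scale instead).
#'
#' Confounder effects, when given, are estimated per view before the latent
#' variables and then frozen, so scores and loadings are conditioned on
#' them.  Missing cells simply drop out of all estimating equations.
#'
#' @param views a [view_data()] object or list of them, aligned by sample
#'   id (a sample absent from a view is treated as all-missing there).
#' @param M number of latent dimensions (2 or 3 for plotting).
#' @param metadata data.frame of sample variables (rownames = sample ids);
#'   required for `constrain` or `confounders`.
#' @param constrain character vector of metadata variables: fit a
#'   constrained ordination with scores restricted to linear combinations
#'   (environmental gradients) of these variables.
#' @param confounders character vector (all views) or list per view of
#'   metadata variables whose effects are removed before estimation.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change per outer iteration.
#' @param max_iter maximum outer iterations per dimension.
#' @param max_trend_iter maximum variance-model re-estimations per
#'   dimension (re-estimation also stops once the trend changes < 1%).
#' @param weights optional list of per-feature weight vectors (the diagonal
#'   weight metric); defaults to mean relative abundance (count views) or
#'   inverse shrunken variance (gaussian views), normalized to sum p.
#' @param verbose print per-dimension progress.
#' @return object of class `compint`; see [mean_matrix()],
#'   [multiplot_coordinates()], [influence_scores()], [quasi_score()].
#' @examples
#' sim <- simulate_views(n = 20, p = c(40, 30), seed = 1)
#' fit <- compint(sim$views, M = 2)
#' fit
#' @export
compint <- function(views, M = 2L, metadata = NULL, constrain = NULL,
                    confounders = NULL, tol = 1e-6, max_iter = 1000L,
                    max_trend_iter = 5L, weights = NULL, verbose = FALSE) {
  if (inherits(views, "view_data")) {
    warning("single-view fit: this is an ordination, not an integration")
    views <- list(views)
  }
  stopifnot(length(views) >= 1L, M >= 1L, tol > 0)
  if (is.null(names(views)))
    names(views) <- make.unique(vapply(views, `[[`, "", "name"))
  views <- align_views(views)
  n <- nrow(views[[1L]]$x)
  ids <- rownames(views[[1L]]$x)

  # per-view fitting state
  vfs <- lapply(views, function(v) {
    indep <- independence_model(v)
    x0 <- v$x; obs <- !is.na(x0); x0[!obs] <- 0
    list(x0 = x0, obs = obs, family = v$family, indep = indep,
         name = v$name, p = ncol(x0), feature_ids = colnames(x0))
  })

  # diagonal weight metric per view, normalized to sum p
  for (k in seq_along(vfs)) {
    vf <- vfs[[k]]
    w <- if (!is.null(weights)) weights[[k]] else if (vf$family == "count")
      vf$indep$pi_indep else {
      rv <- feature_weighted_variance(views[[k]]$x,
              matrix(vf$indep$offset, n, vf$p, byrow = TRUE), vf$indep$depths)
      1 / shrink_variances(rv, pmax(colSums(vf$obs) - 1L, 1L))$post_var
    }
    vfs[[k]]$omega <- as.vector(w) / sum(w) * vf$p
  }

  # confounder pre-conditioning (coefficients frozen afterwards)
  if (!is.null(confounders)) {
    if (is.null(metadata)) stop("confounders require metadata")
    if (!is.list(confounders))
      confounders <- stats::setNames(rep(list(confounders), length(vfs)),
                                     names(vfs))
    md <- metadata[ids, , drop = FALSE]
    for (k in seq_along(vfs)) {
      vars <- confounders[[names(vfs)[k]]] %||% confounders[[k]]
      if (is.null(vars)) next
      enc <- encode_design(md, vars)
      vfs[[k]] <- fit_confounders(vfs[[k]], enc$design, tol)
    }
  }

  gradient <- NULL
  if (!is.null(constrain)) {
    if (is.null(metadata)) stop("constrained fit requires metadata")
    enc <- encode_design(metadata[ids, , drop = FALSE], constrain)
    gradient <- list(design = enc$design, blocks = enc$blocks,
                     Lambda = matrix(0, ncol(enc$design), M,
                                     dimnames = list(colnames(enc$design),
                                                     NULL)))
  }

  Z <- matrix(0, n, M, dimnames = list(ids, paste0("dim", seq_len(M))))
  for (k in seq_along(vfs)) {
    vfs[[k]]$loadings <- matrix(0, M, vfs[[k]]$p,
                                dimnames = list(NULL, vfs[[k]]$feature_ids))
    vfs[[k]]$trends <- vector("list", M)
    vfs[[k]]$sigma2_dims <- vector("list", M)
  }
  conv <- data.frame(dimension = integer(), iterations = integer(),
                     converged = logical(), delta = numeric(),
                     max_score_scores = numeric(),
                     max_score_loadings = numeric(), psi = numeric())

  M_eff <- M
  for (m in seq_len(M)) {
    res <- fit_one_dimension(vfs, Z, m, gradient, tol, max_iter,
                             max_trend_iter, verbose)
    if (res$degenerate) {
      warning("dimension ", m, " is degenerate (psi ~ 0); returning ",
              m - 1L, " dimension(s)")
      M_eff <- m - 1L
      break
    }
    vfs <- res$vfs; Z <- res$Z; gradient <- res$gradient
    conv <- rbind(conv, res$conv)
  }
  if (M_eff < 1L) stop("no non-degenerate dimensions could be fitted")
  if (M_eff < M) {
    Z <- Z[, seq_len(M_eff), drop = FALSE]
    for (k in seq_along(vfs)) {
      vfs[[k]]$loadings <- vfs[[k]]$loadings[seq_len(M_eff), , drop = FALSE]
      vfs[[k]]$trends <- vfs[[k]]$trends[seq_len(M_eff)]
      vfs[[k]]$sigma2_dims <- vfs[[k]]$sigma2_dims[seq_len(M_eff)]
    }
    if (!is.null(gradient))
      gradient$Lambda <- gradient$Lambda[, seq_len(M_eff), drop = FALSE]
  }
  for (k in seq_along(vfs)) {      # working slots refer to the last dimension
    vfs[[k]]$trend <- vfs[[k]]$trends[[M_eff]]
    vfs[[k]]$sigma2 <- vfs[[k]]$sigma2_dims[[M_eff]]
  }
  structure(
    list(views = vfs, scores = Z, psi = colSums(Z^2), gradient = gradient,
         M = M_eff, convergence = conv, tol = tol,
         sample_ids = ids, call = match.call()),
    class = "compint")
}

# One sequentially fitted dimension: initialize from the SVD of working
# residuals, then alternate one Newton/Gauss-Newton step per block
# (scores-or-gradient, then each view's loading row) with restriction
# projections after every outer pass, re-estimating the variance models on
# the first few passes.
fit_one_dimension <- function(vfs, Z, m, gradient, tol, max_iter,
                              max_trend_iter, verbose) {
  n <- nrow(Z)
  Zprev <- if (m > 1L) Z[, seq_len(m - 1L), drop = FALSE] else NULL
  constrained <- !is.null(gradient)

  # variance models conditional on the lower-dimensional fit
  for (k in seq_along(vfs))
    vfs[[k]] <- refresh_variance(vfs[[k]], Z, m - 1L, m)

  ini <- init_dimension(vfs, Z, m)
  z <- project_scores(ini$z, Zprev)
  lambda <- NULL
  if (constrained) {
    cdes <- gradient$design
    lam0 <- tryCatch(solve(crossprod(cdes), crossprod(cdes, z)),
                     error = function(e) crossprod(cdes, z) /
                       colSums(cdes^2))
    Lprev <- if (m > 1L) gradient$Lambda[, seq_len(m - 1L), drop = FALSE]
    lambda <- project_gradient(as.vector(lam0), Lprev, gradient$blocks)$l
    z <- as.vector(cdes %*% lambda)
  }
  for (k in seq_along(vfs)) {
    pr <- project_loading(ini$gammas[[k]],
                          if (m > 1L) vfs[[k]]$loadings[seq_len(m - 1L), ,
                                                        drop = FALSE],
                          vfs[[k]]$omega,
                          center = vfs[[k]]$family == "count")
    vfs[[k]]$loadings[m, ] <- if (!constrained && pr$norm > 0)
      pr$g / pr$norm else pr$g
  }

  trend_live <- TRUE
  delta <- Inf; it <- 0L
  relax <- 1; prev_step <- NULL
  for (it in seq_len(max_iter)) {
    z_old <- z
    g_old <- lapply(vfs, function(vf) vf$loadings[m, ])

    # (a) scores / gradient block: one damped Newton step on the stacked
    # equations, taken inside the tangent space of the identifiability
    # restrictions (steps never move along restriction gradients, so the
    # projections in (c) are second-order retractions, not O(1)
    # perturbations).  The Fisher information ignores the dependence of
    # the variance weights on z, which can make raw steps overshoot and
    # cycle; halving any sample's step until its score magnitude stops
    # increasing restores monotone progress.
    zscore <- function(zv) {
      sc <- numeric(n); info <- numeric(n)
      for (k in seq_along(vfs)) {
        vf <- vfs[[k]]
        eta <- linear_predictor(vf, zcol(Z, zv, m), m)
        bl <- if (vf$family == "count")
          count_z_block(vf, count_state(vf, eta), vf$loadings[m, ])
        else gauss_z_block(vf, eta, vf$loadings[m, ])
        sc <- sc + bl$score; info <- info + bl$info
      }
      list(sc = sc, info = info)
    }
    cur <- zscore(z)
    if (constrained) {
      ltang <- cbind(if (m > 1L)
        gradient$Lambda[, seq_len(m - 1L), drop = FALSE], lambda,
        block_basis(gradient))
      u <- as.vector(crossprod(cdes, cur$sc))
      Jl <- crossprod(cdes, cur$info * cdes)
      diag(Jl) <- diag(Jl) + 1e-10 * max(mean(diag(Jl)), 1e-12)
      # a singular system means the restrictions exhaust the gradient
      # space (no free direction left); the dimension will then be caught
      # as degenerate
      dl <- tryCatch(kkt_step(Jl, u, ltang),
                     error = function(e) numeric(length(lambda)))
      pu <- as.vector(project_out(u, ltang))
      retract <- function(l) project_gradient(l,
        if (m > 1L) gradient$Lambda[, seq_len(m - 1L), drop = FALSE],
        gradient$blocks)$l
      for (t in 1:6) {
        u_new <- project_out(crossprod(cdes,
          zscore(as.vector(cdes %*% retract(lambda + dl)))$sc), ltang)
        if (sum(u_new^2) <= sum(pu^2) || sum(pu^2) < 1e-24) break
        dl <- dl / 2
      }
      lambda <- retract(lambda + relax * dl)
      z <- as.vector(cdes %*% lambda)
    } else {
      ztang <- cbind(rep(1, n), Zprev)
      step <- kkt_step(cur$info, cur$sc, ztang)
      psc <- as.vector(project_out(cur$sc, ztang))
      for (t in 1:6) {
        nxt <- as.vector(project_out(zscore(z + step)$sc, ztang))
        if (sum(nxt^2) <= sum(psc^2) || sum(psc^2) < 1e-24) break
        step <- step / 2
      }
      z <- z + relax * step
    }

    # (b) loading rows, one view at a time: restricted Gauss-Newton
    # (count) or exact restricted least squares (gaussian), both via the
    # KKT system of the loading restrictions at the current point
    for (k in seq_along(vfs)) {
      vf <- vfs[[k]]
      Zm <- zcol(Z, z, m)
      gtang <- t(vf$loadings[seq_len(if (constrained) m - 1L else m), ,
                             drop = FALSE]) * vf$omega
      if (constrained && m == 1L) gtang <- NULL
      if (vf$family == "count")
        gtang <- cbind(rep(1, vf$p), gtang)
      eta <- linear_predictor(vf, Zm, m)
      if (vf$family == "count") {
        # damped restricted Gauss-Newton: the variance weights move with
        # gamma through the trend, so halve the step until the projected
        # score norm stops increasing
        st <- count_state(vf, eta)
        gs <- count_gamma_step(vf, st, z, C = gtang)
        dg <- gs$delta
        ps0 <- sum(project_out(gs$score, gtang)^2)
        for (t in 1:6) {
          vtry <- vf; vtry$loadings[m, ] <- vf$loadings[m, ] + dg
          st2 <- count_state(vtry, linear_predictor(vtry, Zm, m))
          ps1 <- sum(project_out(count_gamma_score(vtry, st2, z), gtang)^2)
          if (ps1 <= ps0 || ps0 < 1e-24) break
          dg <- dg / 2
        }
      } else {
        bl <- gauss_theta_block(vf, eta, z)
        dg <- kkt_step(bl$info, bl$score, gtang)
      }
      vfs[[k]]$loadings[m, ] <- vf$loadings[m, ] + relax * dg
    }

    # (c) re-impose restrictions exactly (a small retraction, since the
    # steps above were tangential)
    if (constrained) {
      for (k in seq_along(vfs)) {
        pr <- project_loading(vfs[[k]]$loadings[m, ],
                if (m > 1L) vfs[[k]]$loadings[seq_len(m - 1L), , drop = FALSE],
                vfs[[k]]$omega, center = vfs[[k]]$family == "count")
        vfs[[k]]$loadings[m, ] <- pr$g
      }
    } else {
      z <- project_scores(z, Zprev)
      for (k in seq_along(vfs)) {
        pr <- project_loading(vfs[[k]]$loadings[m, ],
                if (m > 1L) vfs[[k]]$loadings[seq_len(m - 1L), , drop = FALSE],
                vfs[[k]]$omega, center = vfs[[k]]$family == "count")
        vfs[[k]]$loadings[m, ] <- if (pr$norm > 0) pr$g / pr$norm else pr$g
      }
    }

    delta <- max(abs(z - z_old),
                 max(vapply(seq_along(vfs), function(k)
                   max(abs(vfs[[k]]$loadings[m, ] - g_old[[k]])), 0)))

    # adaptive relaxation: oscillating consecutive steps (negative
    # direction cosine, the signature of an alternation eigenvalue near
    # -1) shrink the step fraction; persistent same-direction steps (a
    # slow contraction) restore it
    this_step <- c(z - z_old,
                   unlist(lapply(seq_along(vfs), function(k)
                     vfs[[k]]$loadings[m, ] - g_old[[k]])))
    if (!is.null(prev_step)) {
      den <- sqrt(sum(this_step^2) * sum(prev_step^2))
      cs <- if (den > 0) sum(this_step * prev_step) / den else 0
      if (cs < -0.2) relax <- max(relax * 0.6, 0.1)
      else if (cs > 0.2) relax <- min(relax * 1.25, 1)
    }
    prev_step <- this_step

    # (d) variance-model re-estimation on the first few passes
    if (trend_live && it <= max_trend_iter) {
      ch <- 0
      for (k in seq_along(vfs)) {
        upd <- refresh_variance(vfs[[k]], zcol(Z, z, m), m, m)
        ch <- max(ch, variance_change(vfs[[k]], upd))
        vfs[[k]] <- upd
      }
      if (ch < 0.01 || it == max_trend_iter) trend_live <- FALSE
      next                      # do not test convergence while models move
    }
    if (delta < tol) break
  }

  psi <- sum(z^2)
  psi_floor <- n * 1e-12
  if (m > 1L)
    psi_floor <- max(psi_floor, 1e-10 * max(colSums(
      Z[, seq_len(m - 1L), drop = FALSE]^2)))
  if (psi < psi_floor)
    return(list(degenerate = TRUE))

  # sign convention: largest-|loading| entry of the first view positive
  g1 <- vfs[[1L]]$loadings[m, ]
  if (g1[which.max(abs(g1))] < 0) {
    z <- -z
    for (k in seq_along(vfs)) vfs[[k]]$loadings[m, ] <- -vfs[[k]]$loadings[m, ]
    if (constrained) lambda <- -lambda
  }
  Z[, m] <- z
  if (constrained) gradient$Lambda[, m] <- lambda

  fit_tmp <- structure(list(views = vfs, scores = Z, gradient = gradient,
                            M = m), class = "compint")
  msz <- max(abs(quasi_score(fit_tmp, dimension = m, block = "scores")))
  msl <- max(vapply(seq_along(vfs), function(k)
    max(abs(quasi_score(fit_tmp, view = k, dimension = m,
                        block = "loadings"))), 0))
  if (verbose)
    message(sprintf(
      "dim %d: %d iter, delta %.2e, |score| z %.2e loadings %.2e, psi %.3g",
      m, it, delta, msz, msl, psi))
  conv <- data.frame(dimension = m, iterations = it,
                     converged = delta < tol, delta = delta,
                     max_score_scores = msz, max_score_loadings = msl,
                     psi = psi)
  if (!conv$converged)
    warning("dimension ", m, " did not converge in ", max_iter,
            " iterations (delta = ", signif(delta, 3), ")")
  list(vfs = vfs, Z = Z, gradient = gradient, conv = conv,
       degenerate = FALSE)
}

# Z with column m replaced by the working score vector.
zcol <- function(Z, z, m) { Z[, m] <- z; Z }

# Re-estimate the variance model of a view conditional on dimensions
# 1..dims, storing it as the model for dimension `store`.
refresh_variance <- function(vf, Z, dims, store) {
  if (is.matrix(Z)) Zm <- Z else Zm <- matrix(Z, ncol = 1L)
  eta <- linear_predictor(vf, Zm, dims)
  E <- if (vf$family == "count") softmax_rows(eta) * vf$indep$depths else eta
  x <- vf$x0; x[!vf$obs] <- NA
  rv <- feature_weighted_variance(x, E, vf$indep$depths)
  if (vf$family == "count") {
    vf$trend <- suppressWarnings(fit_variance_trend(vf$indep$pi_indep, rv))
    vf$trends[[store]] <- vf$trend
  } else {
    nconf <- if (is.null(vf$conf_design)) 0L else ncol(vf$conf_design)
    df <- pmax(colSums(vf$obs) - 1L - dims - nconf, 1L)
    vf$sigma2 <- shrink_variances(rv, df)$post_var
    vf$sigma2_dims[[store]] <- vf$sigma2
  }
  vf
}

# Relative change between a view's previous and updated variance model,
# evaluated on a grid (counts) or per feature (gaussian).
variance_change <- function(old, new) {
  if (old$family == "count") {
    if (is.null(old$trend)) return(Inf)
    q <- stats::quantile(old$indep$pi_indep, c(.1, .25, .5, .75, .9, .99))
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    max(abs(trend_value(new$trend, q) / trend_value(old$trend, q) - 1))
  } else {
    if (is.null(old$sigma2)) return(Inf)
    max(abs(new$sigma2 / old$sigma2 - 1))
  }
}

# Deterministic start for dimension m: clr-scale (counts, pseudocount 0.5)
# or raw (gaussian) working residuals about the lower-dimensional fit,
# stacked across views after scaling each view to unit mean square, then
# the leading singular-vector pair.  The pseudocount appears only here,
# never in the model itself.
init_dimension <- function(vfs, Z, m) {
  n <- nrow(vfs[[1L]]$x0)
  blocks <- list(); scales <- numeric(length(vfs))
  for (k in seq_along(vfs)) {
    vf <- vfs[[k]]
    eta <- linear_predictor(vf, Z, m - 1L)
    if (vf$family == "count") {
      q <- vf$x0 + 0.5
      lw <- log(q) - rowMeans(log(q))
      r <- lw - eta
    } else r <- vf$x0 - eta
    r[!vf$obs] <- 0
    scales[k] <- sqrt(mean(r[vf$obs]^2))
    if (scales[k] == 0) scales[k] <- 1
    blocks[[k]] <- r / scales[k]
  }
  sv <- svd(do.call(cbind, blocks), nu = 1L, nv = 1L)
  v1 <- sv$v[, 1L]
  if (v1[which.max(abs(v1))] < 0) { v1 <- -v1; sv$u[, 1L] <- -sv$u[, 1L] }
  sd1 <- sqrt(sv$d[1L])
  at <- 0L; gammas <- list()
  for (k in seq_along(vfs)) {
    p <- vfs[[k]]$p
    gammas[[k]] <- sd1 * scales[k] * v1[at + seq_len(p)]
    at <- at + p
  }
  list(z = sd1 * sv$u[, 1L], gammas = gammas)
}

# Estimate confounder coefficients for one view under the independence
# model (no latent terms), then freeze them.  Count views: cyclic
# Gauss-Newton over the design columns with the softmax machinery (rows
# centered: the clr scale fixes each row only up to a constant); the
# abundance-variance trend is re-estimated once after a first pass.
# Gaussian views: per-feature least squares via the pseudoinverse (dummy
# blocks are rank-deficient by construction).
fit_confounders <- function(vf, design, tol) {
  vf$conf_design <- design
  d <- ncol(design); p <- vf$p
  vf$conf_coefs <- matrix(0, d, p, dimnames = list(colnames(design),
                                                   vf$feature_ids))
  Z0 <- matrix(0, nrow(design), 1L)
  if (vf$family == "gaussian") {
    r <- vf$x0 - matrix(vf$indep$offset, nrow(design), p, byrow = TRUE)
    pinv <- function(A) {
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-10
      sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    }
    if (all(vf$obs)) {
      vf$conf_coefs <- pinv(design) %*% r
    } else {
      for (j in seq_len(p)) {
        idx <- vf$obs[, j]
        vf$conf_coefs[, j] <-
          pinv(design[idx, , drop = FALSE]) %*% r[idx, j]
      }
    }
    return(vf)
  }
  vf <- refresh_variance(vf, Z0, 0L, 1L)   # trend under independence
  for (pass in seq_len(100L)) {
    ch <- 0
    for (k in seq_len(d)) {
      st <- count_state(vf, linear_predictor(vf, Z0, 0L))
      stp <- count_gamma_step(vf, st, design[, k])
      row <- vf$conf_coefs[k, ] + stp$delta
      row <- row - mean(row)
      ch <- max(ch, max(abs(row - vf$conf_coefs[k, ])))
      vf$conf_coefs[k, ] <- row
    }
    if (pass == 2L) vf <- refresh_variance(vf, Z0, 0L, 1L)
    if (ch < max(tol, 1e-8) && pass > 2L) break
  }
  vf
}
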