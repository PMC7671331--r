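#' Parametric multi-view simulator with differential-abundance ground truth
#'
#' Generates negative-binomial count views and gaussian views for two
#' equally sized sample groups.  Per-feature parameters are drawn from
#' configurable parametric pools (log-normal baseline abundances/means,
#' gamma dispersions and standard deviations) that stand in for parameter
#' pools estimated from real datasets.  A fraction `da_fraction` of
#' features in each view is differentially abundant (DA): in group 2 their
#' expected (pre-normalization) mean is multiplied by `fold_change_count`
#' (count views) or `1 + fold_change_gaussian` (gaussian views).
#'
#' For count views with `compensation = TRUE`, part of the DA features is
#' increased `fold_change_count`-fold and the remaining DA features are
#' scaled down by the common factor that exactly preserves the total
#' expected abundance, so the *relative* abundances of non-DA features are
#' unchanged between groups; without compensation all DA features go up,
#' and renormalization drags every non-DA relative abundance down (the
#' compositional artifact).  Counts are drawn with per-sample depth factors
#' so library sizes vary.
#'
#' @param n number of samples (even; two equal groups).
#' @param p integer vector: features per view.
#' @param families per view, `"count"` or `"gaussian"`.
#' @param da_fraction fraction of DA features per view.
#' @param fold_change_count multiplicative group-2 mean change, count views.
#' @param fold_change_gaussian relative group-2 mean shift, gaussian views.
#' @param compensation balance DA increases and decreases (count views).
#' @param depth_meanlog,depth_sdlog log-normal sequencing-depth pool.
#' @param abundance_sdlog spread of log baseline abundances (count views).
#' @param dispersion_shape,dispersion_rate gamma pool of NB dispersions
#'   (variance = mu + dispersion * mu^2).
#' @param gauss_meanlog,gauss_sdlog log-normal pool of gaussian feature
#'   means.
#' @param gauss_sd_shape,gauss_sd_rate gamma pool of gaussian feature sds.
#' @param seed optional integer seed for reproducibility.
#' @return list with `views` (list of [view_data()]), and `truth`: `groups`
#'   (factor), and per view a data.frame with `feature`, `da`, `direction`
#'   (+1/-1/0) and `fold_change` (applied multiplier).
#' @export
simulate_views <- function(n = 40L, p = c(1000L, 1000L),
                           families = c("count", "gaussian"),
                           da_fraction = 0.10, fold_change_count = 4,
                           fold_change_gaussian = 0.1, compensation = TRUE,
                           depth_meanlog = log(2e4), depth_sdlog = 0.5,
                           abundance_sdlog = 2,
                           dispersion_shape = 2, dispersion_rate = 4,
                           gauss_meanlog = 2, gauss_sdlog = 0.7,
                           gauss_sd_shape = 4, gauss_sd_rate = 4,
                           seed = NULL) {
  if (n %% 2L != 0L) stop("'n' must be even (two equal groups)")
  if (da_fraction <= 0 || da_fraction >= 1)
    stop("'da_fraction' must lie in (0, 1)")
  families <- rep_len(families, length(p))
  if (!is.null(seed)) set.seed(seed)
  groups <- factor(rep(c("g1", "g2"), each = n %/% 2L))
  g2 <- groups == "g2"
  views <- list(); truth <- list(groups = groups, views = list())

  for (v in seq_along(p)) {
    pv <- p[v]
    nda <- round(da_fraction * pv)
    da_idx <- sample.int(pv, nda)
    direction <- integer(pv)
    fc <- rep(1, pv)
    if (families[v] == "count") {
      lambda <- stats::rlnorm(pv, 0, abundance_sdlog)
      disp <- stats::rgamma(pv, shape = dispersion_shape,
                            rate = dispersion_rate)
      lambda2 <- lambda
      if (compensation) {
        # assign ~1/(fc + 1) of the DA mass to the "up" set (taken from
        # the smallest DA features so the target is reachable under
        # heavy-tailed abundances); the common down-scaling factor that
        # preserves total abundance is then near 1/fc and positive
        ord <- da_idx[order(lambda[da_idx])]
        mass <- lambda[ord]
        up <- ord[cumsum(mass) <= sum(mass) / (fold_change_count + 1)]
        if (!length(up)) up <- ord[1L]
        if (length(up) == length(ord)) up <- ord[-length(ord)]
        down <- setdiff(ord, up)
        fdown <- 1 - (fold_change_count - 1) * sum(lambda[up]) /
          sum(lambda[down])
        if (fdown <= 0)
          stop("compensation infeasible for this abundance draw")
        lambda2[up] <- lambda[up] * fold_change_count
        lambda2[down] <- lambda[down] * fdown
        direction[up] <- 1L; direction[down] <- -1L
        fc[up] <- fold_change_count; fc[down] <- fdown
      } else {
        lambda2[da_idx] <- lambda[da_idx] * fold_change_count
        direction[da_idx] <- 1L
        fc[da_idx] <- fold_change_count
      }
      depths <- stats::rlnorm(n, depth_meanlog, depth_sdlog)
      pi1 <- lambda / sum(lambda)
      pi2 <- lambda2 / sum(lambda2)
      mu <- outer(depths, pi1)
      mu[g2, ] <- outer(depths[g2], pi2)
      x <- matrix(stats::rnbinom(n * pv, mu = mu,
                                 size = rep(1 / pmax(disp, 1e-8), each = n)),
                  n, pv)
      vd <- view_data(x, family = "count", name = paste0("count", v))
    } else {
      mus <- stats::rlnorm(pv, gauss_meanlog, gauss_sdlog)
      sds <- stats::rgamma(pv, shape = gauss_sd_shape, rate = gauss_sd_rate)
      mu <- matrix(mus, n, pv, byrow = TRUE)
      mu[g2, da_idx] <- mu[g2, da_idx] * (1 + fold_change_gaussian)
      direction[da_idx] <- 1L
      fc[da_idx] <- 1 + fold_change_gaussian
      x <- mu + matrix(stats::rnorm(n * pv, sd = rep(sds, each = n)), n, pv)
      vd <- view_data(x, family = "gaussian", name = paste0("gaussian", v))
    }
    rownames(vd$x) <- paste0("s", seq_len(n))
    views[[v]] <- vd
    truth$views[[v]] <- data.frame(
      feature = colnames(vd$x), da = direction != 0L,
      direction = direction, fold_change = fc)
  }
  names(views) <- names(truth$views) <- vapply(views, `[[`, "", "name")
  list(views = views, truth = truth)
}

#' Independently permute the samples of each view
#'
#' Shuffles the rows of every view with an independent permutation.  Each
#' view's content is unchanged as a multiset of sample rows (marginal
#' distributions, depths and within-view structure are preserved) but the
#' cross-view alignment is destroyed, giving a null setting with real data
#' characteristics.
#'
#' @param views list of [view_data()] objects.
#' @param seed optional integer seed.
#' @param permutations optional list of explicit permutation index vectors,
#'   one per view (overrides random draws).
#' @return list of permuted views (sample ids keep their original order).
#' @export
permute_views <- function(views, seed = NULL, permutations = NULL) {
  if (length(views) < 2L) stop("need at least two views to permute")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(views), function(k) {
    v <- views[[k]]
    perm <- if (!is.null(permutations)) permutations[[k]] else
      sample.int(nrow(v$x))
    ids <- rownames(v$x)
    v$x <- v$x[perm, , drop = FALSE]
    rownames(v$x) <- ids
    v
  }) |> stats::setNames(names(views))
}
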