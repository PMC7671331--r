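#' Correlation of sample scores with sample sums
#'
#' A well-behaved compositional ordination should not track sequencing
#' depth: this computes the Pearson correlation of each score column with
#' the per-view sample sums and with the overall sum across views (missing
#' cells counted as zero).  Values near zero indicate depth insensitivity.
#'
#' @param scores n-by-M score matrix (or a [compint()] fit).
#' @param views list of [view_data()] objects aligned with the scores.
#' @return matrix with one row per score dimension and one column per view
#'   plus `overall`.
#' @export
score_sum_correlation <- function(scores, views) {
  if (inherits(scores, "compint")) scores <- scores$scores
  scores <- as.matrix(scores)
  sums <- vapply(views, function(v) rowSums(v$x, na.rm = TRUE),
                 numeric(nrow(scores)))
  sums <- cbind(sums, overall = rowSums(sums))
  out <- matrix(0, ncol(scores), ncol(sums),
                dimnames = list(colnames(scores), colnames(sums)))
  for (m in seq_len(ncol(scores))) {
    z <- scores[, m]
    if (stats::sd(z) == 0) {
      warning("score column ", m, " is constant; correlation reported as 0")
      next
    }
    out[m, ] <- apply(sums, 2L, function(s)
      if (stats::sd(s) == 0) 0 else stats::cor(z, s))
  }
  out
}

#' Standardized Wilcoxon statistic on loading inner products
#'
#' Computes the inner products of all pairs of feature loading vectors
#' (within views and between views, or between views only) and asks, via a
#' Wilcoxon rank-sum comparison, whether truly correlated feature pairs
#' rank higher than the rest:
#' `z = (W - n1 (n1 + n2 + 1) / 2) / sqrt(n1 n2 (n1 + n2 + 1) / 12)`
#' with midranks for ties, where `W` is the rank sum of the truly
#' correlated group.  Large positive values mean the loadings discriminate
#' correlated pairs well; a shuffled truth gives values near zero.
#'
#' A pair counts as truly correlated when both features are differentially
#' abundant in the same direction (they respond to the same group signal).
#'
#' @param loadings list of M-by-p loading matrices (or a [compint()] fit).
#' @param truth simulation truth as returned by [simulate_views()], or a
#'   list of per-view direction vectors (+1/-1/0).
#' @param between_view_only use only pairs whose features lie in different
#'   views.
#' @return the standardized statistic (scalar).
#' @export
wilcoxon_inner_product <- function(loadings, truth,
                                   between_view_only = FALSE) {
  if (inherits(loadings, "compint"))
    loadings <- lapply(loadings$views, `[[`, "loadings")
  dirs <- if (!is.null(truth$views))
    lapply(truth$views, `[[`, "direction") else truth
  stopifnot(length(loadings) == length(dirs))
  L <- do.call(cbind, loadings)
  d <- unlist(dirs, use.names = FALSE)
  if (ncol(L) != length(d))
    stop("truth labels do not match the number of features")
  ip <- crossprod(L)                       # gamma_a' gamma_b for all pairs
  P <- ncol(L)
  ut <- upper.tri(ip)
  if (between_view_only) {
    vid <- rep(seq_along(loadings),
               vapply(loadings, ncol, integer(1L)))
    ut <- ut & outer(vid, vid, `!=`)
  }
  x <- ip[ut]
  corr <- (outer(d, d) == 1L)[ut]          # same nonzero direction
  wilcoxon_z(x, corr)
}

# standardized rank-sum statistic with midranks, no tie correction
wilcoxon_z <- function(x, group1) {
  n1 <- sum(group1); n2 <- sum(!group1)
  if (n1 == 0L || n2 == 0L)
    stop("both correlated and uncorrelated pairs are required")
  W <- sum(rank(x)[group1])
  (W - n1 * (n1 + n2 + 1) / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
}

#' Pseudo-F statistic of group separation in score space
#'
#' Quantifies how well samples of the same group cluster in the
#' M-dimensional score space as the ratio of between-group to within-group
#' dispersion: `(SSB / (k - 1)) / (SSW / (n - k))` on Euclidean distances
#' (the Calinski-Harabasz form).  `type = "permanova"` computes the same
#' ratio from pairwise distances only (the distance-based form), which
#' coincides with the first for Euclidean distances but accepts any
#' dissimilarity.  Perfect separation with zero within-group spread yields
#' `Inf`.
#'
#' @param scores n-by-M score matrix (or a [compint()] fit).
#' @param groups group labels, at least two groups with two samples each.
#' @param type `"calinski"` (default) or `"permanova"`.
#' @param dist_method distance for `type = "permanova"`.
#' @return the statistic (possibly `Inf` for degenerate separation).
#' @export
pseudo_f <- function(scores, groups, type = c("calinski", "permanova"),
                     dist_method = "euclidean") {
  if (inherits(scores, "compint")) scores <- scores$scores
  scores <- as.matrix(scores)
  type <- match.arg(type)
  groups <- factor(groups)
  k <- nlevels(groups); n <- nrow(scores)
  if (k < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs at least two samples")
  if (type == "calinski") {
    gm <- colMeans(scores)
    ssb <- 0; ssw <- 0
    for (g in levels(groups)) {
      sg <- scores[groups == g, , drop = FALSE]
      cg <- colMeans(sg)
      ssb <- ssb + nrow(sg) * sum((cg - gm)^2)
      ssw <- ssw + sum(sweep(sg, 2L, cg)^2)
    }
  } else {
    d2 <- as.matrix(stats::dist(scores, method = dist_method))^2
    sst <- sum(d2) / (2 * n)
    ssw <- 0
    for (g in levels(groups)) {
      idx <- groups == g
      ssw <- ssw + sum(d2[idx, idx]) / (2 * sum(idx))
    }
    ssb <- sst - ssw
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}
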