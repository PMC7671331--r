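#' Multiplot coordinates of a fitted integration
#'
#' Assembles the coordinates of a biplot/triplot/quadriplot: sample dots at
#' their score pairs, feature labels at their loading pairs for every view,
#' and (for constrained fits) gradient labels at their rows of Lambda.
#' Features are ranked by the Euclidean norm of their loadings in the
#' chosen dimensions, and the threshold selects which are *displayed*;
#' stored loadings are never altered, and ties at the cutoff are all
#' retained.
#'
#' @param fit a [compint()] fit.
#' @param dims pair of dimensions to display.
#' @param threshold either `"all"`, a single number `k` (top-k features per
#'   view by loading norm), or `list(quantile = q)` to keep the top
#'   `(1 - q)` norm quantile.
#' @return object of class `multiplot` with elements `samples` (data.frame
#'   id/x/y), `features` (list per view of data.frame id/x/y/norm/shown)
#'   and optional `gradient`.
#' @export
multiplot_coordinates <- function(fit, dims = c(1L, 2L), threshold = 15) {
  stopifnot(inherits(fit, "compint"))
  if (max(dims) > fit$M || length(dims) != 2L)
    stop("'dims' must be two fitted dimensions")
  samples <- data.frame(id = fit$sample_ids,
                        x = fit$scores[, dims[1L]],
                        y = fit$scores[, dims[2L]], row.names = NULL)
  features <- lapply(fit$views, function(vf) {
    g <- t(vf$loadings[dims, , drop = FALSE])
    nrm <- sqrt(rowSums(g^2))
    shown <- if (identical(threshold, "all")) rep(TRUE, length(nrm))
    else if (is.list(threshold)) nrm >= stats::quantile(nrm,
                                                        threshold$quantile)
    else if (is.numeric(threshold)) {
      k <- min(threshold, length(nrm))
      nrm >= sort(nrm, decreasing = TRUE)[k]   # ties at the cutoff retained
    } else stop("unknown threshold rule")
    data.frame(id = vf$feature_ids, x = g[, 1L], y = g[, 2L],
               norm = nrm, shown = shown, row.names = NULL)
  })
  gradient <- NULL
  if (!is.null(fit$gradient))
    gradient <- data.frame(id = rownames(fit$gradient$Lambda),
                           x = fit$gradient$Lambda[, dims[1L]],
                           y = fit$gradient$Lambda[, dims[2L]],
                           row.names = NULL)
  structure(list(samples = samples, features = features,
                 gradient = gradient, dims = dims),
            class = "multiplot")
}

#' Plot a fitted integration as a multiplot
#'
#' Samples are dots, feature labels (thresholded by loading norm) are
#' colored by view, and gradient labels appear for constrained fits.  Axes
#' are forced square (`coord_fixed(1)`) so Euclidean distances between
#' sample dots are faithful; the method deliberately reports no
#' "variance explained" percentages, because such fractions are not
#' comparable across heterogeneous views.
#'
#' @param x a [compint()] fit.
#' @param dims pair of dimensions.
#' @param threshold display threshold, see [multiplot_coordinates()].
#' @param color_by,shape_by optional vectors (or metadata column values)
#'   mapped to sample dot color/shape.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.compint <- function(x, dims = c(1L, 2L), threshold = 15,
                         color_by = NULL, shape_by = NULL, ...) {
  mp <- multiplot_coordinates(x, dims = dims, threshold = threshold)
  samples <- mp$samples
  if (!is.null(color_by)) samples$color <- color_by
  if (!is.null(shape_by)) samples$shape <- shape_by
  feats <- do.call(rbind, lapply(names(mp$features), function(nm) {
    f <- mp$features[[nm]][mp$features[[nm]]$shown, , drop = FALSE]
    if (nrow(f)) cbind(f, view = nm)
  }))
  sample_layer <-
    if (is.null(color_by) && is.null(shape_by))
      ggplot2::geom_point(data = samples,
                          ggplot2::aes(x = .data$x, y = .data$y),
                          colour = "grey25")
    else if (is.null(shape_by))
      ggplot2::geom_point(data = samples,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$color))
    else if (is.null(color_by))
      ggplot2::geom_point(data = samples,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       shape = .data$shape),
                          colour = "grey25")
    else
      ggplot2::geom_point(data = samples,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$color,
                                       shape = .data$shape))
  g <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey70") +
    sample_layer +
    ggplot2::geom_text(data = feats,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$id, colour = .data$view),
                       size = 2.5, show.legend = FALSE) +
    ggplot2::coord_fixed(ratio = 1) +
    ggplot2::labs(x = paste("Dimension", dims[1L]),
                  y = paste("Dimension", dims[2L]), colour = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(mp$gradient))
    g <- g + ggplot2::geom_text(data = mp$gradient,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$id),
                                colour = "black", fontface = "bold",
                                size = 3)
  g
}

#' Projection of a sample's score onto a feature link
#'
#' For two features a, b of the same compositional view, the change of
#' their log-ratio relative to the independence model in sample i is the
#' projection of the sample's score onto the link between the loadings:
#' `log(pi_ia / pi_ib) - log(pi_a / pi_b under independence)
#'  = Z_i' (gamma_a - gamma_b)`.
#' This is the quantity a reader extracts geometrically from a multiplot.
#' Interpretation across two different compositional views is not defined,
#' so both features must come from the same view.
#'
#' @param fit a [compint()] fit.
#' @param view a compositional (count) view index or name.
#' @param feature_a,feature_b feature ids or indices.
#' @param sample sample id or index.
#' @return scalar projection (log-ratio units).
#' @export
feature_link_projection <- function(fit, view, feature_a, feature_b,
                                    sample) {
  stopifnot(inherits(fit, "compint"))
  vf <- fit$views[[view]]
  if (vf$family != "count")
    stop("feature links are defined for compositional views")
  ga <- vf$loadings[, feature_a]
  gb <- vf$loadings[, feature_b]
  sum(fit$scores[sample, ] * (ga - gb))
}
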