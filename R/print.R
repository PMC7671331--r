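#' @export
print.compint <- function(x, ...) {
  cat(sprintf("Joint latent-variable integration: %d view(s), %d samples, %d dimension(s)%s\n",
              length(x$views), nrow(x$scores), x$M,
              if (!is.null(x$gradient)) " (constrained)" else ""))
  for (vf in x$views)
    cat(sprintf("  view '%s' (%s): %d features\n", vf$name, vf$family,
                vf$p))
  cat(sprintf("psi (score scales): %s\n",
              paste(signif(x$psi, 4), collapse = ", ")))
  cv <- x$convergence
  for (i in seq_len(nrow(cv)))
    cat(sprintf("  dim %d: %d iterations, %s (max |proj. score| %.2e)\n",
                cv$dimension[i], cv$iterations[i],
                if (cv$converged[i]) "converged" else "NOT converged",
                max(cv$max_score_scores[i], cv$max_score_loadings[i])))
  invisible(x)
}

#' @export
summary.compint <- function(object, ...) {
  print(object)
  cat("\nConvergence detail:\n")
  print(object$convergence, row.names = FALSE)
  invisible(object)
}

#' @export
print.multiplot <- function(x, ...) {
  cat(sprintf("multiplot of dims (%d, %d): %d samples, %s feature labels%s\n",
              x$dims[1L], x$dims[2L], nrow(x$samples),
              paste(vapply(x$features, function(f) sum(f$shown), 0L),
                    collapse = "+"),
              if (!is.null(x$gradient)) ", gradient labels" else ""))
  invisible(x)
}

#' @export
print.variance_trend <- function(x, ...) {
  cat(sprintf("abundance-variance trend (%s), Poisson below pi = %.3g\n",
              x$type, x$pi_low))
  invisible(x)
}
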