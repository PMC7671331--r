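#' Centered log-ratio transform
#'
#' The clr maps a vector of strictly positive values to log-ratio space by
#' dividing each part by the geometric mean of all parts and taking logs.
#' It is the link function used for compositional views: it allocates a
#' single coordinate to each feature, which is what makes compositional
#' biplots readable.  The input need not sum to one; the clr is invariant to
#' overall scaling, so any positive rescaling of `x` gives the same result.
#'
#' @param x numeric vector, all entries strictly positive.
#' @return numeric vector of the same length summing to zero.
#' @seealso [clr_inverse()], [perturb()]
#' @examples
#' clr(c(0.5, 0.25, 0.25))
#' all.equal(clr(1:4), clr(10 * (1:4)))
#' @export
clr <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("'x' must be a numeric vector with at least two parts")
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("clr undefined: entry ", bad[1L], " is not strictly positive")
  lx <- log(x)
  lx - mean(lx)
}

#' Inverse clr (softmax)
#'
#' Maps any real vector to a composition: `exp(y)` renormalized to sum to
#' one.  Computed with max-subtraction so that linear predictors with very
#' large magnitude (which occur transiently during optimization) do not
#' overflow.  Shift-invariant: adding a constant to `y` does not change the
#' result, which is why clr vectors (sum zero) are the canonical
#' representatives.
#'
#' @param y finite numeric vector.
#' @return composition (strictly positive, sums to 1).
#' @examples
#' clr_inverse(c(0, 0, 0))
#' clr_inverse(clr(c(0.2, 0.3, 0.5)))
#' @export
clr_inverse <- function(y) {
  if (!is.numeric(y) || any(!is.finite(y)))
    stop("clr_inverse requires finite numeric input")
  e <- exp(y - max(y))
  e / sum(e)
}

# row-wise softmax of a matrix of linear predictors, max-subtraction per row
softmax_rows <- function(eta) {
  e <- exp(eta - apply(eta, 1L, max))
  e / rowSums(e)
}

#' Compositional perturbation
#'
#' Aitchison's perturbation operator, the compositional analogue of
#' addition: multiply two positive vectors entrywise and renormalize to a
#' composition.  The uniform composition is the neutral element.
#'
#' @param u composition (strictly positive, summing to one up to rounding).
#' @param v strictly positive vector of the same length.
#' @return composition of the same length.
#' @examples
#' perturb(c(0.5, 0.3, 0.2), c(2, 1, 1))
#' @export
perturb <- function(u, v) {
  if (length(u) != length(v))
    stop("'u' and 'v' must have the same length")
  if (any(!is.finite(u) | u <= 0))
    stop("'u' must be a strictly positive composition")
  if (any(!is.finite(v) | v <= 0))
    stop("'v' must be strictly positive")
  w <- u * v
  w / sum(w)
}

#' Compose a sample's mean composition by chained perturbation
#'
#' Builds the modelled composition of one sample by starting from the
#' baseline (independence-model) composition and perturbing it, dimension by
#' dimension, with each loading direction powered by the sample's score:
#' `clr_inverse(u_x) (+) clr_inverse(g_1)^z_1 (+) ... (+) clr_inverse(g_M)^z_M`,
#' where powering is entrywise.  Algebraically this equals the softmax of
#' the linear predictor `u_x + z' G`, which is how the fitting code computes
#' means; this function exists because the chain form is the geometric
#' reading of the model (each dimension perturbs the composition with
#' direction `g_m` and strength `z_m`).
#'
#' @param u_x baseline clr vector (length p).
#' @param loadings M-by-p matrix of loading rows.
#' @param z numeric score vector of length M.
#' @return composition of length p.
#' @export
composition_chain <- function(u_x, loadings, z) {
  loadings <- rbind(loadings)
  if (ncol(loadings) != length(u_x))
    stop("ncol(loadings) must match length(u_x)")
  if (nrow(loadings) != length(z))
    stop("nrow(loadings) must match length(z)")
  out <- clr_inverse(u_x)
  for (m in seq_along(z))
    out <- perturb(out, clr_inverse(loadings[m, ])^z[m])
  out
}
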