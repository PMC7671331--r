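# Shared fixtures, all generated in code.

# Simulate directly from the integration model with known latent scores:
# a count view (clr link, negative binomial noise) and a gaussian view
# sharing the same Z.  Used for parameter-recovery oracles.
sim_from_model <- function(n = 40, p = 200, q = 200, seed = 1, M = 2,
                           sd_z = c(2, 1.2), depth = 1e4, noise_g = 1,
                           nb_size = 10) {
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * M), n, M)
  Z <- scale(Z, TRUE, FALSE)
  Z <- qr.Q(qr(Z))
  Z <- sweep(Z, 2L, sd_z * sqrt(n), `*`)
  u <- clr(stats::rlnorm(p, 0, 1.5))
  G <- matrix(stats::rnorm(M * p), M, p)
  G <- G - rowMeans(G)
  G <- G / sqrt(rowSums(G^2)) * 0.15 * sqrt(p)
  eta <- matrix(u, n, p, byrow = TRUE) + Z %*% G
  P <- exp(eta - apply(eta, 1L, max)); P <- P / rowSums(P)
  s <- stats::rlnorm(n, log(depth), 0.3)
  x <- matrix(stats::rnbinom(n * p, mu = P * s, size = nb_size), n, p)
  rownames(x) <- paste0("s", seq_len(n))
  uy <- stats::rnorm(q, 5, 1)
  Th <- matrix(stats::rnorm(M * q), M, q)
  Th <- Th / sqrt(rowSums(Th^2)) * 0.1 * sqrt(q)
  y <- matrix(uy, n, q, byrow = TRUE) + Z %*% Th +
    matrix(stats::rnorm(n * q, 0, noise_g), n, q)
  rownames(y) <- paste0("s", seq_len(n))
  list(views = list(view_data(x, "count", name = "counts"),
                    view_data(y, "gaussian", name = "gauss")),
       Z = Z, G = G, Theta = Th, u = u, depths = s)
}

# A small simulated two-view dataset and its fit, computed once per test
# session (several files exercise the same fitted object).
.fixture_env <- new.env(parent = emptyenv())

cached_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    sim <- simulate_views(n = 30, p = c(80, 60),
                          families = c("count", "gaussian"), seed = 3)
    .fixture_env$sim <- sim
    .fixture_env$fit <- suppressWarnings(compint(sim$views, M = 2))
  }
  list(sim = .fixture_env$sim, fit = .fixture_env$fit)
}

# random composition of length p
rcomp <- function(p) {
  x <- stats::rgamma(p, 2, 1) + 1e-6
  x / sum(x)
}
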