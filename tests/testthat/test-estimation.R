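test_that("single-feature quasi fit agrees with an independent Poisson IRLS", {
  set.seed(12)
  n <- 60
  z <- rnorm(n)
  s <- rlnorm(n, log(500), 0.4)
  x <- rpois(n, s * exp(-4 + 0.6 * z))
  fit <- fit_feature_ql(x, z, s)
  # independent oracle: standard IRLS for Poisson regression with offset
  beta <- c(log(sum(x) / sum(s)), 0)
  X <- cbind(1, z)
  for (i in 1:50) {
    mu <- s * exp(X %*% beta)
    W <- as.vector(mu)
    zz <- X %*% beta + (x - mu) / mu
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * zz))
    if (max(abs(beta_new - beta)) < 1e-12) break
    beta <- beta_new
  }
  expect_equal(unname(fit$coef), as.vector(beta), tolerance = 1e-6)
  expect_lt(max(abs(fit$score)), 1e-4)
})

test_that("fits are deterministic and the first dimension is M-independent", {
  cf <- cached_fit()
  sim <- cf$sim
  f1 <- suppressWarnings(compint(sim$views, M = 1))
  frep <- suppressWarnings(compint(sim$views, M = 1))
  expect_identical(f1$scores, frep$scores)     # no RNG in the default path
  # sequential fitting: dimension 1 of the M = 2 fit equals the M = 1 fit
  f2 <- cf$fit
  expect_equal(f1$scores[, 1], f2$scores[, 1], tolerance = 1e-8)
  expect_equal(f1$views[[1]]$loadings[1, ], f2$views[[1]]$loadings[1, ],
               tolerance = 1e-8)
  expect_equal(f1$views[[2]]$loadings[1, ], f2$views[[2]]$loadings[1, ],
               tolerance = 1e-8)
})

test_that("noiseless rank-1 gaussian data is solved at initialization", {
  set.seed(13)
  n <- 12; q <- 9
  z0 <- scale(rnorm(n))[, 1]
  y <- 2 + outer(z0, rnorm(q))
  rownames(y) <- paste0("s", 1:n)
  fit <- suppressWarnings(compint(view_data(y, "gaussian"), M = 1))
  # variance re-estimation passes aside, no iteration is needed
  expect_lte(fit$convergence$iterations, 8)
  expect_gt(abs(cor(fit$scores[, 1], z0)), 1 - 1e-9)
})

test_that("a single homoscedastic gaussian view reproduces the SVD", {
  set.seed(14)
  n <- 30; q <- 50
  y <- matrix(rnorm(n * q), n, q) + outer(rnorm(n, 0, 2), rnorm(q))
  rownames(y) <- paste0("s", 1:n)
  fit <- suppressWarnings(compint(view_data(y, "gaussian"), M = 1))
  pc1 <- svd(scale(y, TRUE, FALSE))$u[, 1]
  expect_gt(abs(cor(fit$scores[, 1], pc1)), 0.999)
})

test_that("identifiability restrictions hold after fitting", {
  cf <- cached_fit()
  fit <- cf$fit
  ZtZ <- crossprod(fit$scores)
  expect_lt(max(abs(ZtZ - diag(diag(ZtZ)))), 1e-6)
  expect_lt(max(abs(colSums(fit$scores))), 1e-6)
  for (vf in fit$views) {
    GOG <- vf$loadings %*% (vf$omega * t(vf$loadings))
    expect_lt(max(abs(GOG - diag(fit$M))), 1e-6)
    if (vf$family == "count")
      expect_lt(max(abs(rowSums(vf$loadings))), 1e-6)
  }
  expect_equal(fit$psi, diag(ZtZ), ignore_attr = TRUE)
})

test_that("quasi-scores vanish at the solution on the identified scale", {
  cf <- cached_fit()
  fit <- cf$fit
  for (m in 1:2) {
    expect_lt(max(abs(quasi_score(fit, dimension = m))), 100 * fit$tol)
    for (k in 1:2)
      expect_lt(max(abs(quasi_score(fit, view = k, dimension = m,
                                    block = "loadings"))), 100 * fit$tol)
  }
  # raw unprojected scores are reported in data units and need not vanish
  raw <- quasi_score(fit, dimension = 1, projected = FALSE,
                     standardized = FALSE)
  expect_true(all(is.finite(raw)))
})

test_that("two identical gaussian views get identical dimension-1 loadings", {
  set.seed(15)
  n <- 20; q <- 25
  y <- matrix(rnorm(n * q), n, q) + outer(rnorm(n, 0, 1.5), rnorm(q))
  rownames(y) <- paste0("s", 1:n)
  vs <- list(view_data(y, "gaussian", name = "a"),
             view_data(y, "gaussian", name = "b"))
  fit <- compint(vs, M = 1)
  l1 <- fit$views[[1]]$loadings[1, ]
  l2 <- fit$views[[2]]$loadings[1, ]
  expect_equal(abs(l1), abs(l2), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("scores are insensitive to one sample's sequencing depth", {
  # Poisson counts: the variance model Var = v(pi) s then holds exactly at
  # every depth, isolating the depth-insensitivity property itself
  sm <- sim_from_model(n = 30, p = 150, q = 100, seed = 16, nb_size = 1e8)
  vs <- lapply(sm$views, filter_features)
  f0 <- suppressWarnings(compint(vs, M = 1))
  vs2 <- vs
  vs2[[1]]$x[5, ] <- vs2[[1]]$x[5, ] * 10
  f1 <- suppressWarnings(compint(vs2, M = 1))
  # compare on the standardized score scale: psi (the overall score scale)
  # is a property of the whole fit and shifts slightly with total depth
  z0 <- f0$scores[, 1] / sd(f0$scores[, 1])
  z1 <- f1$scores[, 1] / sd(f1$scores[, 1])
  z1 <- z1 * sign(cor(z0, z1))
  expect_lt(abs(z1[5] - z0[5]), 0.1 * max(abs(z0[5]), 1))
  expect_gt(abs(cor(z0, z1)), 0.99)
})

test_that("confounder adjustment removes the group signal", {
  sim <- simulate_views(n = 30, p = c(100, 80),
                        families = c("count", "gaussian"), seed = 17)
  vs <- lapply(sim$views, filter_features)
  md <- data.frame(group = sim$truth$groups,
                   row.names = rownames(vs[[1]]$x))
  f_raw <- suppressWarnings(compint(vs, M = 1))
  f_adj <- suppressWarnings(compint(vs, M = 1, metadata = md,
                                    confounders = "group"))
  pf_raw <- pseudo_f(f_raw, sim$truth$groups)
  pf_adj <- pseudo_f(f_adj, sim$truth$groups)
  expect_gt(pf_raw, 10)
  expect_lt(pf_adj, 2)
})

test_that("constrained fits recover known gradient directions", {
  set.seed(18)
  n <- 40; p <- 150; q <- 60
  u <- clr(rlnorm(p, 0, 1.5))
  c1 <- scale(rnorm(n))[, 1]
  c2 <- scale(rnorm(n))[, 1]
  c2 <- scale(c2 - c1 * sum(c1 * c2) / sum(c1^2))[, 1]
  G1 <- rnorm(p); G1 <- G1 - mean(G1)
  G1 <- G1 / sqrt(sum(G1^2)) * 0.12 * sqrt(p)
  G2 <- rnorm(p); G2 <- G2 - mean(G2)
  G2 <- G2 / sqrt(sum(G2^2)) * 0.07 * sqrt(p)
  eta <- matrix(u, n, p, byrow = TRUE) + outer(c1 * 2, G1) +
    outer(c2 * 1.2, G2)
  P <- exp(eta - apply(eta, 1, max)); P <- P / rowSums(P)
  s <- rlnorm(n, log(1e4), 0.3)
  x <- matrix(rnbinom(n * p, mu = P * s, size = 10), n, p)
  rownames(x) <- paste0("s", 1:n)
  y <- matrix(rnorm(n * q, 4, 1), n, q) + outer(c1 * 2, rnorm(q, 0, 0.1)) +
    outer(c2 * 1.2, rnorm(q, 0, 0.1))
  rownames(y) <- paste0("s", 1:n)
  md <- data.frame(v1 = c1, v2 = c2, junk = rnorm(n),
                   row.names = paste0("s", 1:n))
  vs <- list(filter_features(view_data(x, "count")),
             view_data(y, "gaussian"))
  fit <- compint(vs, M = 2, metadata = md, constrain = c("v1", "v2", "junk"))
  L <- fit$gradient$Lambda
  expect_lt(max(abs(crossprod(L) - diag(2))), 1e-6)
  expect_gt(abs(L["v1", 1]), 0.95)
  expect_gt(abs(L["v2", 2]), 0.95)
  expect_lt(max(abs(L["junk", ])), 0.2)
})

test_that("constrained fits impose zero-sum blocks on categorical gradients", {
  sim <- simulate_views(n = 24, p = c(60, 50),
                        families = c("count", "gaussian"), seed = 19)
  md <- data.frame(group = sim$truth$groups,
                   batch = rep(c("b1", "b2", "b3"), 8),
                   cont = rnorm(24),
                   row.names = rownames(sim$views[[1]]$x))
  fit <- suppressWarnings(compint(sim$views, M = 2, metadata = md,
                                  constrain = c("group", "batch", "cont")))
  L <- fit$gradient$Lambda
  expect_lt(max(abs(crossprod(L) - diag(2))), 1e-6)
  for (idx in fit$gradient$blocks)
    expect_lt(max(abs(colSums(L[idx, , drop = FALSE]))), 1e-6)
  for (m in 1:2)
    expect_lt(max(abs(quasi_score(fit, dimension = m))), 100 * fit$tol)
})

test_that("missing cells are excluded, not imputed", {
  sm <- sim_from_model(n = 30, p = 120, q = 80, seed = 20)
  vs <- lapply(sm$views, filter_features)
  full <- suppressWarnings(compint(vs, M = 1))
  set.seed(21)
  vs2 <- vs
  for (k in 1:2) {
    idx <- sample(length(vs2[[k]]$x), round(0.1 * length(vs2[[k]]$x)))
    vs2[[k]]$x[idx] <- NA
  }
  vs2 <- lapply(vs2, filter_features)
  masked <- suppressWarnings(compint(vs2, M = 1))
  expect_gt(abs(cor(full$scores[, 1], masked$scores[, 1])), 0.95)
})

test_that("degenerate extra dimensions are dropped with a warning", {
  set.seed(22)
  n <- 10; q <- 6
  y <- 1 + outer(scale(rnorm(n))[, 1], rnorm(q))   # exactly rank 1
  rownames(y) <- paste0("s", 1:n)
  expect_warning(
    fit <- withCallingHandlers(
      compint(view_data(y, "gaussian"), M = 3),
      warning = function(w) {
        if (grepl("single-view", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    "degenerate")
  expect_lt(fit$M, 3)
})
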