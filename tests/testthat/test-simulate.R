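test_that("simulator flags the configured DA fraction with the right fold change", {
  sim <- simulate_views(n = 40, p = c(300, 200),
                        families = c("count", "gaussian"), seed = 23)
  expect_equal(sum(sim$truth$views[[1]]$da), 30)
  expect_equal(sum(sim$truth$views[[2]]$da), 20)
  up <- sim$truth$views[[1]]$direction == 1
  expect_true(all(sim$truth$views[[1]]$fold_change[up] == 4))
  gda <- sim$truth$views[[2]]$da
  expect_true(all(sim$truth$views[[2]]$fold_change[gda] == 1.1))
  expect_equal(as.vector(table(sim$truth$groups)), c(20, 20))
  expect_error(simulate_views(n = 7), "even")
  expect_error(simulate_views(da_fraction = 1.2), "da_fraction")
})

test_that("same seed reproduces bit-identical data", {
  a <- simulate_views(n = 20, p = c(50, 40), seed = 24)
  b <- simulate_views(n = 20, p = c(50, 40), seed = 24)
  expect_identical(a, b)
})

test_that("compensation preserves non-DA relative abundances between groups", {
  # Monte-Carlo over replicates: mean relative abundance of non-DA
  # features should differ < 1% between groups in expectation
  set.seed(25)
  rel_diff <- replicate(50, {
    sim <- simulate_views(n = 40, p = 200, families = "count",
                          compensation = TRUE, depth_sdlog = 0,
                          seed = sample.int(1e6, 1))
    x <- sim$views[[1]]$x
    rel <- x / rowSums(x)
    nda <- !sim$truth$views[[1]]$da
    g <- sim$truth$groups
    m1 <- colMeans(rel[g == "g1", nda]); m2 <- colMeans(rel[g == "g2", nda])
    (sum(m2) - sum(m1)) / sum(m1)
  })
  expect_lt(abs(mean(rel_diff)), 0.01)
  # without compensation the non-DA relative abundances shift down
  set.seed(26)
  rel_diff_nc <- replicate(20, {
    sim <- simulate_views(n = 40, p = 200, families = "count",
                          compensation = FALSE, depth_sdlog = 0,
                          seed = sample.int(1e6, 1))
    x <- sim$views[[1]]$x
    rel <- x / rowSums(x)
    nda <- !sim$truth$views[[1]]$da
    g <- sim$truth$groups
    (sum(colMeans(rel[g == "g2", nda])) -
       sum(colMeans(rel[g == "g1", nda]))) /
      sum(colMeans(rel[g == "g1", nda]))
  })
  expect_lt(mean(rel_diff_nc), -0.02)
})

test_that("null fold change gives pseudo-F in the permuted-label range", {
  sim <- simulate_views(n = 40, p = c(150, 100), fold_change_count = 1,
                        fold_change_gaussian = 0, seed = 27)
  fit <- suppressWarnings(compint(lapply(sim$views, filter_features), M = 2))
  pf <- pseudo_f(fit, sim$truth$groups)
  set.seed(28)
  null_pf <- replicate(200, pseudo_f(fit, sample(sim$truth$groups)))
  expect_lt(pf, quantile(null_pf, 0.99))
})

test_that("permuting views preserves rows but destroys alignment", {
  sim <- simulate_views(n = 20, p = c(60, 60),
                        families = c("count", "count"), seed = 29)
  pv <- permute_views(sim$views, seed = 30)
  for (k in 1:2) {
    a <- sim$views[[k]]$x; b <- pv[[k]]$x
    expect_identical(rownames(a), rownames(b))
    expect_equal(a[do.call(order, as.data.frame(a)), ],
                 b[do.call(order, as.data.frame(b)), ],
                 ignore_attr = TRUE)          # same multiset of rows
  }
  # explicit identity permutations leave data untouched
  idp <- permute_views(sim$views, permutations = list(1:20, 1:20))
  expect_identical(idp[[1]]$x, sim$views[[1]]$x)
  expect_identical(idp[[2]]$x, sim$views[[2]]$x)
  expect_error(permute_views(sim$views[1]), "two views")
})

test_that("permutation drives cross-view correlation into the null band", {
  sim <- simulate_views(n = 40, p = c(100, 100),
                        families = c("count", "count"),
                        fold_change_count = 8, seed = 31)
  cc_of <- function(vs) {
    r1 <- rowSums(vs[[1]]$x[, sim$truth$views[[1]]$direction == 1])
    r2 <- rowSums(vs[[2]]$x[, sim$truth$views[[2]]$direction == 1])
    abs(cor(r1 / rowSums(vs[[1]]$x), r2 / rowSums(vs[[2]]$x)))
  }
  strong <- cc_of(sim$views)
  set.seed(32)
  permuted <- replicate(20, cc_of(permute_views(sim$views,
                                                seed = sample.int(1e6, 1))))
  expect_gt(strong, quantile(permuted, 0.95))
})
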