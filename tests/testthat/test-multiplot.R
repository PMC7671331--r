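test_that("thresholding selects display features without altering loadings", {
  cf <- cached_fit()
  fit <- cf$fit
  mp_all <- multiplot_coordinates(fit, threshold = "all")
  expect_true(all(vapply(mp_all$features, function(f) all(f$shown),
                         logical(1))))
  mp10 <- multiplot_coordinates(fit, threshold = 10)
  for (k in seq_along(mp10$features)) {
    f <- mp10$features[[k]]
    expect_equal(sum(f$shown), 10)
    expect_true(min(f$norm[f$shown]) >= max(f$norm[!f$shown]))
    # stored coordinates identical whatever the threshold
    expect_equal(f[c("x", "y", "norm")], mp_all$features[[k]][c("x", "y", "norm")])
  }
  mpq <- multiplot_coordinates(fit, threshold = list(quantile = 0.9))
  expect_true(all(vapply(mpq$features, function(f)
    sum(f$shown) >= 1, logical(1))))
  expect_error(multiplot_coordinates(fit, dims = c(1, 5)), "dims")
})

test_that("ties at the threshold cutoff are all retained", {
  cf <- cached_fit()
  fit <- cf$fit
  # constructed tie: force two features to the same loading norm
  fit2 <- fit
  fit2$views[[1]]$loadings[, 1] <- c(0.3, 0.4)
  fit2$views[[1]]$loadings[, 2] <- c(0.4, 0.3)
  ord_norm <- sqrt(rowSums(t(fit2$views[[1]]$loadings)^2))
  k <- sum(ord_norm >= sort(ord_norm, decreasing = TRUE)[3])
  mp <- multiplot_coordinates(fit2, threshold = 3)
  expect_equal(sum(mp$features[[1]]$shown), k)
  expect_gte(k, 3)
})

test_that("feature link projection equals the mean-model log-ratio change", {
  cf <- cached_fit()
  fit <- cf$fit
  expect_equal(feature_link_projection(fit, 1, 3, 3, 1), 0)
  mm <- mean_matrix(fit, view = 1)
  pi_fit <- mm / rowSums(mm)
  pi0 <- fit$views[[1]]$indep$pi_indep
  for (i in c(2, 11)) for (ab in list(c(1, 5), c(7, 2))) {
    a <- ab[1]; b <- ab[2]
    lhs <- unname(log(pi_fit[i, a] / pi_fit[i, b]) - log(pi0[a] / pi0[b]))
    expect_equal(feature_link_projection(fit, 1, a, b, i), lhs,
                 tolerance = 1e-10)
  }
  expect_error(feature_link_projection(fit, 2, 1, 2, 1), "compositional")
})

test_that("multiplot coordinates round-trip through TSV bit-exactly", {
  cf <- cached_fit()
  mp <- multiplot_coordinates(cf$fit, threshold = 15)
  dir <- withr::local_tempdir()
  write_multiplot(mp, dir)
  mp2 <- read_multiplot(dir)
  expect_identical(mp2$samples$x, mp$samples$x)
  expect_identical(mp2$samples$y, mp$samples$y)
  for (nm in names(mp$features)) {
    expect_identical(mp2$features[[nm]]$x, mp$features[[nm]]$x)
    expect_identical(mp2$features[[nm]]$norm, mp$features[[nm]]$norm)
    expect_identical(mp2$features[[nm]]$shown, mp$features[[nm]]$shown)
  }
  expect_identical(mp2$dims, c(1L, 2L))
})

test_that("plots are square and never report variance explained", {
  cf <- cached_fit()
  g <- plot(cf$fit, threshold = 10)
  expect_s3_class(g, "ggplot")
  expect_equal(g$coordinates$ratio, 1)
  labs <- unlist(g$labels)
  expect_false(any(grepl("%|variance|explained", labs, ignore.case = TRUE)))
  built <- ggplot2::ggplot_build(g)
  expect_gt(nrow(built$data[[3]]), 0)
  # constrained fits add gradient labels
  sim <- cf$sim
  set.seed(53)
  md <- data.frame(group = sim$truth$groups, cont = rnorm(30),
                   row.names = rownames(sim$views[[1]]$x))
  fitc <- suppressWarnings(compint(sim$views, M = 2, metadata = md,
                                   constrain = c("group", "cont")))
  gc <- plot(fitc, color_by = md$group)
  expect_s3_class(gc, "ggplot")
  mpc <- multiplot_coordinates(fitc)
  expect_equal(nrow(mpc$gradient), 3)
})

test_that("fit serialization round-trips scores, loadings and gradient", {
  cf <- cached_fit()
  dir <- withr::local_tempdir()
  write_fit(cf$fit, dir)
  ex <- read_fit(dir)
  expect_identical(unname(ex$scores), unname(cf$fit$scores))
  expect_equal(ex$views[[1]]$loadings, cf$fit$views[[1]]$loadings,
               ignore_attr = TRUE)
  expect_equal(ex$views[[2]]$offset, cf$fit$views[[2]]$indep$offset,
               ignore_attr = TRUE)
  expect_equal(ex$meta$M, 2)
})
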