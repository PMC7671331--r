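test_that("view construction validates families and missingness", {
  x <- matrix(c(1, 2, 0, 5, 3, 1), 2, 3)
  v <- view_data(x, "count")
  expect_s3_class(v, "view_data")
  expect_error(view_data(x - 0.5, "count"), "integers")
  expect_error(view_data(-x, "count"), "integers")
  xg <- matrix(rlnorm(6), 2, 3)
  vg <- view_data(xg, "gaussian", log_transform = TRUE)
  expect_equal(vg$x[1, 1], log(xg[1, 1]))
  expect_error(view_data(x, "count", log_transform = TRUE), "gaussian")
})

test_that("feature filtering removes unidentifiable features", {
  x <- cbind(a = c(0, 0, 0), b = c(1, 2, 3), c = c(5, NA, NA),
             d = c(2, 0, 1))
  rownames(x) <- paste0("s", 1:3)
  v <- filter_features(view_data(x, "count"))
  expect_equal(colnames(v$x), c("b", "d"))   # a: zero total, c: 1 obs cell
  expect_error(independence_model(view_data(x, "count")), "filter_features")
})

test_that("view TSV round trip preserves values and missingness", {
  set.seed(5)
  x <- matrix(rpois(12, 20), 3, 4,
              dimnames = list(paste0("s", 1:3), paste0("f", 1:4)))
  x[2, 3] <- NA
  v <- view_data(x, "count")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_view(v, f)
  v2 <- read_view(f, "count")
  expect_equal(v2$x, v$x)
})

test_that("independence model follows observed totals", {
  x <- rbind(c(10, 20, 70), c(10, 20, 70))
  rownames(x) <- c("s1", "s2")
  im <- independence_model(view_data(x, "count"))
  expect_equal(unname(im$pi_indep), c(0.1, 0.2, 0.7))
  expect_equal(unname(im$depths), c(100, 100))
  expect_equal(im$offset, clr(im$pi_indep))
  # equal counts everywhere -> zero offset
  xe <- matrix(7, 4, 5, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(unname(independence_model(view_data(xe, "count"))$offset),
               rep(0, 5))
  # masked cell excluded from totals (hand summation)
  xm <- rbind(c(5, 5, 10, 0), c(NA, 5, 10, 5), c(5, 0, 10, 5))
  rownames(xm) <- paste0("s", 1:3)
  imm <- independence_model(view_data(xm, "count"))
  expect_equal(unname(imm$depths), c(20, 20, 20))
  expect_equal(unname(imm$pi_indep), c(10, 10, 30, 10) / 60)
})

test_that("mean matrix reduces to the independence model and sums to depth", {
  cf <- cached_fit()
  fit <- cf$fit
  mm0 <- mean_matrix(fit, view = 1, dims = 0)
  im <- fit$views[[1]]$indep
  expect_equal(mm0, outer(im$depths, im$pi_indep), tolerance = 1e-12,
               ignore_attr = TRUE)
  mm <- mean_matrix(fit, view = 1)
  expect_equal(unname(rowSums(mm)), unname(im$depths), tolerance = 1e-8)
  # identity with the perturbation-chain form, row by row
  for (i in c(1, 17)) {
    expect_equal(mm[i, ] / im$depths[i],
                 composition_chain(im$offset, fit$views[[1]]$loadings,
                                   fit$scores[i, ]), tolerance = 1e-10)
  }
})

test_that("gaussian views are location-equivariant", {
  set.seed(6)
  n <- 20
  y <- matrix(rnorm(n * 30), n, 30) + outer(rnorm(n, 0, 2), rnorm(30))
  rownames(y) <- paste0("s", 1:n)
  x <- matrix(rpois(n * 40, 50), n, 40)
  rownames(x) <- paste0("s", 1:n)
  vs1 <- list(view_data(x, "count"), view_data(y, "gaussian"))
  vs2 <- list(view_data(x, "count"), view_data(y + 11.5, "gaussian"))
  f1 <- suppressWarnings(compint(vs1, M = 1))
  f2 <- suppressWarnings(compint(vs2, M = 1))
  expect_equal(f2$views[[2]]$indep$offset, f1$views[[2]]$indep$offset + 11.5)
  expect_equal(f2$scores, f1$scores, tolerance = 1e-6)
  expect_equal(f2$views[[2]]$loadings, f1$views[[2]]$loadings,
               tolerance = 1e-6)
})

test_that("design encoding expands factors fully and scales continuous", {
  md <- data.frame(g = c("A", "A", "B", "B"), t = c(1, 2, 3, 4),
                   l3 = c("x", "y", "z", "x"),
                   row.names = paste0("s", 1:4))
  enc <- encode_design(md, c("g", "t", "l3"))
  expect_equal(unname(enc$design[, 1:2]),
               cbind(c(1, 1, 0, 0), c(0, 0, 1, 1)))
  expect_equal(unname(enc$design[, "t"]),
               c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  expect_equal(sd(enc$design[, "t"]), 1)
  expect_equal(unname(rowSums(enc$design[, enc$blocks$l3])), rep(1, 4))
  expect_equal(enc$blocks$g, 1:2)
  expect_error(encode_design(md, "missing_var"), "not in metadata")
  md$const <- 1
  expect_error(encode_design(md, "const"), "constant")
  md$one <- "same"
  expect_error(encode_design(md, "one"), "single level")
})
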