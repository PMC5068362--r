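test_that("R-squared is exact for perfectly explained or orthogonal responses", {
  set.seed(71)
  X <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), c("x1", "x2")))
  y <- matrix(2 + 3 * X[, 1] - X[, 2], dimnames = list(rownames(X), "v"))
  fit <- fit_r2(y, X)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # response orthogonal to the centered predictors
  x <- rnorm(15)
  yo <- residuals(lm(rnorm(15) ~ x))
  fo <- fit_r2(matrix(yo, dimnames = list(paste0("s", 1:15), "v")),
               matrix(x, dimnames = list(paste0("s", 1:15), "x")))
  expect_equal(fo$r_squared, 0, tolerance = 1e-10)
})

test_that("multivariate RDA R-squared equals the per-column OLS oracle", {
  set.seed(72)
  for (rep in 1:5) {
    M <- matrix(rnorm(15 * 4), 15, 4,
                dimnames = list(paste0("s", 1:15), paste0("v", 1:4)))
    X <- matrix(rnorm(30), 15, 2,
                dimnames = list(paste0("s", 1:15), c("x1", "x2")))
    fit <- fit_r2(M, X)
    ssf <- 0; sst <- 0
    for (j in 1:4) {
      m <- lm(M[, j] ~ X)
      ssf <- ssf + sum((fitted(m) - mean(M[, j]))^2)
      sst <- sst + sum((M[, j] - mean(M[, j]))^2)
    }
    expect_equal(fit$r_squared, ssf / sst, tolerance = 1e-10)
  }
})

test_that("weighted univariate R-squared matches lm with weights", {
  set.seed(73)
  x <- rnorm(12)
  y <- 1 + x + rnorm(12)
  w <- runif(12, 0.5, 3)
  fit <- fit_r2(matrix(y, dimnames = list(paste0("s", 1:12), "v")),
                matrix(x, dimnames = list(paste0("s", 1:12), "x")),
                weights = w)
  ref <- summary(lm(y ~ x, weights = w))$r.squared
  expect_equal(fit$r_squared, ref, tolerance = 1e-10)
})

test_that("rank-deficient predictors are dropped and saturated fits refused", {
  set.seed(74)
  x <- rnorm(10)
  X <- cbind(a = x, b = 2 * x, c = rnorm(10))
  rownames(X) <- paste0("s", 1:10)
  y <- matrix(rnorm(10), dimnames = list(rownames(X), "v"))
  expect_warning(fit <- fit_r2(y, X), "collinear")
  expect_equal(fit$p, 2)

  Xbig <- matrix(rnorm(10 * 9), 10, 9, dimnames = list(rownames(X), NULL))
  expect_error(fit_r2(y, Xbig), "too many predictors")
})

test_that("the Ezekiel adjustment matches its closed form", {
  expect_equal(adjust_r2(1, 15, 3), 1)
  expect_equal(adjust_r2(0, 15, 1), -1 / 13)
  expect_equal(adjust_r2(0.5, 15, 2), 1 - 0.5 * 14 / 12)
  expect_error(adjust_r2(0.5, 4, 3), "n > p")
})

test_that("partition identities and symmetries hold", {
  set.seed(75)
  for (rep in 1:10) {
    resp <- matrix(rnorm(12 * 3), 12, 3,
                   dimnames = list(paste0("s", 1:12), paste0("v", 1:3)))
    E <- matrix(rnorm(24), 12, 2, dimnames = list(rownames(resp), c("e1", "e2")))
    S <- matrix(rnorm(24), 12, 2, dimnames = list(rownames(resp), c("s1", "s2")))
    pt <- partition_variation(resp, E, S)
    expect_equal(sum(pt$raw), 1, tolerance = 1e-10)
    expect_equal(pt$raw[["a"]], pt$totals[["abc"]] - pt$totals[["bc"]],
                 tolerance = 1e-10)
    expect_equal(pt$raw[["c"]], pt$totals[["abc"]] - pt$totals[["ab"]],
                 tolerance = 1e-10)
    expect_equal(pt$raw[["d"]], 1 - pt$totals[["abc"]], tolerance = 1e-10)
    expect_true(all(pt$clamped >= 0))

    sw <- partition_variation(resp, S, E)
    expect_equal(sw$raw[["a"]], pt$raw[["c"]], tolerance = 1e-10)
    expect_equal(sw$raw[["c"]], pt$raw[["a"]], tolerance = 1e-10)
    expect_equal(sw$raw[["b"]], pt$raw[["b"]], tolerance = 1e-10)
    expect_equal(sw$raw[["d"]], pt$raw[["d"]], tolerance = 1e-10)
  }
})

test_that("identical blocks put everything in the shared fraction", {
  set.seed(76)
  x <- matrix(rnorm(12), dimnames = list(paste0("s", 1:12), "x"))
  resp <- matrix(x + rnorm(12, sd = 0.3), dimnames = list(rownames(x), "v"))
  expect_warning(pt <- partition_variation(resp, x, x), "collinear")
  expect_equal(pt$raw[["a"]], 0, tolerance = 1e-10)
  expect_equal(pt$raw[["c"]], 0, tolerance = 1e-10)
  expect_equal(pt$raw[["b"]], pt$totals[["ab"]], tolerance = 1e-10)
})

test_that("an empty block contributes an exactly zero unique fraction", {
  set.seed(77)
  resp <- matrix(rnorm(24), 12, 2,
                 dimnames = list(paste0("s", 1:12), c("v1", "v2")))
  E <- matrix(rnorm(12), dimnames = list(rownames(resp), "e"))
  pt <- partition_variation(resp, E, NULL)
  expect_identical(pt$raw[["c"]], 0)
  expect_equal(pt$raw[["d"]], 1 - pt$totals[["ab"]], tolerance = 1e-12)
})

test_that("adjusted fractions agree with vegan::varpart on Hellinger data", {
  sim <- small_bundle(seed = 41)
  Ym <- as.matrix(sim$abundance[-1])
  rownames(Ym) <- sim$abundance$site
  H <- as.matrix(hellinger_transform(Ym)[-1])
  rownames(H) <- rownames(Ym)
  E <- as.matrix(sim$sites[paste0("env_", 1:3)])
  rownames(E) <- sim$sites$site
  W <- build_connectivity(sim$sites)
  S <- as.matrix(mem_predictor(mem_basis(W))[-1])
  rownames(S) <- sim$sites$site

  pt <- partition_variation(H, E, S)
  vp <- vegan::varpart(H, E, S)
  # vegan's indfract rows are [X1|X2, X2|X1, joint, residual]; map onto the
  # environment/shared/space/residual convention used here
  ref <- vp$part$indfract$Adj.R.square
  expect_equal(unname(pt$raw), ref[c(1, 3, 2, 4)], tolerance = 1e-10)
})

test_that("unadjusted and adjusted fractions order consistently at equal block sizes", {
  set.seed(78)
  for (rep in 1:10) {
    resp <- matrix(rnorm(24), 12, 2,
                   dimnames = list(paste0("s", 1:12), c("v1", "v2")))
    E <- matrix(rnorm(24), 12, 2, dimnames = list(rownames(resp), c("e1", "e2")))
    S <- matrix(rnorm(24), 12, 2, dimnames = list(rownames(resp), c("s1", "s2")))
    pt <- partition_variation(resp, E, S)
    raw_a_minus_c <- pt$fits$abc$r_squared - pt$fits$bc$r_squared -
      (pt$fits$abc$r_squared - pt$fits$ab$r_squared)
    expect_equal(sign(raw_a_minus_c), sign(pt$raw[["a"]] - pt$raw[["c"]]))
  }
})

test_that("significance codes follow the published thresholds", {
  expect_identical(significance_code(0.009), "**")
  expect_identical(significance_code(0.01), "**")
  expect_identical(significance_code(0.05), "*")
  expect_identical(significance_code(0.07), "@")
  expect_identical(significance_code(0.10), "@")
  expect_identical(significance_code(0.2), "")
  expect_identical(significance_code(c(0.004, NA, 0.3)), c("**", NA, ""))
  expect_error(significance_code(1.2), "\\[0, 1\\]")
})

test_that("tidy, glance, and autoplot expose the partition", {
  set.seed(79)
  resp <- matrix(rnorm(24), 12, 2,
                 dimnames = list(paste0("s", 1:12), c("v1", "v2")))
  E <- matrix(rnorm(12), dimnames = list(rownames(resp), "e"))
  S <- matrix(rnorm(12), dimnames = list(rownames(resp), "s"))
  pt <- partition_variation(resp, E, S)
  td <- tidy(pt)
  expect_identical(td$fraction, c("a", "b", "c", "d"))
  expect_equal(td$estimate, unname(pt$raw))
  gl <- glance(pt)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$adj_r_squared_full, pt$totals[["abc"]])

  tests <- tibble::tibble(fraction = c("a", "c"), p_value = c(0.03, 0.4))
  pt2 <- add_partition_tests(pt, tests)
  expect_equal(unname(pt2$p_values), c(0.03, 0.4))
  expect_identical(tidy(pt2)$code[1], "*")
  expect_s3_class(autoplot(pt2), "ggplot")
})
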