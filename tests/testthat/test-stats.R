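test_that("exact Mann-Whitney p-values match full enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # swapping the samples leaves p unchanged
  r2 <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(r2$p, r$p, tolerance = 1e-12)
  # identical samples: no separation
  expect_equal(mann_whitney(c(2, 2, 2), c(2, 2))$p, 1)
})

test_that("exact and approximate p-values agree for small samples", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(4:8, 1))
    y <- rnorm(sample(4:8, 1), mean = runif(1, -1, 1))
    ex <- mann_whitney(x, y)
    expect_equal(ex$method, "exact")
    # force the normal approximation by inflating one sample size check:
    # compare against R's own implementation instead
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
    expect_equal(ex$u, unname(ref$statistic))
    expect_equal(ex$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the tie-corrected normal approximation matches wilcox.test", {
  set.seed(6)
  x <- round(rnorm(19, 0, 1), 1)   # rounding induces ties
  y <- round(rnorm(28, 0.4, 1), 1)
  r <- mann_whitney(x, y)
  expect_equal(r$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(r$u, unname(ref$statistic))
  expect_equal(r$p, ref$p.value, tolerance = 1e-8)
})

test_that("inverse regression recovers the coefficient exactly when noiseless", {
  d <- seq(1.8, 4.2, length.out = 25)
  u <- 26.4 / d
  ft <- fit_inverse(d, u)
  expect_equal(ft$a, 26.4, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  # homogeneity: scaling U scales a
  ft2 <- fit_inverse(d, 3 * u)
  expect_equal(ft2$a, 3 * 26.4, tolerance = 1e-10)
})

test_that("a constant velocity sample defeats the forced inverse model", {
  d <- seq(2, 4, length.out = 30)
  u <- rep(9, 30)
  ft <- fit_inverse(d, u)
  expect_lte(ft$r_squared, 0)
  expect_error(fit_inverse(2.5, 9), "at least 2")
  expect_error(fit_inverse(c(-1, 2), c(1, 2)), "> 0")
})

test_that("quartile outlier rule flags values outside [Q1, Q3]", {
  idx <- flag_outliers(c(1, 2, 3, 4))
  # median-exclusive quartiles: Q1 = 1.5, Q3 = 3.5
  expect_equal(sort(idx), c(1L, 4L))
  expect_equal(unname(attr(idx, "bounds")), c(1.5, 3.5))
  # constant sample: nothing outside
  expect_length(flag_outliers(rep(5, 6)), 0L)
  # permutation invariance of the flagged VALUES
  x <- c(0.1, 5, 5.1, 5.2, 5.3, 9.9)
  v1 <- sort(x[flag_outliers(x)])
  p <- c(4, 2, 6, 1, 3, 5)
  v2 <- sort(x[p][flag_outliers(x[p])])
  expect_equal(v1, v2)
  # Tukey fence variant is wider
  expect_lte(length(flag_outliers(x, rule = "fence")), length(flag_outliers(x)))
})

test_that("age split uses the 65-year boundary with >= to older", {
  coh <- data.frame(sex = c("male", "female", "male", "female"),
                    age = c(64, 65, 30, 80))
  g <- split_groups(coh)
  expect_equal(g$young, c(1L, 3L))
  expect_equal(g$older, c(2L, 4L))
  expect_equal(g$male, c(1L, 3L))
  expect_true(all(sort(c(g$young, g$older)) == 1:4))
  coh$age[2] <- NA
  expect_warning(g2 <- split_groups(coh), "missing age")
  expect_equal(g2$older, 4L)
})

test_that("linear fit recovers printed-curve coefficients from exact data", {
  x <- seq(10, 90, by = 5)
  y <- 0.006 * x + 0.208
  ft <- linear_fit(x, y)
  expect_equal(ft$slope, 0.006, tolerance = 1e-12)
  expect_equal(ft$intercept, 0.208, tolerance = 1e-12)
  expect_equal(ft$r_squared, 1, tolerance = 1e-12)
  # constant response: zero slope, zero R^2
  ft0 <- linear_fit(x, rep(2, length(x)))
  expect_equal(ft0$slope, 0, tolerance = 1e-12)
  expect_equal(ft0$r_squared, 0)
  # order invariance
  p <- sample(length(x))
  expect_equal(linear_fit(x[p], y[p])$slope, ft$slope, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), 1:5), "degenerate")
})

test_that("group comparison reports medians and exclusive IQRs", {
  r <- mann_whitney(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(r$median, c(2.5, 25))
  expect_equal(r$iqr, c(2, 20))
  expect_true(r$significant == (r$p < 0.05))
})
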