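test_that("SMA slope matches the direct-formula oracle", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(20, 10, 2)
    y <- 0.7 * x + rnorm(20, 0, 1) * sample(c(1, -1), 1)
    f <- sma_fit(x, y)
    expect_equal(f$slope, oracle_sma_slope(x, y), tolerance = 1e-12)
    expect_equal(f$intercept, mean(y) - f$slope * mean(x), tolerance = 1e-12)
  }
})

test_that("perfect proportionality gives exact slope and R2 = 1", {
  f <- sma_fit(1:10, 2 * (1:10))
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, 0)
})

test_that("independent equal-SD data still yield |slope| near 1 (documented pathology)", {
  set.seed(5)
  x <- rnorm(5000)
  y <- rnorm(5000)
  f <- sma_fit(x, y)
  expect_equal(abs(f$slope), 1, tolerance = 0.05)
  expect_lt(f$r_squared, 0.01)
})

test_that("SMA is symmetric in x/y and scale-equivariant", {
  set.seed(7)
  x <- runif(40, 1, 5)
  y <- 1.6 * x + rnorm(40, 0, 0.5)
  f_xy <- sma_fit(x, y)
  f_yx <- sma_fit(y, x)
  expect_equal(f_yx$slope, 1 / f_xy$slope, tolerance = 1e-12)
  f_scaled <- sma_fit(3 * x, y)
  expect_equal(f_scaled$slope, f_xy$slope / 3, tolerance = 1e-12)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(sma_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(sma_fit(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(sma_fit(-1:5, 2 * (-1:5), log10 = TRUE), "positive")
})

test_that("prefilter applies strict R2 and p thresholds", {
  expect_true(sma_prefilter(1:30, 2 * (1:30) + rnorm(30, 0, 0.01)))
  # pin R^2 just below the threshold via orthogonalised components: the
  # strict gate must fail even though the correlation p-value is tiny
  n <- 30
  x <- as.numeric(scale(1:n))
  e <- as.numeric(scale(resid(lm(rnorm(n) ~ x))))
  r2 <- 0.1 - 1e-9
  y <- sqrt(r2) * x + sqrt(1 - r2) * e
  expect_equal(cor(x, y)^2, r2, tolerance = 1e-9)
  expect_false(sma_prefilter(x, y))
  # uncorrelated noise passes only rarely
  set.seed(11)
  rate <- mean(replicate(400, sma_prefilter(rnorm(30), rnorm(30))))
  expect_lt(rate, 0.35)
})

test_that("group comparisons never run when the prefilter fails", {
  set.seed(13)
  d <- data.frame(x = rnorm(60), y = rnorm(60),
                  g = rep(c("a", "b"), each = 30))
  # force both groups uncorrelated; repeat until prefilter fails for one
  d$y <- rnorm(60, 0, 1)
  cmp <- sma_compare_groups(d, "x", "y", "g", log10 = FALSE)
  if (!cmp$prefilter_passed) {
    expect_true(is.na(cmp$common_slope_p))
    expect_true(is.na(cmp$elevation_p))
  }
  # one strongly correlated group alone is not enough; the second group
  # is built with exactly zero correlation so it must fail the prefilter
  xn <- rnorm(30, 10)
  yn <- resid(lm(rnorm(30) ~ xn))
  d2 <- data.frame(x = c(1:30, xn),
                   y = c(2 * (1:30) + rnorm(30, 0, 0.1), yn),
                   g = rep(c("good", "noise"), each = 30))
  cmp2 <- sma_compare_groups(d2, "x", "y", "g", log10 = FALSE)
  expect_false(cmp2$prefilter_passed)
  expect_true("noise" %in% cmp2$excluded)
  expect_true(is.na(cmp2$common_slope_p))
})

test_that("common-slope test keeps nominal size and detects slope shifts", {
  gen_pair <- function(s1, s2, n = 100, noise = 0.1) {
    x1 <- runif(n, 1, 3); x2 <- runif(n, 1, 3)
    data.frame(x = c(x1, x2),
               y = c(1 + s1 * x1 + rnorm(n, 0, noise),
                     1 + s2 * x2 + rnorm(n, 0, noise)),
               g = rep(c("a", "b"), each = n))
  }
  set.seed(17)
  null_rej <- mean(replicate(300, {
    d <- gen_pair(1, 1)
    sma_compare_groups(d, "x", "y", "g", log10 = FALSE)$common_slope_p < 0.05
  }))
  expect_gt(null_rej, 0.02)
  expect_lt(null_rej, 0.09)

  set.seed(19)
  power <- mean(replicate(100, {
    d <- gen_pair(1, 0.5)
    sma_compare_groups(d, "x", "y", "g", log10 = FALSE)$common_slope_p < 0.05
  }))
  expect_gte(power, 0.95)
})

test_that("elevation shifts are detected under a common slope", {
  set.seed(23)
  hits <- replicate(100, {
    n <- 100
    x1 <- runif(n, 1, 3); x2 <- runif(n, 1, 3)
    d <- data.frame(x = c(x1, x2),
                    y = c(1 + x1 + rnorm(n, 0, 0.1),
                          2 + x2 + rnorm(n, 0, 0.1)),
                    g = rep(c("a", "b"), each = n))
    cmp <- sma_compare_groups(d, "x", "y", "g", log10 = FALSE)
    c(common = cmp$slopes_common,
      elev = isTRUE(cmp$elevation_p < 0.05))
  })
  expect_gt(mean(hits["common", ]), 0.9)
  expect_gte(mean(hits["elev", hits["common", ] == 1]), 0.95)
})

test_that("elevation/shift tests are reported NA when slopes differ", {
  set.seed(29)
  n <- 150
  x <- runif(2 * n, 1, 3)
  d <- data.frame(x = x,
                  y = c(1 + 1.0 * x[1:n], 1 + 0.4 * x[(n + 1):(2 * n)]) +
                    rnorm(2 * n, 0, 0.05),
                  g = rep(c("a", "b"), each = n))
  cmp <- sma_compare_groups(d, "x", "y", "g", log10 = FALSE)
  expect_false(cmp$slopes_common)
  expect_true(is.na(cmp$elevation_p))
  expect_true(is.na(cmp$shift_p))
})

test_that("chi-squared p-values agree with a permutation oracle on small samples", {
  set.seed(31)
  agree <- replicate(20, {
    n <- 25
    shift <- sample(c(0, 0.6), 1)  # mix of null and alternative cases
    x1 <- runif(n, 1, 4); x2 <- runif(n, 1, 4)
    y1 <- 1 + x1 + rnorm(n, 0, 0.3)
    y2 <- 1 + (1 + shift) * x2 + rnorm(n, 0, 0.3)
    d <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = rep(c("a", "b"), each = n))
    cmp <- sma_compare_groups(d, "x", "y", "g", log10 = FALSE)
    p_perm <- oracle_perm_common_slope_p(d$x, d$y, d$g, n_perm = 199,
                                         seed = sample.int(1e6, 1))
    (cmp$common_slope_p < 0.05) == (p_perm < 0.05)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("significance codes follow the conventional thresholds", {
  expect_equal(significance_code(c(0.2, 0.09, 0.04, 0.009, 0.0009)),
               c("", "+", "*", "**", "***"))
  expect_true(is.na(significance_code(NA_real_)))
})
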