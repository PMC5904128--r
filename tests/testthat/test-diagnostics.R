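test_that("OLS trend recovers exact lines and rejects bad input", {
  t <- 1:20
  tr <- ols_trend(2 * t + 5, t)
  expect_equal(tr$slope, 2)
  expect_equal(tr$se, 0, tolerance = 1e-12)
  expect_equal(ols_trend(rep(3, 10))$slope, 0)
  expect_error(ols_trend(c(1, 2), c(1, 2)), "at least 3")
  expect_error(ols_trend(1:5, rep(2, 5)), "constant")
  expect_error(ols_trend(c(1, NA, 3, 4)), "missing")
})

test_that("OLS trend matches a normal-equations oracle", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    t <- sort(runif(n, 0, 100))
    y <- rnorm(n)
    tr <- ols_trend(y, t)
    # brute-force normal equations and classical slope variance
    X <- cbind(1, t)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    resid <- y - X %*% beta
    s2 <- sum(resid^2) / (n - 2)
    se <- sqrt(s2 / sum((t - mean(t))^2))
    expect_equal(tr$slope, beta[2], tolerance = 1e-10)
    expect_equal(tr$se, se, tolerance = 1e-10)
  }
})

test_that("the OLS slope estimator is unbiased on noisy lines", {
  set.seed(12)
  slopes <- replicate(1000, ols_trend(1:18 + rnorm(18), 1:18)$slope)
  expect_lt(abs(mean(slopes) - 1), 3 * stats::sd(slopes) / sqrt(1000))
})

test_that("interval overlap declares equality and separation correctly", {
  expect_true(overlap_test(5, 1, 5, 2))
  expect_false(overlap_test(0, 1, 10, 1)) # [-1.385,1.385] vs [8.615,11.385]
  # touching endpoints count as overlap (closed intervals)
  expect_true(overlap_test(0, 1, 2 * 1.385, 1))
  # symmetric in its arguments
  set.seed(4)
  for (i in 1:25) {
    m <- rnorm(2); s <- runif(2)
    expect_identical(overlap_test(m[1], s[1], m[2], s[2]),
                     overlap_test(m[2], s[2], m[1], s[1]))
  }
  expect_error(overlap_test(0, -1, 0, 1), ">= 0")
})

test_that("moving average preserves constants and lines, truncates ends", {
  expect_equal(moving_average(rep(4, 30)), rep(4, 21))
  lin <- moving_average(1:30, 10)
  expect_equal(length(lin), 21)
  expect_equal(diff(lin), rep(1, 20))
  expect_error(moving_average(1:30, 0), "window")
  expect_error(moving_average(1:5, 10), "longer")
})

test_that("pearson correlation matches hand-verified values", {
  expect_equal(pearson_correlation(1:10, 1:10), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  # 5 / sqrt(2 * 38/3): verified against the normal-equations definition
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 7)), 0.99340,
               tolerance = 1e-4)
  expect_error(pearson_correlation(1:3, rep(2, 3)), "zero-variance")
  expect_error(pearson_correlation(1:4, 1:5), "lengths")
})

test_that("per-cell trend maps are exact and aggregate linearly", {
  g <- small_grid()
  n <- length(g$lat)
  # constant field: zero map
  const <- matrix(5, n, 12)
  expect_equal(per_cell_trend_map(const, g)$slope, rep(0, n))
  # field = t * pattern: slope map equals the pattern
  pattern <- runif(n)
  fields <- outer(pattern, 1:12)
  expect_equal(per_cell_trend_map(fields, g)$slope, pattern)
  # trend of the summed series equals the sum of cell trends
  set.seed(9)
  noisy <- matrix(rnorm(n * 15), n, 15)
  tm <- per_cell_trend_map(noisy, g)
  expect_equal(sum(tm$slope), ols_trend(colSums(noisy))$slope,
               tolerance = 1e-10)
  # the zonal split partitions the total
  expect_equal(sum(tm$zonal$trend), sum(tm$slope), tolerance = 1e-10)
})

test_that("the emergent curve finds a constructed population optimum", {
  set.seed(14)
  p_d <- 10^runif(400, -1, 2.5)
  burned <- pmax(0, 2 - abs(log10(p_d) - log10(20))) + runif(400, 0, 0.05)
  cv <- emergent_population_curve(p_d, burned, bins = 20)
  am <- attr(cv, "argmax_bin")
  expect_true(am[1] <= 20 && 20 <= am[2])
  # flat input: flat curve
  flat <- emergent_population_curve(p_d, rep(1, 400), bins = 10)
  expect_true(all(abs(flat$median_burned_pct - 1) < 1e-12, na.rm = TRUE))
  # unburned or unpopulated cells are excluded from every bin
  p2 <- c(p_d, rep(0, 50), rep(10, 50))
  b2 <- c(burned, rep(1, 50), rep(0, 50))
  cv2 <- emergent_population_curve(p2, b2, bins = 20)
  expect_equal(sum(cv2$n_cells), 400)
})

test_that("the all-forcings run rises early and declines late", {
  rs <- default_runs()$results
  s <- rs$all$series$burned_Mha
  early <- ols_trend(s[1:50])
  late <- ols_trend(s[100:length(s)])
  expect_gte(early$slope, 0)
  expect_lt(late$slope, 0)
})

test_that("the simulated emergent population-fire curve is unimodal", {
  rs <- default_runs()$results
  r <- rs$all$series
  yrs <- 140:160
  p_d <- rowMeans(rs$all$percell$p_d[, yrs])
  burned <- 100 * rowMeans(rs$all$percell$burned_frac[, yrs])
  cv <- emergent_population_curve(p_d, burned, bins = 12)
  med <- cv$median_burned_pct[cv$n_cells > 0]
  k <- which.max(med)
  expect_gt(k, 1)
  expect_lt(k, length(med))
})
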