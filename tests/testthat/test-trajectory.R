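test_that("raw series ingestion sorts by age and validates input", {
  s <- raw_series(c(3, 1, 2, 5, 4), c(0.3, 0.1, 0.2, 0.5, 0.4), "g", "sp")
  expect_equal(s$ages, 1:5)
  expect_equal(s$values, (1:5) / 10)
  expect_error(raw_series(1:4, 1:4), "insufficient observations")
  expect_error(raw_series(1:5, c(1, 2, NA, 4, 5)), "missing")
  expect_error(raw_series(1:5, 1:4), "same length")
})

test_that("spline fit hits the requested effective df and stores residuals", {
  set.seed(1)
  t <- sort(runif(39, 0, 47))
  s <- raw_series(t, sin(pi * t / 25) + rnorm(39, sd = 0.3), "g", "human")
  f <- fit_spline(s, df = 4)
  expect_lt(abs(f$df - 4), 0.1)
  expect_equal(length(residuals(f)), 39)
  # fitted + residuals reconstructs the observations exactly
  expect_equal(f$fitted + f$residuals, s$values)
  expect_true(f$df >= 2 && f$df <= 38.5)
})

test_that("exact polynomials are reproduced in the interpolation limit", {
  # linear data: the penalty null space, exact even at df = 2
  s_lin <- poly_series(c(0, 1, 0), t = seq(1, 20))
  f2 <- fit_spline(s_lin, df = 2)
  expect_lt(max(abs(residuals(f2))), 1e-5)
  expect_lt(var(residuals(f2)), 1e-10)
  # noiseless cubic: GCV drives lambda to the interpolation limit
  s_cub <- poly_series(c(1, 2, -0.5, 0.25))
  fg <- fit_spline(s_cub, df = "gcv")
  expect_lt(max(abs(residuals(fg))), 1e-6)
})

test_that("residual sum of squares is non-increasing in df", {
  set.seed(7)
  t <- seq(1, 30)
  s <- raw_series(t, 0.1 * t + sin(t / 3) + rnorm(30, sd = 0.2))
  rss <- vapply(c(2, 3, 4, 6), function(d)
    sum(residuals(fit_spline(s, df = d))^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("spline fitting rejects degenerate input", {
  expect_error(fit_spline(raw_series(rep(1, 5), 1:5)), "constant-age")
  s <- raw_series(1:10, rnorm(10))
  expect_error(fit_spline(s, df = 1.5), "df must be")
  expect_error(fit_spline(s, df = 10), "df must be")
})

test_that("uniform interpolation spans the domain with constant step", {
  set.seed(2)
  s <- raw_series(sort(runif(39, 0, 47)), rnorm(39), "g", "human")
  f <- fit_spline(s, df = 4)
  ip <- interpolate_uniform(f, 40)
  expect_equal(ip$K, 40)
  expect_equal(ip$times[1], min(s$ages))
  expect_equal(ip$times[40], max(s$ages))
  steps <- diff(ip$times)
  expect_lt(diff(range(steps)) / mean(steps), 1e-9)
  # K = 2 gives the endpoints only
  ip2 <- interpolate_uniform(f, 2)
  expect_equal(ip2$times, range(s$ages))
  expect_error(interpolate_uniform(f, 1), "at least 2")
})

test_that("interpolating an exactly fitted parabola recovers the closed form", {
  t <- seq(0, 4, length.out = 17)
  f <- fit_spline(raw_series(t, t^2), df = "gcv")
  ip <- interpolate_uniform(f, 5)
  expect_equal(ip$times, c(0, 1, 2, 3, 4))
  expect_lt(max(abs(ip$values - c(0, 1, 4, 9, 16))), 1e-6)
})

test_that("log2 age transform is correct, monotone and guarded", {
  expect_equal(transform_ages(0, offset = 1), 0)
  expect_equal(transform_ages(3, offset = 1), 2)
  a <- sort(runif(20, 0.1, 50))
  expect_true(all(diff(transform_ages(a, offset = 0.77)) > 0))
  expect_error(transform_ages(c(-2, 1), offset = 1), "strictly positive")
  expect_error(transform_ages(1, offset = -1), "non-negative")
})
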