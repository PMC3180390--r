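test_that("noise sd resolves from the error-variance fraction", {
  # linear y = t on t = 1..3: signal variance 1, r = 0.2 -> sd = 0.5
  m <- signal_model("linear", a = 0, b = 1, grid = 1:3)
  expect_equal(resolve_sd(m, r = 0.2), 0.5)
  # equal split: sd = sqrt(var(signal))
  m2 <- signal_model("quadratic", a = 1, b = 2, d = -0.1, n = 20)
  expect_equal(resolve_sd(m2, r = 0.5), sqrt(var(m2$fun(m2$grid))))
  # the sine benchmark at sd = 0.3 sits near a 15% error fraction
  ms <- signal_model("sine", n = 20)
  v <- var(ms$fun(ms$grid))
  r_at_03 <- 0.09 / (0.09 + v)
  expect_lt(abs(r_at_03 - 0.1525), 0.011)
  expect_error(resolve_sd(m, r = 1.2), "between 0 and 1")
  mc <- signal_model("linear", a = 1, b = 1, grid = 1:10)
  mc$fun <- function(t) rep(1, length(t))
  expect_error(resolve_sd(mc, r = 0.2), "constant signal")
})

test_that("benchmark pairs implement the documented generative model", {
  # zero noise, zero shift: the two series coincide
  m <- signal_model("quadratic", a = 3, b = 2, d = -1, n = 20)
  p0 <- make_pair(m, shift = 0, sd = 0)
  expect_equal(p0$reference$values, p0$query$values)
  # zero noise, constant shift: query(t) = f(t + delta) exactly
  p2 <- make_pair(m, shift = 2, sd = 0)
  expect_equal(p2$query$values, m$fun(m$grid + 2))
  expect_equal(p2$true_shift, rep(2, 20))
  # a shift wider than the grid span is rejected
  expect_error(make_pair(m, shift = 25, sd = 0), "exceeds")
  expect_error(make_pair(m, shift = 1), "exactly one of")
})

test_that("empirical error-variance fraction matches the request", {
  set.seed(61)
  m <- signal_model("quadratic", a = 0, b = 1, d = -0.04, n = 20)
  for (r_req in c(0.1, 0.3)) {
    sdv <- resolve_sd(m, r = r_req)
    fr <- replicate(200, {
      e <- rnorm(20, 0, sdv)
      var(e) / (var(m$fun(m$grid) + e))
    })
    expect_lt(abs(mean(fr) - r_req), 0.02)
  }
})

test_that("noiseless recovery is exact to within one grid step", {
  m <- signal_model("quadratic", a = 3, b = 2, d = -1, n = 20)
  rep1 <- run_recovery(m, shift = 2, sd = 0, N = 20, M = 40, R = 1,
                       seed = 1)
  step <- diff(range(m$grid)) / 39
  interior <- 5:15
  expect_true(all(abs(rep1$bias[interior]) <= step + 1e-8))
})

test_that("estimate precision improves with the number of time points", {
  set.seed(63)
  vars <- vapply(c(10, 20, 40), function(n) {
    m <- signal_model("sine", n = n)
    rp <- run_recovery(m, shift = 5, sd = 0.3, N = n, M = 2 * n, R = 60,
                       keep_estimates = TRUE)
    # spread at matched interior positions
    idx <- round(seq(0.3, 0.7, length.out = 5) * n)
    mean(apply(rp$estimates[, idx], 2, var))
  }, numeric(1))
  expect_true(all(diff(vars) <= 0.05))
  expect_lt(vars[3], vars[1])
})

test_that("boundary biases at high noise have the documented signs", {
  set.seed(65)
  m <- signal_model("sine", n = 20)
  rp <- run_recovery(m, shift = 0, r = 0.3, N = 20, M = 40, R = 500)
  # positive bias at the start, negative at the end of the age range
  expect_gt(rp$mean[1], 0)
  expect_lt(rp$mean[20], 0)
})

test_that("model comparison distinguishes curved from linear shift profiles", {
  qt <- seq(1, 20)
  mk <- function(mean_est) structure(
    list(query_times = qt, mean = mean_est, true_shift = rep(0, 20),
         bias = rep(0, 20), rmse = rep(0, 20), R = 10, N = 20, M = 40),
    class = "recovery_report")
  # exactly linear mean estimates (with tiny jitter for a full-rank fit)
  set.seed(67)
  lin <- mk(2 + 0.1 * qt + rnorm(20, sd = 1e-6))
  expect_equal(compare_shift_models(lin)$preferred, "linear")
  # exact quadratic curvature dominating residual: p below 1e-6
  qd <- mk(4 - 0.08 * (qt - 10.5)^2 + rnorm(20, sd = 1e-4))
  cmp <- compare_shift_models(qd)
  expect_lt(cmp$p, 1e-6)
  expect_equal(cmp$preferred, "quadratic")
  # constant estimates: both models collapse; parsimony picks linear
  cst <- mk(rep(3, 20))
  expect_equal(compare_shift_models(cst)$preferred, "linear")
})

test_that("shift presets have the documented shapes", {
  g <- 1:20; rng <- c(1, 20)
  c1 <- shift_preset("C1")$fun(g, rng)
  expect_equal(c1[1], 0); expect_equal(c1[20], 4)
  expect_true(all(diff(c1) > 0))
  c2 <- shift_preset("C2")$fun(g, rng)
  expect_equal(c2, rev(c1))
  c3 <- shift_preset("C3")$fun(g, rng)
  expect_equal(c3[1], 0); expect_equal(c3[20], 0)
  expect_equal(max(c3), 4, tolerance = 0.01)
  c4 <- shift_preset("C4")$fun(g, rng)
  expect_equal(c4[1], 4); expect_lt(min(c4), 0.05)
})
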