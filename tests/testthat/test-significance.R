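test_that("the null model recovers the trajectory and the noise level", {
  # noiseless cubic: residual noise is essentially zero
  s <- poly_series(c(1, 2, -0.5, 0.05), t = seq(1, 20, length.out = 30))
  nm <- build_null_model(s, df = "gcv")
  expect_lt(nm$noise$sd, 1e-6)
  # known noise: sample-sd consistency at n = 200
  set.seed(41)
  t <- seq(1, 50, length.out = 200)
  s2 <- raw_series(t, sin(pi * t / 25) + rnorm(200, sd = 0.3), "g", "sp")
  nm2 <- build_null_model(s2, df = "gcv")
  expect_lt(abs(nm2$noise$sd - 0.3) / 0.3, 0.15)
  # the residual mean is retained, not zeroed
  expect_equal(nm2$noise$mean, mean(residuals(nm2$model)))
  # the "residual" convention reproduces the plain residual variance
  nm3 <- build_null_model(s2, df = 4, noise_var = "residual")
  expect_equal(nm3$noise$sd, sd(residuals(nm3$model)))
})

test_that("zero-shift pairs follow the RNG contract and the model curve", {
  s <- poly_series(c(0, 1, 0), t = 1:20)
  nm <- build_null_model(s, df = 4)
  set.seed(1); p1 <- simulate_zero_shift_pair(nm$model, nm$noise, 1:20, 1:20)
  set.seed(1); p2 <- simulate_zero_shift_pair(nm$model, nm$noise, 1:20, 1:20)
  expect_equal(p1, p2)
  set.seed(2); p3 <- simulate_zero_shift_pair(nm$model, nm$noise, 1:20, 1:20)
  expect_false(identical(p1$x$values, p3$x$values))
  expect_error(
    simulate_zero_shift_pair(nm$model, nm$noise, c(1:19, 25), 1:20),
    "outside")
})

test_that("pointwise p-values are the exceedance proportion", {
  # 50 of 1000 simulations at least as extreme -> p = 0.05
  sims <- matrix(0, 1000, 3)
  sims[1:50, 1] <- 2
  sims[, 2] <- 5
  real <- c(2, -1, 0)
  p <- pointwise_pvalues(real, sims)
  expect_equal(p[1], 0.05)   # |sim| >= 2 for exactly 50 draws
  expect_equal(p[2], 1)      # every |sim| = 5 >= 1
  expect_equal(p[3], 1)      # zero real shift is never exceeded... by less
  # real shift larger than every simulation -> p = 0
  expect_equal(pointwise_pvalues(c(9, 9, 9), sims), c(0, 0, 0))
  # permuting the simulation set leaves p unchanged
  set.seed(43)
  sims2 <- matrix(rnorm(200 * 5), 200, 5)
  r2 <- rnorm(5)
  expect_equal(pointwise_pvalues(r2, sims2),
               pointwise_pvalues(r2, sims2[sample(200), ]))
  # add-one correction
  expect_equal(pointwise_pvalues(c(9, 9, 9), sims, correction = TRUE),
               rep(1 / 1001, 3))
  expect_error(pointwise_pvalues(1:4, sims), "grid")
})

test_that("per-gene significance counts points below alpha", {
  set.seed(45)
  m <- signal_model("quadratic", a = 1, b = 1, d = -0.03, n = 20)
  pr <- make_pair(m, shift = 3, r = 0.1)
  rs <- run_gene_significance(pr$query, pr$reference, B = 120, G = 5,
                              seed = 46)
  expect_equal(rs$n_significant, sum(rs$pointwise_p < rs$alpha))
  expect_equal(length(rs$null_counts), 5)
  expect_true(all(rs$null_counts >= 0 & rs$null_counts <= 20))
  # a strongly shifted gene reaches the one-third-of-points convention
  expect_gte(rs$n_significant, 7)
  # a zero-shift gene has few
  pr0 <- make_pair(m, shift = 0, r = 0.1)
  rs0 <- run_gene_significance(pr0$query, pr0$reference, B = 120, G = 2,
                               seed = 47)
  expect_lt(rs0$n_significant, 10)
})

test_that("the FPR ratio definition and threshold scan behave as defined", {
  # c = 0: both tails are 1
  expect_equal(estimate_fpr(c(1, 5, 9), c(0, 1, 2), 0), 1)
  # nulls all below c while real has genes at c -> FPR 0
  expect_equal(estimate_fpr(c(8, 9), c(1, 2, 3), 7), 0)
  # ratio reading reproduces the published pairing: a real tail of
  # 482/1183 with a null tail of 0.0436 gives ~10.7%
  real <- c(rep(10, 482), rep(0, 1183 - 482))
  null <- c(rep(10, 436), rep(0, 9564))
  expect_equal(estimate_fpr(real, null, 7), (436 / 10000) / (482 / 1183),
               tolerance = 1e-12)
  expect_equal(round(100 * estimate_fpr(real, null, 7), 1), 10.7)
  # empty real tail errors
  expect_error(estimate_fpr(c(1, 2), c(5, 6), 3), "no genes at threshold")
  # threshold scan equals a direct search
  set.seed(49)
  realc <- rpois(300, 6); nullc <- rpois(3000, 2)
  N <- 20
  target <- 0.10
  direct <- NA
  for (cc in 0:N) {
    if (mean(realc >= cc) == 0) break
    if (estimate_fpr(realc, nullc, cc) <= target) { direct <- cc; break }
  }
  expect_equal(choose_threshold(realc, nullc, target, N), direct)
  expect_equal(choose_threshold(realc, nullc, 1, N), 0L)
  # identical real and null distributions keep FPR at ~1 for every c
  expect_error(choose_threshold(realc, realc, 1e-9, N), "no threshold")
  # FPR curve is non-increasing on this well-behaved fixture
  curve <- vapply(0:10, function(cc) estimate_fpr(realc, nullc, cc),
                  numeric(1))
  expect_true(all(diff(curve) <= 1e-12))
})

test_that("dataset-level calibration is reproducible and coherent", {
  set.seed(51)
  ds <- lapply(1:6, function(i) {
    m <- signal_model("quadratic", a = runif(1, -1, 1), b = 1,
                      d = runif(1, -0.05, 0.05), n = 20)
    pr <- make_pair(m, shift = if (i <= 3) 3 else 0, r = 0.1)
    list(query = pr$query, reference = pr$reference)
  })
  s1 <- calibrate_fpr(ds, B = 60, G = 5, target_fpr = 0.5, seed = 53)
  s2 <- calibrate_fpr(ds, B = 60, G = 5, target_fpr = 0.5, seed = 53)
  expect_identical(s1$table, s2$table)
  expect_equal(dim(s1$null_counts), c(6, 5))
  expect_equal(s1$real_counts, s1$table$n_significant)
  if (!is.na(s1$threshold_c))
    expect_equal(s1$table$gene_significant,
                 s1$real_counts >= s1$threshold_c)
})
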