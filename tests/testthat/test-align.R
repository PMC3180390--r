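test_that("aligning a series to itself gives the zero-cost diagonal", {
  v <- c(0.2, 1.5, -0.3, 0.8, 2.2)
  X <- as_interp(v)
  p <- align(X, X)
  expect_equal(p$cost, 0)
  expect_equal(p$omitted, integer(0))
  expect_equal(p$pairs, cbind(1:5, 1:5))
  sp <- shifts_from_path(p, X, X)
  expect_equal(sp$shifts, rep(0, 5))
})

test_that("omitted columns can sit at the reference ends (unanchored)", {
  # only columns 3 and 4 match the query; 1 and 2 must be dropped free
  X <- as_interp(c(0, 5, 1, 2))
  Y <- as_interp(c(1, 2))
  p <- align(X, Y)
  expect_equal(p$cost, 0)
  expect_equal(p$omitted, c(1L, 2L))
  expect_equal(p$pairs, cbind(1:2, 3:4))
  # and at the tail
  p2 <- align(as_interp(c(1, 2, 9, 9)), Y)
  expect_equal(p2$cost, 0)
  expect_equal(p2$omitted, c(3L, 4L))
})

test_that("a square instance with no omissions forces full coverage", {
  X <- as_interp(c(0, 3))
  Y <- as_interp(c(1, 2))
  p <- align(X, Y)
  expect_equal(length(p$omitted), 0)
  expect_equal(p$cost, (0 - 1)^2 + (3 - 2)^2)
  expect_equal(p$n_pairs, 2)
})

test_that("dynamic program matches the exhaustive oracle on random instances", {
  set.seed(11)
  for (i in 1:60) {
    inst <- random_instance()
    mm <- sample(c("both", "query-only"), 1)
    a <- align(inst$X, inst$Y, multi_map = mm)
    b <- brute_force_align(inst$X, inst$Y, multi_map = mm)
    expect_equal(a$cost, b$cost, tolerance = 0)
    expect_equal(a$n_pairs, b$n_pairs)
  }
})

test_that("every alignment satisfies the balanced-path invariants", {
  set.seed(13)
  for (i in 1:40) {
    N <- sample(2:8, 1); M <- N + sample(0:12, 1)
    X <- as_interp(rnorm(M)); Y <- as_interp(rnorm(N))
    p <- align(X, Y)
    expect_equal(length(p$omitted), M - N)
    expect_equal(length(unique(p$pairs[, 2])), N)
    expect_identical(sort(unique(p$pairs[, 1])), 1:N)
    expect_true(all(diff(p$pairs[, 1]) >= 0))
    expect_true(all(diff(p$pairs[, 2]) >= 0))
    expect_true(all(diff(p$pairs[, 1]) + diff(p$pairs[, 2]) >= 1))
    expect_false(any(p$omitted %in% p$pairs[, 2]))
  }
})

test_that("query-only mapping reduces to a one-to-one column match", {
  set.seed(17)
  X <- as_interp(rnorm(9)); Y <- as_interp(rnorm(4))
  p <- align(X, Y, multi_map = "query-only")
  expect_equal(nrow(p$pairs), 4)
  expect_equal(p$pairs[, 1], 1:4)
  expect_true(all(diff(p$pairs[, 2]) >= 1))
})

test_that("state count grows as O(M^3) at a fixed shape ratio", {
  X1 <- as_interp(rnorm(40)); Y1 <- as_interp(rnorm(20))
  X2 <- as_interp(rnorm(80)); Y2 <- as_interp(rnorm(40))
  c1 <- align(X1, Y1)$cells
  c2 <- align(X2, Y2)$cells
  expect_gt(c2 / c1, 6)
  expect_lt(c2 / c1, 10)
})

test_that("shifts follow the mean-aligned-time rule", {
  # query point at time 3 aligned to reference points at times 4 and 6
  X <- as_interp(c(1, 1, 9), times = c(2, 4, 6))
  Y <- as_interp(c(1, 9), times = c(1, 3))
  p <- align(X, Y)
  # construct expected by hand from the path
  sp <- shifts_from_path(p, X, Y)
  manual <- vapply(1:2, function(i)
    mean(X$times[p$pairs[p$pairs[, 1] == i, 2]]) - Y$times[i], numeric(1))
  expect_equal(sp$shifts, manual)
  # direct formula cases
  X2 <- as_interp(c(5, 5), times = c(5, 6))
  Y2 <- as_interp(c(5, 5), times = c(2, 3))
  sp2 <- shifts_from_path(align(X2, Y2), X2, Y2)
  expect_equal(sp2$shifts, c(3, 3))
  # reporting scale: log2(aligned reference age / query age)
  expect_equal(sp2$reporting_shifts, log2(c(5, 6) / c(2, 3)))
})

test_that("shift estimates stay within the reference-domain bounds", {
  set.seed(19)
  for (i in 1:20) {
    M <- 12; N <- 5
    X <- as_interp(rnorm(M), times = seq(2, 9, length.out = M))
    Y <- as_interp(rnorm(N), times = seq(1, 6, length.out = N))
    sp <- shifts_from_path(align(X, Y), X, Y)
    expect_true(all(sp$shifts >= min(X$times) - max(Y$times) - 1e-12))
    expect_true(all(sp$shifts <= max(X$times) - min(Y$times) + 1e-12))
  }
})

test_that("noiseless constant shift is recovered at interior points", {
  f <- function(t) sin(pi * t / 25)
  t <- (1:20) * 2.5
  delta <- 5
  ref <- raw_series(t, f(t), "g", "sp1")
  qry <- raw_series(t, f(t + delta), "g", "sp2")
  sp <- align_and_shift(ref, qry, K_A = 40, K_B = 20, direction = "B_to_A")
  step <- diff(range(t)) / 39  # reference grid step
  interior <- 4:14             # query times whose target lies in-domain
  expect_true(all(abs(sp$shifts[interior] - delta) <= step + 1e-8))
})

test_that("reversing the alignment direction flips the shift sign", {
  f <- function(t) 3 + 2 * t - 0.08 * t^2
  t <- 1:20
  a <- raw_series(t, f(t), "g", "sp1")
  b <- raw_series(t, f(t + 2), "g", "sp2")
  fw <- align_and_shift(a, b, K_A = 40, K_B = 20, direction = "B_to_A")
  bw <- align_and_shift(b, a, K_A = 40, K_B = 20, direction = "B_to_A")
  interior <- 6:15
  expect_lt(max(abs(fw$shifts[interior] - 2)), 0.6)
  expect_lt(max(abs(bw$shifts[interior] + 2)), 0.6)
  # the A_to_B direction switch is equivalent to exchanging the arguments
  ab <- align_and_shift(b, a, K_A = 20, K_B = 40, direction = "A_to_B")
  expect_equal(ab$shifts, fw$shifts)
})

test_that("a shorter reference triggers the documented role swap", {
  set.seed(23)
  X <- as_interp(rnorm(4))   # shorter than the query
  Y <- as_interp(rnorm(7))
  p <- align(X, Y)
  expect_equal(p$orientation, "swapped")
  expect_equal(length(p$omitted), 3)
})

test_that("non-finite values and tiny queries are rejected", {
  expect_error(align(as_interp(c(1, NA, 3)), as_interp(c(1, 2))),
               "non-finite")
  expect_error(align(as_interp(c(1, 2, 3)), as_interp(2)), "at least 2")
})
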