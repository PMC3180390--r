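#' Benchmark signal models
#'
#' Defines the smooth mean trajectories used by the heterochrony benchmarks:
#' a sine wave `f(t) = sin(pi * t / 25)` (period 50 time units, standing in
#' for periodic processes such as the cell cycle or circadian expression),
#' and linear/quadratic trends `f(t) = a + b*t + d*t^2` (standing in for
#' developmental or ageing trajectories).
#'
#' The default grid is `t = (1..n) * 50/n` for the sine (one full period, so
#' the signal variance over the grid is ~0.5) and `t = 1..n` for the
#' polynomial models.
#'
#' @param kind `"sine"`, `"linear"` or `"quadratic"`.
#' @param a,b,d polynomial coefficients (`d` ignored for `"linear"`; all
#'   ignored for `"sine"`).
#' @param n number of observed time points (default grid length).
#' @param grid optional explicit time grid (strictly increasing).
#' @param literal_sine if `TRUE` the sine model uses the singular form
#'   `sin(pi * 25 / t)` instead of `sin(pi * t / 25)`; exposed only for
#'   comparison, not a sensible benchmark.
#' @return an object of class `signal_model` with elements `kind`, `fun`
#'   (vectorised `f(t)`), `grid`, `coefficients`.
#' @examples
#' m <- signal_model("quadratic", a = 3, b = 2, d = -1, n = 20)
#' head(m$fun(m$grid))
#' @export
signal_model <- function(kind = c("sine", "linear", "quadratic"),
                         a = 0, b = 0, d = 0, n = 20, grid = NULL,
                         literal_sine = FALSE) {
  kind <- match.arg(kind)
  if (n < 5) stop("need at least 5 time points")
  if (kind == "linear") d <- 0
  fun <- switch(kind,
    sine = if (literal_sine) function(t) sin(pi * 25 / t)
           else function(t) sin(pi * t / 25),
    linear = ,
    quadratic = function(t) a + b * t + d * t^2)
  if (kind != "sine" && b == 0 && d == 0)
    warning("constant signal: no age-related change to align on")
  if (is.null(grid)) {
    grid <- if (kind == "sine") (seq_len(n)) * (50 / n) else seq_len(n)
  } else {
    grid <- as.numeric(grid)
    if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  }
  structure(list(kind = kind, fun = fun, grid = grid,
                 coefficients = c(a = a, b = b, d = d)),
            class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat(sprintf("signal model: %s over %d points in [%g, %g]\n", x$kind,
              length(x$grid), min(x$grid), max(x$grid)))
  if (x$kind != "sine")
    cat(sprintf("  f(t) = %g + %g t + %g t^2\n", x$coefficients["a"],
                x$coefficients["b"], x$coefficients["d"]))
  invisible(x)
}

#' Injected time-shift functions
#'
#' Evaluable shift profiles `Delta(t)` injected into the second series of a
#' benchmark pair: constant, linear ramps, and center-peaked / center-dipped
#' quadratics. The conventional families used throughout the benchmarks are
#' C1 (linear 0 to 4), C2 (linear 4 to 0), C3 (quadratic 0 -> 4 -> 0) and C4
#' (quadratic 4 -> 0 -> 4), parameterised over the simulation grid; their
#' exact amplitudes are a reconstruction and fully configurable.
#'
#' @param kind `"constant"`, `"linear"` or `"quadratic"`.
#' @param value constant shift (for `"constant"`).
#' @param from,to endpoint values of a linear ramp over `[t_min, t_max]`.
#' @param edge,center values at the interval ends and midpoint of a
#'   quadratic profile.
#' @return an object of class `shift_function`: `kind`, `fun` (`Delta(t)`,
#'   needs the grid range supplied at evaluation), `params`.
#' @examples
#' C3 <- shift_function("quadratic", edge = 0, center = 4)
#' C3$fun(seq(1, 20), c(1, 20))
#' @export
shift_function <- function(kind = c("constant", "linear", "quadratic"),
                           value = 0, from = 0, to = 0, edge = 0,
                           center = 0) {
  kind <- match.arg(kind)
  fun <- switch(kind,
    constant = function(t, rng) rep(value, length(t)),
    linear = function(t, rng)
      from + (to - from) * (t - rng[1]) / (rng[2] - rng[1]),
    quadratic = function(t, rng) {
      tm <- mean(rng)
      edge + (center - edge) * (1 - ((t - tm) / (tm - rng[1]))^2)
    })
  structure(list(kind = kind, fun = fun,
                 params = c(value = value, from = from, to = to,
                            edge = edge, center = center)),
            class = "shift_function")
}

#' Conventional variable-shift families C1-C4
#'
#' @param name one of `"C1"` (linear 0 to 4), `"C2"` (linear 4 to 0),
#'   `"C3"` (quadratic 0 -> 4 -> 0), `"C4"` (quadratic 4 -> 0 -> 4).
#' @param amplitude peak shift amplitude (default 4).
#' @return a [shift_function()].
#' @export
shift_preset <- function(name = c("C1", "C2", "C3", "C4"), amplitude = 4) {
  name <- match.arg(name)
  switch(name,
    C1 = shift_function("linear", from = 0, to = amplitude),
    C2 = shift_function("linear", from = amplitude, to = 0),
    C3 = shift_function("quadratic", edge = 0, center = amplitude),
    C4 = shift_function("quadratic", edge = amplitude, center = 0))
}

#' Noise level from an error-variance fraction
#'
#' Benchmarks quote noise as the fraction `r` of the total variance
#' attributable to error. This resolves the Gaussian noise sd so that
#' `sd^2 / (sd^2 + var(f(grid))) = r`, i.e.
#' `sd = sqrt(r / (1 - r) * var(f(grid)))`, using the sample variance of the
#' signal over the grid.
#'
#' @param model a [signal_model()].
#' @param grid time grid (defaults to the model's own grid).
#' @param r error-variance fraction in (0, 1).
#' @return the noise standard deviation.
#' @examples
#' m <- signal_model("linear", a = 0, b = 1, grid = 1:3)
#' resolve_sd(m, r = 0.2)  # signal var 1 -> sd 0.5
#' @export
resolve_sd <- function(model, grid = model$grid, r) {
  if (length(r) != 1 || !is.finite(r) || r <= 0 || r >= 1)
    stop("r must lie strictly between 0 and 1")
  v <- var(model$fun(grid))
  if (v < .Machine$double.eps)
    stop("constant signal over the grid: error fraction is undefined")
  sqrt(r / (1 - r) * v)
}

#' Generate a benchmark pair with known injected heterochrony
#'
#' Draws two series on the same time grid: `series1 = f(t) + e1` and
#' `series2 = f(t + Delta(t)) + e2`, with independent Gaussian errors of the
#' same sd. `f` is analytic, so the shifted evaluation may leave the grid
#' without extrapolation issues. Aligning `series2` (query) to `series1`
#' (reference) should recover `+Delta(t)`: series2 carries at time `t` the
#' expression the reference only reaches at time `t + Delta(t)`, so the
#' reference is delayed by `Delta`.
#'
#' @param model a [signal_model()].
#' @param shift a [shift_function()] (or a single number for a constant
#'   shift).
#' @param sd noise standard deviation; give either `sd` or `r`.
#' @param r error-variance fraction, resolved via [resolve_sd()].
#' @param groups group labels for the two series.
#' @param gene_id identifier.
#' @return `list(reference, query)` of [raw_series()].
#' @export
make_pair <- function(model, shift = 0, sd = NULL, r = NULL,
                      groups = c("sp1", "sp2"), gene_id = "sim") {
  stopifnot(inherits(model, "signal_model"))
  if (is.numeric(shift)) shift <- shift_function("constant", value = shift)
  stopifnot(inherits(shift, "shift_function"))
  if (is.null(sd) == is.null(r))
    stop("give exactly one of sd or r")
  if (!is.null(r)) sd <- resolve_sd(model, r = r)
  if (sd < 0) stop("sd must be non-negative")
  grid <- model$grid
  rng <- range(grid)
  delta <- shift$fun(grid, rng)
  if (any(abs(delta) >= diff(rng)))
    stop("injected shift exceeds the time-grid span")
  n <- length(grid)
  ref <- raw_series(grid, model$fun(grid) + rnorm(n, 0, sd),
                    gene_id, groups[1])
  qry <- raw_series(grid, model$fun(grid + delta) + rnorm(n, 0, sd),
                    gene_id, groups[2])
  list(reference = ref, query = qry, true_shift = delta, sd = sd)
}

#' Replicated shift-recovery benchmark
#'
#' Repeats [make_pair()] plus the full estimation pipeline (`spline fit ->
#' uniform interpolation -> balanced warping -> shifts`) `R` times and
#' aggregates the per-time-point estimates: mean, bias against the injected
#' shift, RMSE and the empirical 5-95% band.
#'
#' @inheritParams make_pair
#' @param N,M query / reference interpolation grid sizes.
#' @param R number of replicate simulations.
#' @param seed RNG seed (set once before the replicate loop).
#' @param df spline smoothing for the estimation step (default GCV).
#' @param keep_estimates if `TRUE` the full `R x N` estimate matrix is
#'   retained in the report.
#' @return an object of class `recovery_report`: `query_times`,
#'   `true_shift` (injected shift at the query grid), `mean`, `bias`,
#'   `rmse`, `band` (2 x N matrix, 5% and 95%), `R`, and optionally
#'   `estimates`.
#' @examples
#' m <- signal_model("sine", n = 20)
#' rep <- run_recovery(m, shift = 5, sd = 0.3, N = 20, M = 40, R = 20,
#'                     seed = 1)
#' round(interior_mean(rep), 1)
#' @export
run_recovery <- function(model, shift = 0, sd = NULL, r = NULL,
                         N = 20, M = 40, R = 100, seed = NULL, df = "gcv",
                         keep_estimates = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(shift)) shift <- shift_function("constant", value = shift)
  grid <- model$grid
  qt <- seq(min(grid), max(grid), length.out = N)
  est <- matrix(NA_real_, R, N)
  for (rep_i in seq_len(R)) {
    pair <- make_pair(model, shift, sd = sd, r = r)
    est[rep_i, ] <- .shift_once(pair$reference$ages, pair$reference$values,
                                pair$query$ages, pair$query$values,
                                M = M, N = N, df = df)
  }
  truth <- shift$fun(qt, range(grid))
  mu <- colMeans(est)
  structure(
    list(query_times = qt, true_shift = truth, mean = mu,
         bias = mu - truth,
         rmse = sqrt(colMeans((est - matrix(truth, R, N, byrow = TRUE))^2)),
         band = apply(est, 2, quantile, probs = c(0.05, 0.95)),
         R = R, N = N, M = M, sd = if (is.null(sd)) NA_real_ else sd,
         r = if (is.null(r)) NA_real_ else r,
         model_kind = model$kind, shift_kind = shift$kind,
         estimates = if (keep_estimates) est else NULL),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(
    "shift-recovery benchmark: %s signal, %s shift, R = %d replicates\n",
    x$model_kind, x$shift_kind, x$R))
  cat(sprintf("  grids: N = %d query, M = %d reference\n", x$N, x$M))
  cat(sprintf("  interior mean estimate %.3f (true %.3f); max |bias| %.3f\n",
              interior_mean(x), interior_mean(x, what = "true_shift"),
              max(abs(x$bias))))
  invisible(x)
}

#' Mean over the interior of a recovery report
#'
#' Averages a per-time-point summary over the central fraction of the query
#' grid, excluding the boundary points where balanced warping is biased by
#' construction (the query ends are always aligned).
#'
#' @param report a [run_recovery()] report.
#' @param what which per-point vector to average (`"mean"`, `"bias"`,
#'   `"rmse"`, `"true_shift"`).
#' @param frac central fraction of points retained (default 0.5).
#' @return a single number.
#' @export
interior_mean <- function(report, what = "mean", frac = 0.5) {
  v <- report[[what]]
  n <- length(v)
  drop <- floor(n * (1 - frac) / 2)
  mean(v[(drop + 1):(n - drop)])
}

#' Linear versus quadratic description of a recovered shift profile
#'
#' Tests whether the mean recovered shift profile is better described by a
#' quadratic than a linear function of time, via the nested-model F-test.
#' Used to ask whether a variable (curved) injected heterochrony is
#' detectable as such.
#'
#' @param report a [run_recovery()] report with at least 6 time points.
#' @return a list with `F`, `p` (p-value of the quadratic term), and
#'   `preferred` (`"quadratic"` if `p < 0.05`, else `"linear"`; exact ties /
#'   degenerate fits fall back to `"linear"` by parsimony).
#' @export
compare_shift_models <- function(report) {
  stopifnot(inherits(report, "recovery_report"))
  t <- report$query_times
  y <- report$mean
  if (length(t) < 6) stop("need at least 6 time points")
  f1 <- lm(y ~ t)
  f2 <- lm(y ~ t + I(t^2))
  a <- anova(f1, f2)
  Fv <- a$F[2]; p <- a$`Pr(>F)`[2]
  ss1 <- sum(residuals(f1)^2)
  ss2 <- sum(residuals(f2)^2)
  degenerate <- !is.finite(Fv) || is.na(p) ||
    (ss1 - ss2) <= 1e-10 * max(ss1, mean(y)^2, 1e-300)
  if (degenerate) { Fv <- 0; p <- 1 }  # both fits equivalent: parsimony
  list(F = Fv, p = p,
       preferred = if (p < 0.05) "quadratic" else "linear",
       linear_fit = f1, quadratic_fit = f2)
}

#' Simulate a multi-gene expression dataset with injected heterochrony
#'
#' Builds a genes-by-samples log2 expression matrix plus sample metadata for
#' two groups, by drawing every gene from its own randomly parameterised
#' quadratic signal model, injecting a constant time shift into the query
#' group for a chosen fraction of genes. Used to exercise the dataset-level
#' screening, significance and clustering machinery on data of known
#' composition.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param frac_shifted fraction of genes receiving a non-zero shift.
#' @param shift constant shift injected into the affected genes.
#' @param r error-variance fraction per gene.
#' @param groups group labels `(reference, query)`.
#' @param seed RNG seed.
#' @return `list(expr, meta, truth)`: `expr` is a genes x samples matrix,
#'   `meta` a data.frame with columns `sample`, `group`, `age`, and `truth`
#'   a logical vector marking the shifted genes.
#' @export
simulate_expression_set <- function(n_genes = 20, n_per_group = 20,
                                    frac_shifted = 0.5, shift = 2, r = 0.1,
                                    groups = c("sp1", "sp2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages <- seq_len(n_per_group)
  shifted <- seq_len(n_genes) <= round(frac_shifted * n_genes)
  expr <- matrix(NA_real_, n_genes, 2 * n_per_group)
  for (g in seq_len(n_genes)) {
    cf <- c(a = runif(1, -1, 1), b = runif(1, 0.5, 1.5) * sample(c(-1, 1), 1),
            d = runif(1, -0.05, 0.05))
    m <- signal_model("quadratic", a = cf["a"], b = cf["b"], d = cf["d"],
                      n = n_per_group)
    pair <- make_pair(m, shift = if (shifted[g]) shift else 0, r = r,
                      groups = groups)
    expr[g, ] <- c(pair$reference$values, pair$query$values)
  }
  rownames(expr) <- sprintf("gene%03d", seq_len(n_genes))
  samples <- c(sprintf("%s_%02d", groups[1], ages),
               sprintf("%s_%02d", groups[2], ages))
  colnames(expr) <- samples
  meta <- data.frame(sample = samples,
                     group = rep(groups, each = n_per_group),
                     age = rep(ages, 2), stringsAsFactors = FALSE)
  list(expr = expr, meta = meta, truth = shifted)
}
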