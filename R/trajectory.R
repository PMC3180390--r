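#' Construct a raw expression time series
#'
#' Bundles one group's observed (age, expression) measurements for a single
#' gene. Ages are sorted ascending on ingestion; values follow their ages.
#' Expression is assumed to be on a log2 scale and pre-normalised.
#'
#' @param ages numeric vector of sampling times (strictly positive ages in
#'   years, or abstract model time units). Duplicated ages are allowed
#'   (several individuals of the same age).
#' @param values numeric vector of expression levels (log2 units), same
#'   length as `ages`.
#' @param gene_id,group identifier strings attached to the series.
#' @return an object of class `raw_series` with elements `ages`, `values`,
#'   `gene_id`, `group`.
#' @examples
#' s <- raw_series(c(3, 1, 2, 5, 4), c(0.3, 0.1, 0.2, 0.5, 0.4), "g1", "human")
#' s$ages
#' @export
raw_series <- function(ages, values, gene_id = "gene", group = "group") {
  ages <- as.numeric(ages)
  values <- as.numeric(values)
  if (length(ages) != length(values))
    stop("ages and values must have the same length")
  if (length(ages) < 5L)
    stop("insufficient observations: at least 5 points are required")
  if (anyNA(ages) || anyNA(values) || any(!is.finite(ages)) ||
      any(!is.finite(values)))
    stop("missing or non-finite values are not allowed")
  ord <- order(ages)
  structure(
    list(ages = ages[ord], values = values[ord],
         gene_id = as.character(gene_id), group = as.character(group)),
    class = "raw_series")
}

#' @export
print.raw_series <- function(x, ...) {
  cat(sprintf("raw series: gene %s, group %s, %d points, ages [%g, %g]\n",
              x$gene_id, x$group, length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Fit a cubic smoothing spline trajectory
#'
#' Fits a cubic smoothing spline to a noisy age-expression series, either at
#' a requested effective degrees of freedom (trace of the smoother matrix) or
#' with the smoothing level chosen by generalized cross-validation. The
#' fitted trajectory is the basis for uniform interpolation and alignment.
#'
#' `df = 4` is the recommended setting for real biological data with a few
#' dozen samples; `df = "gcv"` is used for simulation-generated series whose
#' wiggliness is not known in advance. If a GCV fit fails on a degenerate
#' draw, the fit falls back to `df = 4`.
#'
#' @param series a [raw_series()].
#' @param df `"gcv"` or a numeric effective degrees of freedom in
#'   `[2, m - 1]` where `m` is the number of observations.
#' @return an object of class `dtws_spline` with elements `fit` (the
#'   underlying [stats::smooth.spline] object), `df` (realised effective
#'   df), `residuals` (observed minus fitted at the observed ages),
#'   `fitted`, `domain`, plus the series identifiers.
#' @examples
#' set.seed(1)
#' t <- seq(1, 20, length.out = 30)
#' s <- raw_series(t, sin(pi * t / 25) + rnorm(30, sd = 0.2))
#' f <- fit_spline(s, df = 4)
#' round(f$df, 2)
#' @export
fit_spline <- function(series, df = 4) {
  stopifnot(inherits(series, "raw_series"))
  m <- length(series$ages)
  if (length(unique(series$ages)) < 2L)
    stop("constant-age series cannot be fitted")
  if (length(unique(series$ages)) < 4L)
    stop("insufficient observations: fewer than 4 distinct ages")
  gcv <- identical(df, "gcv")
  if (!gcv) {
    df <- as.numeric(df)
    if (!is.finite(df) || df < 2 || df > m - 1)
      stop("df must be 'gcv' or a number in [2, m - 1]")
  }
  fit <- if (gcv) {
    tryCatch(
      smooth.spline(series$ages, series$values, cv = FALSE,
                    keep.data = FALSE),
      error = function(e)
        smooth.spline(series$ages, series$values,
                      df = min(4, length(unique(series$ages)) - 1),
                      keep.data = FALSE))
  } else {
    smooth.spline(series$ages, series$values, df = df, keep.data = FALSE)
  }
  fv <- predict(fit, series$ages)$y
  structure(
    list(fit = fit, df = fit$df, requested_df = if (gcv) "gcv" else df,
         residuals = series$values - fv, fitted = fv,
         domain = range(series$ages), series = series,
         gene_id = series$gene_id, group = series$group),
    class = "dtws_spline")
}

#' @export
print.dtws_spline <- function(x, ...) {
  cat(sprintf(
    "cubic smoothing spline: gene %s, group %s, edf %.2f, domain [%g, %g]\n",
    x$gene_id, x$group, x$df, x$domain[1], x$domain[2]))
  cat(sprintf("  residual sd %.4g over %d observations\n",
              sd(x$residuals), length(x$residuals)))
  invisible(x)
}

#' @export
predict.dtws_spline <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.numeric(newdata)
  if (any(newdata < object$domain[1] - 1e-9 |
          newdata > object$domain[2] + 1e-9))
    stop("prediction outside the fitted age domain is not supported")
  predict(object$fit, newdata)$y
}

#' @export
residuals.dtws_spline <- function(object, ...) object$residuals

#' Resample a fitted trajectory at uniform time points
#'
#' Evaluates a fitted spline trajectory at `K` equally spaced time points
#' spanning the observed age domain (endpoints included; never
#' extrapolates). Uniform grids let the aligner compare trajectories sampled
#' at arbitrary, non-matching ages.
#'
#' @param model a [fit_spline()] result.
#' @param K number of interpolation points, at least 2.
#' @return an object of class `interp_series` with `times`, `values`, `K`
#'   and the series identifiers.
#' @examples
#' set.seed(1)
#' s <- raw_series(1:10, (1:10)^2 + rnorm(10, sd = 0.1))
#' interpolate_uniform(fit_spline(s, df = 4), K = 5)$times
#' @export
interpolate_uniform <- function(model, K) {
  stopifnot(inherits(model, "dtws_spline"))
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("K must be at least 2")
  times <- seq(model$domain[1], model$domain[2], length.out = K)
  structure(
    list(times = times, values = predict(model, times), K = K,
         gene_id = model$gene_id, group = model$group),
    class = "interp_series")
}

#' @export
print.interp_series <- function(x, ...) {
  cat(sprintf("interpolated series: gene %s, group %s, K = %d over [%g, %g]\n",
              x$gene_id, x$group, x$K, x$times[1], x$times[x$K]))
  invisible(x)
}

#' Log2 age transform including a pre-birth offset
#'
#' Maps chronological ages to `log2(age + offset)`. With `offset` equal to
#' the gestation length (in the same units as the ages) the transform places
#' conception at `log2(offset)` and spreads early development over a wider
#' portion of the axis, which is how primate brain ontogenesis is usually
#' displayed. `offset = 0` leaves only the plain log2.
#'
#' @param ages numeric vector; `ages + offset` must be strictly positive.
#' @param offset non-negative constant added before taking log2.
#' @return numeric vector `log2(ages + offset)`; strictly monotone in `ages`.
#' @examples
#' transform_ages(c(0, 3), offset = 1)
#' @export
transform_ages <- function(ages, offset = 0) {
  offset <- as.numeric(offset)
  if (length(offset) != 1L || !is.finite(offset) || offset < 0)
    stop("offset must be a single non-negative number")
  ages <- as.numeric(ages)
  if (any(ages + offset <= 0))
    stop("ages + offset must be strictly positive")
  log2(ages + offset)
}
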