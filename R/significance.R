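#' Null model for a gene: fitted trajectory plus residual noise
#'
#' Fits a cubic smoothing spline to the designated source series and
#' summarises its residuals as a Gaussian noise model (the residual mean is
#' retained, not forced to zero). Pairs of series drawn from this model
#' share one mean trajectory and therefore have zero true time shift.
#'
#' A smoother with `edf` effective degrees of freedom absorbs part of the
#' noise, so the plain variance of its residuals under-estimates the noise
#' variance by roughly `(n - edf)/n`; a null background simulated with it is
#' slightly too tame and inflates apparent significance. The default
#' `noise_var = "unbiased"` therefore scales the residual variance by
#' `n / (n - edf)` (the standard noise estimate under a linear smoother);
#' `"residual"` keeps the plain sample variance of the residuals.
#'
#' @param series the source [raw_series()] (conventionally the reference
#'   group's series).
#' @param df spline smoothing for the source fit; default 4, the setting
#'   for real biological data with a few dozen samples.
#' @param noise_var `"unbiased"` (default) or `"residual"`, see Details.
#' @return `list(model, noise)` where `model` is a [fit_spline()] result and
#'   `noise` is `list(mean, sd)`.
#' @export
build_null_model <- function(series, df = 4,
                             noise_var = c("unbiased", "residual")) {
  noise_var <- match.arg(noise_var)
  model <- fit_spline(series, df = df)
  res <- residuals(model)
  n <- length(res)
  s2 <- var(res)
  if (noise_var == "unbiased")
    s2 <- sum((res - mean(res))^2) / max(1, n - model$df)
  list(model = model, noise = list(mean = mean(res), sd = sqrt(s2)))
}

#' Simulate a zero-true-shift pair of series
#'
#' Draws two series from one fitted trajectory -- the expression level at
#' each requested age is the spline value plus Gaussian noise -- so the true
#' time shift between them is exactly zero. The requested ages are normally
#' the real observation ages of the two groups, preserving each group's
#' sampling design.
#'
#' Uses R's global RNG; seed at the caller.
#'
#' @param model a [fit_spline()] result.
#' @param noise `list(mean, sd)` as returned by [build_null_model()].
#' @param times_a,times_b observation ages for the two simulated series;
#'   must lie within the model's fitted domain.
#' @return `list(x, y)` of [raw_series()].
#' @export
simulate_zero_shift_pair <- function(model, noise, times_a, times_b) {
  stopifnot(inherits(model, "dtws_spline"))
  mu_a <- predict(model, times_a)   # errors outside the domain
  mu_b <- predict(model, times_b)
  list(
    x = raw_series(times_a, mu_a + rnorm(length(times_a), noise$mean,
                                         noise$sd),
                   model$gene_id, "sim_a"),
    y = raw_series(times_b, mu_b + rnorm(length(times_b), noise$mean,
                                         noise$sd),
                   model$gene_id, "sim_b"))
}

#' Pointwise Monte-Carlo p-values for a shift profile
#'
#' For every query time point, the p-value is the proportion of simulated
#' zero-shift profiles whose absolute shift at that point is at least as
#' large as the observed absolute shift:
#' `p_i = #\{b : |shift_sim(b, i)| >= |shift_real(i)|\} / B`.
#' The plain proportion can be zero; `correction = TRUE` applies the
#' `(k + 1) / (B + 1)` adjustment instead.
#'
#' @param real observed shifts: a `shift_profile` or numeric vector.
#' @param sims simulated shifts: a list of `shift_profile`s / numeric
#'   vectors, or a `B x N` matrix.
#' @param correction add-one correction (default off).
#' @return numeric vector of length `N` in `[0, 1]`.
#' @export
pointwise_pvalues <- function(real, sims, correction = FALSE) {
  rv <- if (inherits(real, "shift_profile")) real$shifts else as.numeric(real)
  if (is.list(sims))
    sims <- do.call(rbind, lapply(sims, function(s)
      if (inherits(s, "shift_profile")) s$shifts else as.numeric(s)))
  if (ncol(sims) != length(rv))
    stop("simulated profiles do not match the observed grid")
  B <- nrow(sims)
  if (B < 1) stop("need at least one simulation")
  k <- colSums(abs(sims) >= matrix(abs(rv), B, length(rv), byrow = TRUE))
  if (correction) (k + 1) / (B + 1) else k / B
}

#' Per-gene Monte-Carlo significance of time shifts
#'
#' Runs the full per-gene significance scheme: estimate the real shift
#' profile; simulate `B` zero-shift pairs from the null model and re-estimate
#' their shifts to obtain pointwise p-values; count the points with
#' `p < alpha`; then draw `G` further zero-shift "pseudo-real" pairs and
#' count their significant points against the same background (or a fresh
#' background per replicate) to supply this gene's contribution to the null
#' count distribution used for FPR calibration.
#'
#' @param query,reference [raw_series()] for the gene's two groups.
#' @param B number of background zero-shift simulations.
#' @param G number of pseudo-real zero-shift replicates.
#' @param alpha pointwise significance cut-off.
#' @param K_query,K_reference interpolation grid sizes.
#' @param df_est spline smoothing for the *estimation* fits, applied
#'   identically to the real pair and to every simulated pair so that real
#'   and simulated shift magnitudes are comparable (default GCV; set 4 to
#'   mirror the fixed-df analysis of real data).
#' @param df_null spline smoothing for the source-series null model
#'   (default 4).
#' @param noise_var noise-variance convention, see [build_null_model()].
#' @param source which series seeds the null model (default the reference).
#' @param shared_background if `TRUE` (default) the `G` pseudo-real
#'   replicates are compared to the same `B` background simulations; if
#'   `FALSE` each replicate gets a fresh background of size `B`.
#' @param multi_map see [align()].
#' @param seed optional RNG seed.
#' @return an object of class `dtws_sig`: `gene_id`, `shifts` (real
#'   profile), `pointwise_p`, `n_significant`, `null_counts` (length `G`),
#'   `alpha`, `B`, `G`, `N`. Gene-level calls are made at the dataset level
#'   by [calibrate_fpr()].
#' @export
run_gene_significance <- function(query, reference, B = 1000, G = 50,
                                  alpha = 0.05, K_query = 20,
                                  K_reference = 40, df_est = "gcv",
                                  df_null = 4,
                                  noise_var = "unbiased",
                                  source = c("reference", "query"),
                                  shared_background = TRUE,
                                  multi_map = "both", seed = NULL) {
  source <- match.arg(source)
  if (!is.null(seed)) set.seed(seed)
  mm_both <- multi_map == "both"
  real <- .shift_once(reference$ages, reference$values,
                      query$ages, query$values,
                      M = K_reference, N = K_query,
                      multi_map_both = mm_both, df = df_est)
  nm <- build_null_model(if (source == "reference") reference else query,
                         df = df_null, noise_var = noise_var)
  sim_shift <- function() {
    pr <- simulate_zero_shift_pair(nm$model, nm$noise,
                                   reference$ages, query$ages)
    .shift_once(pr$x$ages, pr$x$values, pr$y$ages, pr$y$values,
                M = K_reference, N = K_query, multi_map_both = mm_both,
                df = df_est)
  }
  sims <- t(vapply(seq_len(B), function(b) sim_shift(), numeric(K_query)))
  p <- pointwise_pvalues(real, sims)
  null_counts <- integer(G)
  for (g in seq_len(G)) {
    pseudo <- sim_shift()
    bg <- if (shared_background) sims
          else t(vapply(seq_len(B), function(b) sim_shift(),
                        numeric(K_query)))
    null_counts[g] <- sum(pointwise_pvalues(pseudo, bg) < alpha)
  }
  structure(
    list(gene_id = query$gene_id, shifts = real, pointwise_p = p,
         n_significant = sum(p < alpha), null_counts = null_counts,
         alpha = alpha, B = B, G = G, N = K_query),
    class = "dtws_sig")
}

#' @export
print.dtws_sig <- function(x, ...) {
  cat(sprintf(
    "time-shift significance: gene %s, %d of %d points with p < %g (B = %d)\n",
    x$gene_id, x$n_significant, x$N, x$alpha, x$B))
  invisible(x)
}

#' False positive rate of the per-gene significant-point count
#'
#' The gene-level statistic is the number of query points with a significant
#' shift. Its false positive rate at a count threshold `c` is the ratio of
#' tail probabilities
#' `FPR(c) = P_null(count >= c) / P_real(count >= c)`,
#' where the null distribution pools the zero-shift pseudo-real replicates
#' of all genes and the real distribution is the observed per-gene counts.
#' The ratio is capped at 1. The additive variant
#' `P_null(count >= c) - ...` is not used; a `difference = TRUE` flag
#' returns `P_null(count >= c)` alone for inspection.
#'
#' @param real_counts integer vector: observed significant-point counts, one
#'   per gene.
#' @param null_counts integer vector or matrix (genes x replicates) of
#'   null counts.
#' @param c count threshold (`0 <= c <= N`).
#' @param difference if `TRUE`, return the null tail probability instead of
#'   the ratio.
#' @return the FPR at `c`, in `[0, 1]`.
#' @export
estimate_fpr <- function(real_counts, null_counts, c, difference = FALSE) {
  real_counts <- as.numeric(real_counts)
  null_counts <- as.numeric(null_counts)
  if (!length(real_counts) || !length(null_counts))
    stop("empty count distribution")
  if (c < 0) stop("threshold must be non-negative")
  p_real <- mean(real_counts >= c)
  p_null <- mean(null_counts >= c)
  if (difference) return(p_null)
  if (p_real == 0) stop("no genes at threshold: real tail is empty")
  min(1, p_null / p_real)
}

#' Smallest count threshold achieving a target FPR
#'
#' Scans `c = 0, 1, ..., N` and returns the smallest threshold whose
#' [estimate_fpr()] is defined and at most `target_fpr`.
#'
#' @inheritParams estimate_fpr
#' @param target_fpr desired FPR level in `(0, 1]`.
#' @param N maximum count (number of query points).
#' @return the chosen threshold (integer). Errors if no threshold reaches
#'   the target, listing the achievable FPR curve.
#' @export
choose_threshold <- function(real_counts, null_counts, target_fpr, N) {
  if (target_fpr <= 0 || target_fpr > 1)
    stop("target_fpr must be in (0, 1]")
  curve <- vapply(0:N, function(cc) {
    if (mean(real_counts >= cc) == 0) return(NA_real_)
    estimate_fpr(real_counts, null_counts, cc)
  }, numeric(1))
  ok <- which(!is.na(curve) & curve <= target_fpr)
  if (!length(ok))
    stop(sprintf(
      "no threshold achieves FPR <= %g; achievable curve: %s",
      target_fpr,
      paste(sprintf("c=%d:%.3f", 0:N, curve), collapse = ", ")))
  as.integer(ok[1] - 1L)
}

#' Dataset-level significance with FPR calibration
#'
#' Applies [run_gene_significance()] to every gene of a two-group dataset,
#' pools the per-gene significant-point counts ("real" distribution) and the
#' zero-shift replicate counts ("null" distribution), picks the count
#' threshold at the requested FPR, and calls each gene significant when its
#' count reaches the threshold. Per-gene RNG substreams are derived from the
#' master seed, so results do not depend on evaluation order.
#'
#' @param dataset a list of genes, each `list(query =, reference =)` of
#'   [raw_series()] (as produced by [read_expression_set()] /
#'   [as_gene_pairs()]).
#' @inheritParams run_gene_significance
#' @param target_fpr FPR level for the count threshold.
#' @param seed master seed.
#' @return an object of class `dtws_sig_set`: `table` (data.frame with
#'   gene_id, n_significant, min_p, gene_significant), `threshold_c`,
#'   `fpr_at_c`, `fpr_curve`, `real_counts`, `null_counts` (genes x G
#'   matrix), `per_gene` (list of `dtws_sig`), and the run parameters.
#' @export
calibrate_fpr <- function(dataset, B = 1000, G = 50, alpha = 0.05,
                          target_fpr = 0.10, K_query = 20, K_reference = 40,
                          df_est = "gcv", df_null = 4,
                          noise_var = "unbiased", source = "reference",
                          shared_background = TRUE, multi_map = "both",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, length(dataset))
  per_gene <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    per_gene[[i]] <- run_gene_significance(
      dataset[[i]]$query, dataset[[i]]$reference, B = B, G = G,
      alpha = alpha, K_query = K_query, K_reference = K_reference,
      df_est = df_est, df_null = df_null, noise_var = noise_var,
      source = source,
      shared_background = shared_background, multi_map = multi_map,
      seed = gene_seeds[i])
  }
  real_counts <- vapply(per_gene, `[[`, integer(1), "n_significant")
  null_counts <- do.call(rbind, lapply(per_gene, `[[`, "null_counts"))
  N <- K_query
  fpr_curve <- vapply(0:N, function(cc) {
    if (mean(real_counts >= cc) == 0) return(NA_real_)
    estimate_fpr(real_counts, null_counts, cc)
  }, numeric(1))
  threshold_c <- tryCatch(
    choose_threshold(real_counts, null_counts, target_fpr, N),
    error = function(e) NA_integer_)
  fpr_at_c <- if (is.na(threshold_c)) NA_real_ else fpr_curve[threshold_c + 1]
  tab <- data.frame(
    gene_id = vapply(per_gene, `[[`, character(1), "gene_id"),
    n_significant = real_counts,
    min_p = vapply(per_gene, function(x) min(x$pointwise_p), numeric(1)),
    gene_significant = if (is.na(threshold_c)) NA
                       else real_counts >= threshold_c,
    stringsAsFactors = FALSE)
  structure(
    list(table = tab, threshold_c = threshold_c, fpr_at_c = fpr_at_c,
         fpr_curve = setNames(fpr_curve, 0:N), real_counts = real_counts,
         null_counts = null_counts, per_gene = per_gene,
         B = B, G = G, alpha = alpha, target_fpr = target_fpr, N = N),
    class = "dtws_sig_set")
}

#' @export
print.dtws_sig_set <- function(x, ...) {
  cat(sprintf(
    "dataset significance: %d genes, B = %d, G = %d, alpha = %g\n",
    nrow(x$table), x$B, x$G, x$alpha))
  if (is.na(x$threshold_c)) {
    cat(sprintf("  no count threshold reaches FPR <= %g\n", x$target_fpr))
  } else {
    cat(sprintf(
      "  threshold: >= %d of %d significant points (FPR %.3f); %d genes called\n",
      x$threshold_c, x$N, x$fpr_at_c, sum(x$table$gene_significant)))
  }
  invisible(x)
}
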