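---
title: "Balanced time warping and time-shift significance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced time warping and time-shift significance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtws)
```

## The problem

Developmental gene-expression time series from two groups — two species, two
conditions, two tissues — often trace the same trajectory at different
speeds. Human brain transcriptomes, for example, pass through the same
expression states as chimpanzee transcriptomes but reach them years later
(developmental delay, or *neoteny*). Quantifying that heterochrony per gene
requires (i) an alignment between two noisy, irregularly sampled series,
(ii) a time-shift estimate at every time point rather than a single global
offset, and (iii) a significance statement: how large a shift would be seen
by chance when the true shift is zero?

`dtws` implements all three. The fitting function `dtws()` returns a classed
object with the usual modelling verbs (`coef`, `summary`, `plot`,
`predict`, `residuals`, `simulate`); the surrounding functions provide the
Monte-Carlo significance machinery, benchmark generators with known injected
heterochrony, and an application-layer screen/classify/cluster pipeline.

## Trajectory model

Each group's series for a gene is smoothed with a cubic smoothing spline
(`stats::smooth.spline`), i.e. the minimiser of penalized least squares. The
smoothing level is set either to a target effective degrees of freedom (the
trace of the smoother matrix) or by generalized cross-validation (GCV):

* **`df = 4`** is the default for real biological data with a few dozen
  samples per group. Four effective df accommodate one or two inflections —
  the shape complexity seen in postnatal brain expression trajectories —
  without chasing noise.
* **`df = "gcv"`** is used wherever the wiggliness is not known a priori,
  in particular for every simulated draw inside the significance machinery.
  On noiseless data GCV drives the penalty to zero and the spline becomes an
  interpolant; note that a *fixed* finite df does **not** reproduce an exact
  polynomial (the penalty shrinks its curvature), which is why exactness
  properties are only guaranteed in the GCV/interpolation limit.
  If a GCV fit fails on a degenerate draw, the fit falls back to `df = 4`.

The fitted trajectory is then resampled at `K` uniformly spaced points
spanning exactly the observed age range of its own group — never beyond it
(no extrapolation). Typical grids are `K = 20` for the query and `K = 40`
for the reference, so shifts are resolved at about half a query step. Ages
may optionally be transformed to `log2(age + offset)` at ingestion (the
offset playing the role of a gestation time, spreading early development
across the axis); all downstream shifts are then on the transformed scale.

## Balanced, end-unanchored warping

Let `X` (length `M`) be the interpolated reference and `Y` (length `N <= M`)
the interpolated query. The alignment must
(1) be monotone, (2) allow *multiple mapping* — one point of either series
may align to several consecutive points of the other — and (3) be
*balanced*: exactly `N` distinct reference columns are used, so exactly
`M - N` are omitted. Omissions are free of charge and may fall anywhere,
including before the first and after the last matched column; this removes
the requirement that the series ends correspond, which is rarely known for
developmental processes. The cost of an alignment is the sum of squared
expression differences over aligned pairs (argmin-equivalent to Euclidean
distance, with each multiply-mapped pair contributing its own term).

The dynamic program state is `(i, j, k, s)`: the minimal cost of aligning
the first `i` query points to the first `j` reference columns with `k`
omissions so far, `s` flagging whether column `j` is currently matched.
Transitions: omit column `j` (`k+1`, free); start a new match `(i, j)`;
extend query point `i` to another column; extend column `j` to another query
point (only legal when `s = 1`, so an omitted column can never be re-used —
this is what the `s` bit is for). The terminal state is `(N, M, M - N)`, and
each transition is O(1), giving `O(M N (M - N))` time. For `M = 40, N = 20`
an alignment takes well under a millisecond, which is what makes the
simulation-based significance affordable. `brute_force_align()` is an
independent oracle — exhaustive enumeration of column subsets and monotone
staircases — and the test suite demands exact cost agreement on hundreds of
random instances.

Numerical conventions:

* **Ties** are broken by preferring fewer aligned pairs, then by a fixed
  deterministic traceback order (matches preferred over omissions when
  walking back from the end). Ties beyond the pair count are a measure-zero
  event for continuous data; the traceback makes them reproducible but does
  not guarantee a canonical omitted set.
* **`multi_map = "query-only"`** disables the many-query-points-to-one-column
  transition; under the balanced constraint this reduces to a strict
  one-to-one match over the selected columns.
* **`M < N` input** is handled by swapping roles internally, flagging the
  orientation and inverting shift signs; the profile is then reported on the
  longer series' grid.

## Time shifts and their sign

For query point `Y_i` aligned to reference points `X_j .. X_j+q`,

    shift(Y_i) = mean(time(X_j), ..., time(X_j+q)) - time(Y_i).

When both axes are positive chronological ages, a reporting shift
`log2(aligned reference age / query age)` is also computed. **Positive means
the reference group is delayed**: it reaches the query's expression state at
an older age. Aligning a chimpanzee series to a human reference, positive
shifts are human neoteny. `classify_direction()` applies the majority-sign
rule: at least 70% of time points (zeros counting against) must agree for a
`"delayed"` or `"accelerated"` call, otherwise `"none"`.

## Significance of the shifts

The per-gene null asks: how large are shift estimates when the true shift is
zero but the trajectory and noise are as observed? The scheme:

1. Fit the source series (by default the reference) with `df_null = 4`; this
   is the null trajectory model. Summarise its residuals as Gaussian noise.
2. Draw `B` zero-shift pairs: both series sampled from the one fitted
   trajectory at the *real* observation ages of each group, plus independent
   noise. Estimate each pair's shift profile exactly as for real data.
3. Pointwise p-value at query point `i`: the fraction of the `B` simulated
   profiles whose absolute shift at `i` is at least the observed absolute
   shift (plain proportion; zero is possible, and an optional `+1/(B+1)`
   correction is available). Count the points with `p < alpha`
   (`alpha = 0.05`).
4. Draw `G` further zero-shift "pseudo-real" pairs and count their
   significant points against the same background (`shared_background =
   TRUE`; a fresh background per replicate is available). Pooled over genes
   these counts form the **null** distribution of the per-gene statistic;
   the observed counts form the **real** distribution.
5. The false positive rate at a count threshold `c` is the tail ratio
   `FPR(c) = P_null(count >= c) / P_real(count >= c)`, capped at 1;
   `choose_threshold()` returns the smallest `c` meeting a target FPR. A
   gene is called significant when its count reaches that threshold (with
   20 query points and a ~10% FPR this lands at the familiar
   "at least 7 of 20 points" rule).

Two design choices deserve emphasis:

* **Noise variance.** The plain variance of smoothing-spline residuals
  under-estimates the noise variance by roughly `(n - edf)/n`, because the
  smoother absorbs part of the noise. A null simulated with it is too tame:
  on datasets of zero-shift genes the real counts systematically exceed the
  null counts. The default is therefore the df-adjusted estimator
  `RSS/(n - edf)` (`noise_var = "unbiased"`), under which the real and null
  count distributions are statistically indistinguishable on zero-shift
  data — the calibration property the test suite checks over ten seeded
  datasets of 50 genes (B = 300, G = 20). The plain convention remains
  available as `noise_var = "residual"`.
* **Estimation symmetry.** The spline setting used to *estimate* shifts
  (`df_est`, default GCV) is applied identically to the real pair and to
  every simulated pair; comparing a fixed-df real estimate against GCV
  simulated estimates would bias the pointwise p-values.

Reproducibility: every entry point takes a seed; the dataset-level driver
derives one substream seed per gene from the master seed, so results are
independent of evaluation order and bit-identical across runs.

## Synthetic benchmarks

`signal_model()` + `make_pair()` generate pairs with known injected
heterochrony: `series1 = f(t) + e` and `series2 = f(t + Delta(t)) + e'`,
with independent Gaussian errors of equal sd on a shared grid. `f` is
analytic, so the shifted evaluation needs no extrapolation. Conventions:

* **Sine** `f(t) = sin(pi t / 25)` (period 50), sampled by default at
  `t = (1..n) * 50/n` — one full period, so the signal variance over the
  grid is ~0.5 and Gaussian noise with sd 0.3 contributes ~15% of the total
  variance, the regime typical of microarray developmental series. (The
  singular variant `sin(pi * 25 / t)` is available behind `literal_sine`
  for comparison only.)
* **Linear/quadratic** `f(t) = a + b t + d t^2` on `t = 1..n`, standing in
  for non-periodic organismal processes.
* **Noise** is specified either as an sd or as an error-variance fraction
  `r`, resolved through `sd^2 = r/(1-r) * var(f(grid))` (sample variance).
* **Variable shifts**: the conventional families are linear ramps C1
  (0 to 4) and C2 (4 to 0) and quadratic profiles C3 (0-4-0) and C4
  (4-0-4); their amplitudes are a package convention and fully
  configurable.

`run_recovery()` repeats generation and estimation `R` times and reports
per-time-point mean, bias, RMSE and the empirical 5–95% band;
`compare_shift_models()` runs the linear-vs-quadratic nested F-test on the
mean recovered profile. The benchmark sizes used by the package's own
checks are `n = N = 20, M = 40` with `R = 200` replicates for the sine
benchmark, `R = 100` per coefficient combination for the constant-shift
polynomial grid, and `R = 200` per scenario for the variable-shift study —
large enough that Monte-Carlo error is well inside the reported tolerances.

What the generators emulate — spline-smooth mean trajectories, additive iid
Gaussian noise, identical noise levels in both groups, uniform sampling —
is deliberately simpler than real data, which carry heteroscedastic and
correlated noise, unequal group sizes and opportunistic age sampling.
Passing benchmarks therefore demonstrates correctness of the estimator
under its own model assumptions, not robustness to every real-data
pathology; the significance machinery, which resamples at the *observed*
ages with *gene-specific* noise, is the bridge to real data.

## Known limitations

* **Boundary bias.** The query's first and last points are always aligned,
  while reference columns can be dropped; near the domain ends the shift
  estimates are squeezed toward the feasible range. At high noise
  (r = 0.3) the mean estimate is biased positive at the start of the age
  range and negative at the end; `run_recovery()` reports, rather than
  hides, these edge effects, and `interior_mean()` summarises the central
  half of the grid for this reason.
* **Shape divergence.** Alignment presupposes that the two series traverse
  similar expression states. Genes whose trajectories differ in shape, not
  timing, should be removed first — `screen_genes()` implements the
  age-effect / group-effect / positive-correlation screen, with the
  correlation computed on spline trajectories over percentile-matched age
  grids because the groups' age ranges differ.
* **Flat trajectories.** Where the trajectory is flat the alignment is
  weakly constrained and pointwise nulls are wide; such points are
  legitimately non-significant even under large true shifts.
* **Cluster count.** `cluster_shift_profiles()` repeats k-means from
  k-means++ initialisations and reports the modal partition with its
  reproduction frequency as a stability score; `k` itself is the user's
  choice, with `silhouette_profile()` as a quick aid.
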