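#' Balanced, end-unanchored warping of two interpolated series
#'
#' Finds the minimum-cost monotone alignment of a query series `Y` (length
#' `N`) onto a reference series `X` (length `M >= N`) under the balanced
#' constraint: exactly `N` distinct reference columns are selected (so
#' `M - N` are omitted, possibly at the extremes -- the series ends are not
#' forced to align), every query point is aligned to at least one selected
#' column, and one point may map to several consecutive points in the other
#' series (multiple mapping). The cost is the sum of squared expression
#' differences over aligned pairs, which is argmin-equivalent to the
#' Euclidean distance.
#'
#' The dynamic program fills `O(M * N * (M - N))` states with constant work
#' per state. Ties are broken by preferring fewer aligned pairs, then by a
#' fixed deterministic traceback order.
#'
#' If `X` is shorter than `Y` the roles are swapped internally and the
#' returned path carries `orientation = "swapped"`.
#'
#' @param X reference [interpolate_uniform()] series (or any list with
#'   numeric `times` and `values`).
#' @param Y query series, same form.
#' @param multi_map `"both"` allows many query points to share one reference
#'   column as well as the converse; `"query-only"` forbids reusing a
#'   reference column for several query points, which under the balanced
#'   constraint reduces to a one-to-one match over the selected columns.
#' @return an object of class `alignment_path`: `pairs` (two-column integer
#'   matrix of (query index i, reference index j)), `omitted` (reference
#'   columns not aligned), `cost`, `n_pairs`, `M`, `N`, `orientation`.
#' @seealso [brute_force_align()] for the exhaustive reference
#'   implementation, [shifts_from_path()] to convert a path to time shifts.
#' @examples
#' X <- list(times = 1:4, values = c(0, 5, 1, 2))
#' Y <- list(times = 1:2, values = c(1, 2))
#' align(X, Y)$omitted   # columns 1 and 2 are dropped, cost 0
#' @export
align <- function(X, Y, multi_map = c("both", "query-only")) {
  multi_map <- match.arg(multi_map)
  xv <- as.numeric(X$values); yv <- as.numeric(Y$values)
  orientation <- "as-given"
  if (length(xv) < length(yv)) {
    tmp <- X; X <- Y; Y <- tmp
    xv <- as.numeric(X$values); yv <- as.numeric(Y$values)
    orientation <- "swapped"
  }
  if (length(yv) < 2L) stop("query series must have at least 2 points")
  if (anyNA(xv) || anyNA(yv) || any(!is.finite(c(xv, yv))))
    stop("non-finite expression values cannot be aligned")
  res <- .dtws_core(xv, yv, multi_map == "both")
  path <- structure(
    list(pairs = res$pairs, omitted = as.integer(res$omitted),
         cost = res$cost, n_pairs = res$n_pairs,
         M = length(xv), N = length(yv),
         orientation = orientation, multi_map = multi_map,
         cells = res$cells),
    class = "alignment_path")
  .validate_path(path, xv, yv)
  path
}

# invariant audit run on every alignment the package produces
.validate_path <- function(path, xv, yv) {
  p <- path$pairs
  M <- path$M; N <- path$N
  ok <- nrow(p) >= 1 &&
    all(diff(p[, 1]) >= 0) && all(diff(p[, 2]) >= 0) &&
    identical(sort(unique(p[, 1])), 1:N) &&
    length(unique(p[, 2])) == N &&
    length(path$omitted) == M - N &&
    !any(path$omitted %in% p[, 2]) &&
    path$cost >= 0
  if (!ok) stop("internal error: alignment violates the balanced-path invariants")
  recomputed <- sum((xv[p[, 2]] - yv[p[, 1]])^2)
  if (abs(recomputed - path$cost) > 1e-8 * (1 + abs(path$cost)))
    stop("internal error: alignment cost does not match its path")
  invisible(TRUE)
}

#' @export
print.alignment_path <- function(x, ...) {
  cat(sprintf(
    "balanced alignment: N = %d query points onto M = %d reference columns\n",
    x$N, x$M))
  cat(sprintf("  cost %.6g over %d pairs; %d columns omitted%s\n",
              x$cost, x$n_pairs, length(x$omitted),
              if (x$orientation == "swapped") " (roles swapped)" else ""))
  invisible(x)
}

#' Exhaustive balanced alignment (validation oracle)
#'
#' Enumerates every subset of `N` reference columns and every monotone
#' multiple-mapping staircase over the resulting `N x N` grid, and returns
#' the global minimum-cost balanced alignment. Intended as an independent
#' correctness oracle for [align()] on small instances; it shares no code
#' with the dynamic program.
#'
#' @inheritParams align
#' @return an `alignment_path` (see [align()]).
#' @export
brute_force_align <- function(X, Y, multi_map = c("both", "query-only")) {
  multi_map <- match.arg(multi_map)
  xv <- as.numeric(X$values); yv <- as.numeric(Y$values)
  M <- length(xv); N <- length(yv)
  if (M < N) stop("reference must be at least as long as the query")
  if (M > 12 || N > 6) stop("instance too large for exhaustive enumeration")
  if (N < 2) stop("query series must have at least 2 points")
  paths <- .enum_staircases(N, allow_column_reuse = multi_map == "both")
  subsets <- combn(M, N)
  best <- Inf; best_np <- Inf; best_path <- NULL; best_cols <- NULL
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    for (p in paths) {
      cost <- sum((xv[cols[p[, 2]]] - yv[p[, 1]])^2)
      np <- nrow(p)
      if (cost < best - 1e-12 ||
          (cost <= best + 1e-12 && np < best_np)) {
        best <- cost; best_np <- np; best_path <- p; best_cols <- cols
      }
    }
  }
  pairs <- cbind(best_path[, 1], best_cols[best_path[, 2]])
  path <- structure(
    list(pairs = pairs, omitted = setdiff(1:M, best_cols),
         cost = best, n_pairs = best_np, M = M, N = N,
         orientation = "as-given", multi_map = multi_map, cells = NA_real_),
    class = "alignment_path")
  .validate_path(path, xv, yv)
  path
}

# all monotone staircases on an N x N grid from (1,1) to (N,N); rows are
# query points, columns are the selected reference columns (in order).
# Steps: diagonal (new match), right (query point spans another column),
# down (column reused by the next query point; disabled for one-to-one).
.enum_staircases <- function(N, allow_column_reuse = TRUE) {
  out <- list()
  rec <- function(path, r, c) {
    if (r == N && c == N) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    if (r < N && c < N) rec(rbind(path, c(r + 1L, c + 1L)), r + 1L, c + 1L)
    if (c < N) rec(rbind(path, c(r, c + 1L)), r, c + 1L)
    if (allow_column_reuse && r < N) rec(rbind(path, c(r + 1L, c)), r + 1L, c)
  }
  rec(matrix(c(1L, 1L), 1L), 1L, 1L)
  out
}

#' Convert an alignment path to per-point time shifts
#'
#' For every query point the time shift is the mean time of its aligned
#' reference point(s) minus its own time:
#' `shift(Y_i) = mean(time(X_j), ..., time(X_j+q)) - time(Y_i)`.
#'
#' When both time axes are strictly positive chronological ages a reporting
#' shift `log2(aligned reference age / query age)` is also computed. Under
#' this convention a positive value means the reference group reaches the
#' query's expression state at an older age, i.e. the reference trajectory
#' is delayed (neotenic) relative to the query.
#'
#' @param path an [align()] result (orientation `"as-given"`).
#' @param X,Y the series that produced `path`.
#' @param gene_id identifier to attach.
#' @return an object of class `shift_profile`: `query_times`, `shifts`,
#'   `reporting_shifts` (or `NULL`), `cost`, `gene_id`, `N`.
#' @examples
#' X <- list(times = c(4, 6), values = c(1, 1))
#' Y <- list(times = c(3, 9), values = c(1, 1))
#' # both reference points align pairwise; shift of first query point uses
#' # the mean aligned time
#' @export
shifts_from_path <- function(path, X, Y, gene_id = "gene") {
  stopifnot(inherits(path, "alignment_path"))
  if (path$orientation == "swapped") {
    tmp <- X; X <- Y; Y <- tmp
  }
  tx <- as.numeric(X$times); ty <- as.numeric(Y$times)
  if (length(tx) != path$M || length(ty) != path$N)
    stop("path does not match the supplied series")
  p <- path$pairs
  mean_ref <- vapply(seq_len(path$N),
                     function(i) mean(tx[p[p[, 1] == i, 2]]), numeric(1))
  shifts <- mean_ref - ty
  reporting <- NULL
  if (all(tx > 0) && all(ty > 0)) reporting <- log2(mean_ref / ty)
  prof <- structure(
    list(query_times = ty, shifts = shifts, reporting_shifts = reporting,
         aligned_reference_times = mean_ref,
         cost = path$cost, gene_id = gene_id, N = path$N,
         orientation = path$orientation),
    class = "shift_profile")
  if (path$orientation == "swapped") prof <- .swap_profile(prof)
  prof
}

# a swapped-orientation profile describes the reference's points; negate and
# keep the convention "shift of the series the caller designated as query"
.swap_profile <- function(prof) {
  prof$shifts <- -prof$shifts
  if (!is.null(prof$reporting_shifts))
    prof$reporting_shifts <- -prof$reporting_shifts
  prof
}

#' @export
print.shift_profile <- function(x, ...) {
  cat(sprintf("shift profile: gene %s, %d query points, mean shift %.4g\n",
              x$gene_id, x$N, mean(x$shifts)))
  invisible(x)
}

#' @export
as.data.frame.shift_profile <- function(x, ...) {
  data.frame(gene_id = x$gene_id, query_time = x$query_times,
             shift = x$shifts,
             reporting_shift = if (is.null(x$reporting_shifts)) NA_real_
                               else x$reporting_shifts,
             cost = x$cost)
}

#' One-call facade: fit, interpolate, align and estimate shifts
#'
#' Composes [fit_spline()], [interpolate_uniform()], [align()] and
#' [shifts_from_path()] for a pair of raw series. `direction` selects which
#' series plays the query (the one whose per-point shifts are reported).
#'
#' @param seriesA,seriesB [raw_series()] objects.
#' @param K_A,K_B interpolation grid sizes for A and B.
#' @param direction `"B_to_A"` aligns B (query) onto A (reference);
#'   `"A_to_B"` the converse.
#' @param df spline smoothing, as in [fit_spline()].
#' @param multi_map see [align()].
#' @return a `shift_profile` for the query series.
#' @export
align_and_shift <- function(seriesA, seriesB, K_A = 40, K_B = 20,
                            direction = c("B_to_A", "A_to_B"), df = "gcv",
                            multi_map = "both") {
  direction <- match.arg(direction)
  fitA <- fit_spline(seriesA, df = df)
  fitB <- fit_spline(seriesB, df = df)
  A <- interpolate_uniform(fitA, K_A)
  B <- interpolate_uniform(fitB, K_B)
  if (direction == "B_to_A") {
    path <- align(A, B, multi_map = multi_map)
    shifts_from_path(path, A, B, gene_id = seriesA$gene_id)
  } else {
    path <- align(B, A, multi_map = multi_map)
    shifts_from_path(path, B, A, gene_id = seriesA$gene_id)
  }
}
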