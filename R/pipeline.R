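#' Screen genes for alignable cross-group expression change
#'
#' Applies the three-part screen used before time-shift estimation. A gene
#' passes when (1) expression changes significantly with age (F-test of a
#' polynomial age regression against the intercept-only model), (2) the two
#' groups differ in expression level (F-test of the group main effect on top
#' of the shared age polynomial -- an analysis of covariance), and (3) the
#' two groups' smoothed trajectories are significantly *positively*
#' correlated (Pearson `p < alpha` and `r > 0`); trajectories with opposite
#' shapes reflect more than a timing change and are not alignable.
#'
#' The polynomial degree is chosen per gene by forward selection: terms up
#' to `poly_degree` are added while the incremental F-test is significant at
#' `alpha`. Trajectory correlation is computed on spline interpolations over
#' percentile-matched grids (the same relative position within each group's
#' own age range), since the groups' age ranges may differ.
#'
#' @param expr genes x samples numeric matrix (log2 expression), rownames =
#'   gene ids.
#' @param meta data.frame with columns `sample`, `group`, `age` matching the
#'   columns of `expr`.
#' @param groups length-2 character: the two group labels to compare.
#' @param alpha significance level for all three criteria.
#' @param poly_degree maximum polynomial degree (default 3).
#' @param K grid size for the trajectory correlation.
#' @param df spline smoothing for the correlation trajectories.
#' @return a data.frame with one row per gene: `gene_id`, `age_F_p`,
#'   `species_ancova_p`, `pearson_r`, `pearson_p`, `passed`. Degenerate
#'   per-gene fits are recorded as failed, not raised.
#' @export
screen_genes <- function(expr, meta, groups = unique(meta$group),
                         alpha = 0.05, poly_degree = 3, K = 20, df = 4) {
  stopifnot(length(groups) == 2, all(groups %in% meta$group))
  meta <- meta[meta$group %in% groups, , drop = FALSE]
  expr <- expr[, match(meta$sample, colnames(expr)), drop = FALSE]
  res <- lapply(rownames(expr), function(g) {
    out <- data.frame(gene_id = g, age_F_p = NA_real_,
                      species_ancova_p = NA_real_, pearson_r = NA_real_,
                      pearson_p = NA_real_, passed = FALSE,
                      stringsAsFactors = FALSE)
    tryCatch({
      d <- data.frame(value = as.numeric(expr[g, ]), age = meta$age,
                      group = factor(meta$group, levels = groups))
      deg_max <- min(poly_degree, length(unique(d$age)) - 1)
      # forward selection of the polynomial degree
      deg <- 1
      fit <- lm(value ~ poly(age, 1), data = d)
      while (deg < deg_max) {
        fit2 <- lm(value ~ poly(age, deg + 1), data = d)
        if (anova(fit, fit2)$`Pr(>F)`[2] < alpha) {
          deg <- deg + 1; fit <- fit2
        } else break
      }
      fstat <- summary(fit)$fstatistic
      out$age_F_p <- pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
      # ANCOVA: group main effect on top of the shared age polynomial
      fit_g <- lm(value ~ poly(age, deg) + group, data = d)
      out$species_ancova_p <- anova(fit, fit_g)$`Pr(>F)`[2]
      # trajectory correlation on percentile-matched grids
      probs <- seq(0, 1, length.out = K)
      traj <- lapply(groups, function(gr) {
        dg <- d[d$group == gr, ]
        f <- fit_spline(raw_series(dg$age, dg$value, g, gr),
                        df = min(df, length(unique(dg$age)) - 1))
        predict(f, min(dg$age) + probs * diff(range(dg$age)))
      })
      ct <- cor.test(traj[[1]], traj[[2]])
      out$pearson_r <- unname(ct$estimate)
      out$pearson_p <- ct$p.value
      out$passed <- out$age_F_p < alpha && out$species_ancova_p < alpha &&
        out$pearson_p < alpha && out$pearson_r > 0
      out
    }, error = function(e) out)
  })
  do.call(rbind, res)
}

#' Classify the direction of heterochrony from a shift profile
#'
#' Takes the majority sign of the per-point shifts. If at least
#' `min_consistency` of all time points share that sign the gene is called
#' `"delayed"` (majority positive: the reference trajectory is delayed /
#' neotenic relative to the query) or `"accelerated"` (majority negative);
#' otherwise `"none"`. Zero shifts count against consistency.
#'
#' @param profile a `shift_profile`, `dtws` fit, or numeric vector of
#'   shifts.
#' @param min_consistency required fraction of consistent signs (default
#'   0.7).
#' @return a list: `gene_id`, `direction`, `consistency`.
#' @export
classify_direction <- function(profile, min_consistency = 0.7) {
  gene_id <- "gene"
  if (inherits(profile, "dtws")) profile <- profile$shift
  if (inherits(profile, "shift_profile")) {
    gene_id <- profile$gene_id
    s <- profile$shifts
  } else s <- as.numeric(profile)
  if (length(s) < 3) stop("profile must have at least 3 points")
  npos <- sum(s > 0); nneg <- sum(s < 0)
  if (npos == 0 && nneg == 0)
    return(list(gene_id = gene_id, direction = "none", consistency = 0))
  maj <- if (npos >= nneg) npos else nneg
  consistency <- maj / length(s)
  direction <- if (consistency < min_consistency) "none"
               else if (npos >= nneg) "delayed" else "accelerated"
  list(gene_id = gene_id, direction = direction, consistency = consistency)
}

#' Cluster time-shift profiles with stability assessment
#'
#' Runs k-means with `runs` random restarts, records each run's partition up
#' to label permutation, and reports the modal partition together with its
#' frequency (`stability`). Genes with similar shift trajectories -- similar
#' timing and amplitude of heterochrony -- cluster together even when their
#' expression profiles differ.
#'
#' Each restart initialises its centers with the distance-weighted
#' (k-means++) scheme before running the standard k-means iteration, so that
#' well-separated profile groups are found reliably and the stability score
#' reflects the data rather than initialisation accidents.
#'
#' @param profiles genes x time-points numeric matrix of shifts, rownames =
#'   gene ids.
#' @param k number of clusters.
#' @param runs number of random restarts.
#' @param seed optional RNG seed.
#' @return an object of class `shift_clustering`: `assignments` (named
#'   integer vector, labels in order of first appearance), `k`, `stability`,
#'   `centers` (k x N modal-partition mean profiles), `band` (list of 2 x N
#'   5-95% matrices per cluster), `sizes`, `runs`.
#' @export
cluster_shift_profiles <- function(profiles, k, runs = 1000, seed = NULL) {
  profiles <- as.matrix(profiles)
  if (k > nrow(profiles)) stop("more clusters than profiles")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- sprintf("gene%03d", seq_len(nrow(profiles)))
  if (!is.null(seed)) set.seed(seed)
  signature <- function(cl) paste(match(cl, unique(cl)), collapse = ".")
  sigs <- character(runs)
  for (i in seq_len(runs)) {
    km <- NULL; tries <- 0
    while (is.null(km) && tries < 100) {
      tries <- tries + 1
      centers <- profiles[.kpp_centers(profiles, k), , drop = FALSE]
      km <- tryCatch(kmeans(profiles, centers = centers),
                     error = function(e) NULL)
    }
    if (is.null(km)) stop("k-means failed repeatedly")
    sigs[i] <- signature(km$cluster)
  }
  tab <- sort(table(sigs), decreasing = TRUE)
  modal <- names(tab)[1]
  assignments <- as.integer(strsplit(modal, ".", fixed = TRUE)[[1]])
  names(assignments) <- rownames(profiles)
  centers <- t(vapply(seq_len(k), function(cl)
    colMeans(profiles[assignments == cl, , drop = FALSE]),
    numeric(ncol(profiles))))
  band <- lapply(seq_len(k), function(cl)
    apply(profiles[assignments == cl, , drop = FALSE], 2, quantile,
          probs = c(0.05, 0.95)))
  structure(
    list(assignments = assignments, k = k,
         stability = unname(tab[1]) / runs, centers = centers, band = band,
         sizes = tabulate(assignments, k), runs = runs),
    class = "shift_clustering")
}

# distance-weighted (k-means++) seeding: each further center is drawn with
# probability proportional to the squared distance to the nearest chosen one
.kpp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) {
      idx[j] <- sample(setdiff(seq_len(n), idx[seq_len(j - 1)]), 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  idx
}

#' @export
print.shift_clustering <- function(x, ...) {
  cat(sprintf(
    "shift-profile clustering: k = %d, sizes %s, stability %.3f (%d/%d runs)\n",
    x$k, paste(x$sizes, collapse = "/"), x$stability,
    round(x$stability * x$runs), x$runs))
  invisible(x)
}

#' Silhouette-style support for a range of cluster numbers
#'
#' Mean silhouette width (Euclidean) for `k = 2..k_max`, a quick aid for
#' choosing `k`; the choice remains the user's.
#'
#' @inheritParams cluster_shift_profiles
#' @param k_max largest `k` to evaluate.
#' @return named numeric vector of mean silhouette widths.
#' @export
silhouette_profile <- function(profiles, k_max = 6, runs = 25,
                               seed = NULL) {
  profiles <- as.matrix(profiles)
  if (!is.null(seed)) set.seed(seed)
  dmat <- as.matrix(dist(profiles))
  out <- setNames(numeric(k_max - 1), 2:k_max)
  for (k in 2:min(k_max, nrow(profiles) - 1)) {
    cl <- cluster_shift_profiles(profiles, k, runs = runs)$assignments
    sil <- vapply(seq_len(nrow(profiles)), function(i) {
      a <- mean(dmat[i, cl == cl[i] & seq_along(cl) != i])
      if (!is.finite(a)) a <- 0
      b <- min(vapply(setdiff(seq_len(k), cl[i]), function(oc)
        mean(dmat[i, cl == oc]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    out[as.character(k)] <- mean(sil)
  }
  out
}

#' Genes with correlated shift profiles in two tissues
#'
#' Per gene, the Pearson correlation between its time-shift profiles in two
#' tissue datasets; genes with `p < alpha` and `r > r_min` are selected as
#' showing synchronized heterochrony across tissues.
#'
#' @param profilesA,profilesB genes x time-points matrices with matching
#'   rownames (genes present in both are used).
#' @param r_min minimum correlation (default 0.5).
#' @param alpha significance level.
#' @return a list: `table` (gene_id, r, p, selected) and `selected`
#'   (character vector of gene ids). Constant profiles are excluded with a
#'   warning.
#' @export
correlate_profiles_across_regions <- function(profilesA, profilesB,
                                              r_min = 0.5, alpha = 0.05) {
  genes <- intersect(rownames(profilesA), rownames(profilesB))
  if (!length(genes)) stop("no shared genes between the two profile sets")
  rows <- lapply(genes, function(g) {
    a <- profilesA[g, ]; b <- profilesB[g, ]
    if (sd(a) == 0 || sd(b) == 0) {
      warning(sprintf("gene %s has a constant profile; excluded", g))
      return(NULL)
    }
    ct <- cor.test(a, b)
    data.frame(gene_id = g, r = unname(ct$estimate), p = ct$p.value,
               selected = ct$p.value < alpha && ct$estimate > r_min,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, selected = tab$gene_id[tab$selected])
}
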