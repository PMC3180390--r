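#' Read an expression matrix and sample metadata
#'
#' Reads a genes x samples expression table (TSV or CSV by extension; first
#' column or row names = gene ids, header = sample ids) and a metadata table
#' with columns `sample`, `group`, `age`. Both must be UTF-8 with `.` as the
#' decimal point. Samples are matched by id; unmatched samples are an error.
#'
#' @param expr_file path to the expression table.
#' @param meta_file path to the metadata table.
#' @return `list(expr, meta)` with `expr` a numeric matrix and `meta` a
#'   data.frame.
#' @export
read_expression_set <- function(expr_file, meta_file) {
  rd <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  e <- rd(expr_file)
  if (!is.numeric(e[[1]])) {
    rownames(e) <- e[[1]]
    e <- e[, -1, drop = FALSE]
  }
  expr <- as.matrix(e)
  storage.mode(expr) <- "double"
  meta <- rd(meta_file)
  need <- c("sample", "group", "age")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: sample, group, age")
  meta$age <- as.numeric(meta$age)
  if (anyNA(meta$age)) stop("non-numeric ages in metadata")
  missing <- setdiff(meta$sample, colnames(expr))
  if (length(missing))
    stop("samples in metadata but not in the expression table: ",
         paste(missing, collapse = ", "))
  expr <- expr[, meta$sample, drop = FALSE]
  if (anyNA(expr)) stop("missing expression values are not supported")
  list(expr = expr, meta = meta)
}

#' Split a dataset into per-gene query/reference series pairs
#'
#' @param expr genes x samples numeric matrix.
#' @param meta metadata data.frame (`sample`, `group`, `age`).
#' @param query_group,reference_group group labels.
#' @param age_offset if non-zero, ages are mapped to
#'   `log2(age + age_offset)` via [transform_ages()] before analysis (the
#'   offset is typically the gestation length), and all downstream shifts
#'   are on that transformed scale.
#' @return named list (by gene) of `list(query, reference)` of
#'   [raw_series()].
#' @export
as_gene_pairs <- function(expr, meta, query_group, reference_group,
                          age_offset = 0) {
  stopifnot(query_group %in% meta$group, reference_group %in% meta$group)
  ages <- meta$age
  if (age_offset > 0) ages <- transform_ages(ages, age_offset)
  iq <- meta$group == query_group
  ir <- meta$group == reference_group
  out <- lapply(rownames(expr), function(g) {
    list(query = raw_series(ages[iq], expr[g, meta$sample[iq]], g,
                            query_group),
         reference = raw_series(ages[ir], expr[g, meta$sample[ir]], g,
                                reference_group))
  })
  names(out) <- rownames(expr)
  out
}

#' Screen, align, test and classify a two-group expression dataset
#'
#' The application-layer driver: screens genes ([screen_genes()]), estimates
#' every passing gene's shift profile with [dtws()], runs the Monte-Carlo
#' significance scheme with FPR calibration ([calibrate_fpr()]), classifies
#' the direction of heterochrony ([classify_direction()]) and clusters the
#' significant genes' shift profiles ([cluster_shift_profiles()]). Fully
#' reproducible for a given master seed.
#'
#' @inheritParams as_gene_pairs
#' @param K_query,K_reference interpolation grid sizes.
#' @param df spline smoothing for real data (default 4).
#' @param B,G,alpha,target_fpr significance parameters, see
#'   [calibrate_fpr()].
#' @param min_consistency see [classify_direction()].
#' @param k_clusters clusters for the shift profiles of significant genes
#'   (skipped when fewer than `k_clusters` genes are significant).
#' @param cluster_runs k-means restarts.
#' @param screen_alpha screening level.
#' @param seed master seed for all randomness.
#' @param out_dir if given, the result tables are also written there as TSV
#'   (`screen.tsv`, `shifts.tsv`, `significance.tsv`, `calls.tsv`,
#'   `clusters.tsv`).
#' @return a list: `screen`, `shifts` (long table: gene_id, query_time,
#'   shift, reporting_shift, cost), `significance` (per-gene table plus
#'   `threshold_c`, `fpr_at_c` attributes), `calls` (gene_id, direction,
#'   consistency, cluster), `clustering` (a `shift_clustering` or `NULL`),
#'   `sig_set` (the full `dtws_sig_set`).
#' @export
run_heterochrony_pipeline <- function(expr, meta, query_group,
                                      reference_group, K_query = 20,
                                      K_reference = 40, df = 4, B = 1000,
                                      G = 50, alpha = 0.05,
                                      target_fpr = 0.10,
                                      min_consistency = 0.7, k_clusters = 3,
                                      cluster_runs = 1000,
                                      screen_alpha = 0.05, age_offset = 0,
                                      seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  screen <- screen_genes(expr, meta, c(reference_group, query_group),
                         alpha = screen_alpha)
  keep <- screen$gene_id[screen$passed]
  if (!length(keep)) stop("no genes pass the screen")
  pairs <- as_gene_pairs(expr[keep, , drop = FALSE], meta, query_group,
                         reference_group, age_offset = age_offset)
  fits <- lapply(pairs, function(p)
    dtws(p$query, p$reference, K_query = K_query,
         K_reference = K_reference, df = df, gene_id = p$query$gene_id))
  shifts <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(f$shift)))
  rownames(shifts) <- NULL
  sig <- calibrate_fpr(pairs, B = B, G = G, alpha = alpha,
                       target_fpr = target_fpr, K_query = K_query,
                       K_reference = K_reference, df_est = df, df_null = df)
  calls <- do.call(rbind, lapply(fits, function(f) {
    dc <- classify_direction(f, min_consistency = min_consistency)
    data.frame(gene_id = dc$gene_id, direction = dc$direction,
               consistency = dc$consistency, stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  sig_genes <- sig$table$gene_id[sig$table$gene_significant %in% TRUE]
  clustering <- NULL
  calls$cluster <- NA_integer_
  if (length(sig_genes) >= k_clusters && k_clusters >= 1) {
    prof <- t(vapply(fits[sig_genes], function(f) f$shift$shifts,
                     numeric(K_query)))
    rownames(prof) <- sig_genes
    clustering <- cluster_shift_profiles(prof, k = k_clusters,
                                         runs = cluster_runs)
    calls$cluster <- clustering$assignments[match(calls$gene_id,
                                                  names(clustering$assignments))]
  }
  out <- list(screen = screen, shifts = shifts,
              significance = sig$table, calls = calls,
              clustering = clustering, sig_set = sig)
  attr(out$significance, "threshold_c") <- sig$threshold_c
  attr(out$significance, "fpr_at_c") <- sig$fpr_at_c
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f)
      write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    wt(out$screen, "screen.tsv")
    wt(out$shifts, "shifts.tsv")
    wt(out$significance, "significance.tsv")
    wt(out$calls, "calls.tsv")
    if (!is.null(clustering))
      wt(data.frame(gene_id = names(clustering$assignments),
                    cluster = clustering$assignments), "clusters.tsv")
  }
  out
}
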