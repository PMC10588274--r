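#' Two-sample Kolmogorov-Smirnov distance
#'
#' The sup-norm distance between the empirical CDFs of two value vectors,
#' used throughout the evaluation framework to compare metric distributions
#' across platforms, cell types and subsamples. `NA` values (unevaluated
#' genes) are dropped first.
#'
#' @param x,y Numeric vectors, non-empty after dropping `NA`.
#' @return The KS D statistic in \[0, 1\].
#' @export
ks_distance <- function(x, y) {
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  if (!length(x) || !length(y))
    stop("ks_distance needs non-empty finite vectors")
  grid <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  max(abs(fx - fy))
}

#' Platform-versus-cell-type robustness
#'
#' For each metric, contrasts the KS distance between sequencing platforms
#' within a cell type against the distance between cell types within a
#' platform. A robust metric shows a much smaller platform distance than
#' cell-type distance, i.e. a small `ratio`.
#'
#' @param results A data.frame with columns `metric`, `cell_type`,
#'   `platform`, `value` (one row per evaluated gene per stratum).
#' @return A data.frame per metric with mean cross-platform distance
#'   (`d_platform`), mean cross-cell-type distance (`d_celltype`) and their
#'   `ratio` (platform/cell-type; 0 when both are 0).
#' @export
platform_effect <- function(results) {
  need <- c("metric", "cell_type", "platform", "value")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "))
  cts <- unique(results$cell_type)
  pls <- unique(results$platform)
  if (length(cts) < 2 || length(pls) < 2)
    stop("need at least 2 cell types and 2 platforms; got ",
         length(cts), " cell type(s), ", length(pls), " platform(s)")
  for (ct in cts) for (pl in pls) {
    if (!any(results$cell_type == ct & results$platform == pl))
      stop("missing stratum: cell_type=", ct, ", platform=", pl)
  }
  out <- lapply(unique(results$metric), function(m) {
    sub <- results[results$metric == m, ]
    vals <- function(ct, pl) sub$value[sub$cell_type == ct & sub$platform == pl]
    d_plat <- c()
    for (ct in cts) {
      pp <- utils::combn(pls, 2)
      for (k in seq_len(ncol(pp)))
        d_plat <- c(d_plat, ks_distance(vals(ct, pp[1, k]), vals(ct, pp[2, k])))
    }
    d_ct <- c()
    for (pl in pls) {
      cc <- utils::combn(cts, 2)
      for (k in seq_len(ncol(cc)))
        d_ct <- c(d_ct, ks_distance(vals(cc[1, k], pl), vals(cc[2, k], pl)))
    }
    dp <- mean(d_plat); dc <- mean(d_ct)
    ratio <- if (dp == 0 && dc == 0) 0 else if (dc == 0) Inf else dp / dc
    data.frame(metric = m, d_platform = dp, d_celltype = dc, ratio = ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Association between a metric and a data-structure feature
#'
#' Pearson correlation between a metric's values and a per-gene feature
#' (zero proportion, mean expression, gene length, ...) over jointly
#' evaluated genes. The score is `1 - |r|`, so 1 means the metric is free
#' of that structural dependency ("1 indicates perfect performance").
#'
#' @param result A `VariabilityResult`.
#' @param feature Per-gene numeric vector aligned with the result.
#' @param log_feature If `TRUE`, the feature is transformed as
#'   `log10(feature + 1)` first (conventional for mean expression and gene
#'   length).
#' @return A list with elements `r` (Pearson correlation) and `score`
#'   (`1 - |r|`).
#' @export
feature_association <- function(result, feature, log_feature = FALSE) {
  stopifnot(inherits(result, "VariabilityResult"),
            length(feature) == length(result$values))
  if (log_feature) feature <- log10(feature + 1)
  ok <- result$evaluated & is.finite(feature)
  if (sum(ok) < 3) stop("need at least 3 jointly evaluated genes")
  x <- result$values[ok]; y <- feature[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in metric values or feature")
  r <- stats::cor(x, y, method = "pearson")
  list(r = r, score = 1 - abs(r))
}

#' Gene-set rediscovery in the low-variability quartile
#'
#' Fraction of a stable gene set (ribosomal genes, stably expressed genes)
#' whose metric value falls at or below the first quartile of all evaluated
#' values -- the rate at which a metric rediscovers genes expected to be
#' lowly variable.
#'
#' @param result A `VariabilityResult` with >= 4 evaluated genes and named
#'   values (gene ids).
#' @param geneset Character vector of gene identifiers.
#' @return Proportion in \[0, 1\].
#' @export
geneset_rediscovery <- function(result, geneset) {
  stopifnot(inherits(result, "VariabilityResult"))
  ids <- names(result$values)
  if (is.null(ids)) stop("result values must be named by gene id")
  vals <- result$values[result$evaluated]
  if (length(vals) < 4) stop("need at least 4 evaluated genes")
  members <- intersect(geneset, names(vals))
  if (!length(members)) stop("no gene-set member among evaluated genes")
  q1 <- stats::quantile(vals, 0.25, type = 7, names = FALSE)
  mean(vals[members] <= q1)
}

#' Ground-truth HVG rediscovery
#'
#' Fraction of the simulator's flagged highly variable genes that a metric
#' ranks within its top k values, with k equal to the number of true HVGs.
#' Ties are broken by gene order (first gene wins), which is documented
#' rather than randomized so runs are reproducible.
#'
#' @param result A `VariabilityResult` computed on simulated counts.
#' @param truth The matching `SimTruth`.
#' @return Proportion in \[0, 1\].
#' @export
hvg_rediscovery <- function(result, truth) {
  stopifnot(inherits(result, "VariabilityResult"), inherits(truth, "SimTruth"),
            length(truth$hvg_flags) == length(result$values))
  k <- sum(truth$hvg_flags)
  if (k == 0) stop("truth flags no HVGs")
  if (!any(truth$hvg_flags & result$evaluated))
    stop("no true HVG evaluated by the metric")
  vals <- result$values
  vals[!result$evaluated] <- -Inf
  top <- order(vals, decreasing = TRUE)[seq_len(k)]
  sum(truth$hvg_flags[top]) / k
}

#' Subsampling stability of a metric
#'
#' Repeatedly subsamples cells without replacement at each fraction,
#' recomputes the metric, and reports the KS distance between the
#' subsampled and full-data metric distributions over jointly evaluated
#' genes. Distances shrink toward 0 as the fraction approaches 1.
#'
#' @param counts A `CountMatrix`.
#' @param metric Function `CountMatrix -> VariabilityResult`.
#' @param fractions Cell fractions to draw (default
#'   `c(0.1, 0.2, 0.5, 0.8, 0.9)`).
#' @param reps Replicates per fraction (default 5).
#' @param seed Integer seed governing all draws.
#' @return A data.frame with columns `fraction`, `replicate`, `metric_name`,
#'   `ks_to_full`.
#' @export
subsample_stability <- function(counts, metric,
                                fractions = c(0.1, 0.2, 0.5, 0.8, 0.9),
                                reps = 5, seed = 1L) {
  stopifnot(inherits(counts, "CountMatrix"), is.function(metric))
  n <- ncol(counts$counts)
  sizes <- floor(fractions * n)
  if (any(sizes < 10))
    stop("fraction ", fractions[which(sizes < 10)[1]],
         " yields fewer than 10 cells")
  full <- metric(counts)
  set.seed(seed)
  rows <- list()
  for (f in seq_along(fractions)) {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, sizes[f]))
      sub <- metric(counts[, idx])
      joint <- full$evaluated & sub$evaluated
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = fractions[f], replicate = r,
        metric_name = full$metric_name,
        ks_to_full = ks_distance(full$values[joint], sub$values[joint]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Negative-control dispersion of a metric's distribution
#'
#' On a dataset with no biological variability, a good metric's values
#' should be tightly concentrated. To compare metrics with different native
#' scales, values are min-max scaled to \[0, 1\] and their interquartile
#' range reported; lower is better. Constant values give 0.
#'
#' @param result A `VariabilityResult` with >= 4 evaluated genes.
#' @return Scalar >= 0 (at most 1).
#' @export
negctrl_dispersion <- function(result) {
  stopifnot(inherits(result, "VariabilityResult"))
  vals <- result$values[result$evaluated]
  if (length(vals) < 4) stop("need at least 4 evaluated genes")
  rng <- range(vals)
  if (diff(rng) == 0) return(0)
  scaled <- (vals - rng[1]) / diff(rng)
  stats::IQR(scaled, type = 7)
}

#' Assemble an evaluation report
#'
#' Long-format table of per-metric, per-criterion scores: data-structure
#' criteria (`zero`, `mean`, `gene_length`) via [feature_association()],
#' stable-set criteria (`ribosomal`, `SEG`) via [geneset_rediscovery()],
#' and `hvg` via [hvg_rediscovery()]. The `mean` criterion uses each
#' metric's own input convention: the log-normalized mean for metrics that
#' consume normalized values, the raw mean for raw-count metrics.
#'
#' @param results Named list of `VariabilityResult` (e.g. from
#'   [run_all_metrics()]).
#' @param counts The `CountMatrix` the metrics were computed on.
#' @param annot Optional gene annotation data.frame with `length_bp` and/or
#'   logical `ribosomal` / `SEG` columns keyed by `gene_id`.
#' @param truth Optional `SimTruth` enabling the `hvg` criterion.
#' @param dataset_label Label recorded in every row.
#' @return An `EvaluationReport` data.frame with columns `metric_name`,
#'   `dataset_label`, `criterion`, `score`, `n_genes_evaluated`.
#' @export
aggregate_report <- function(results, counts, annot = NULL, truth = NULL,
                             dataset_label = "dataset") {
  stopifnot(inherits(counts, "CountMatrix"), length(results) >= 1)
  raw_sum <- gene_summaries(counts)
  logmean <- rowMeans(log_cpm_normalize(counts)$values)
  rows <- list()
  add <- function(metric, criterion, score, n_eval) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric_name = metric, dataset_label = dataset_label,
      criterion = criterion, score = score, n_genes_evaluated = n_eval,
      stringsAsFactors = FALSE)
  }
  for (m in names(results)) {
    res <- results[[m]]
    n_eval <- sum(res$evaluated)
    mean_feature <- if (identical(res$input_scheme, "raw")) raw_sum$mean else logmean
    try_score <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    add(m, "zero", try_score(feature_association(res, raw_sum$pct_zero)$score), n_eval)
    add(m, "mean", try_score(feature_association(res, mean_feature,
                                                 log_feature = identical(res$input_scheme, "raw"))$score),
        n_eval)
    if (!is.null(annot) && "length_bp" %in% names(annot)) {
      len <- annot$length_bp[match(counts$gene_ids, annot$gene_id)]
      add(m, "gene_length",
          try_score(feature_association(res, len, log_feature = TRUE)$score),
          n_eval)
    }
    for (set_col in c("ribosomal", "SEG")) {
      if (!is.null(annot) && set_col %in% names(annot)) {
        set_ids <- annot$gene_id[isTRUE_vec(annot[[set_col]])]
        add(m, set_col, try_score(geneset_rediscovery(res, set_ids)), n_eval)
      }
    }
    if (!is.null(truth))
      add(m, "hvg", try_score(hvg_rediscovery(res, truth)), n_eval)
  }
  report <- do.call(rbind, rows)
  class(report) <- c("EvaluationReport", class(report))
  report
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
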