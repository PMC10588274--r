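#' Differential-variability test between two conditions
#'
#' Given aligned per-gene cell-to-cell variability (CCV) estimates for an
#' old and a young condition, computes `delta = CCV(old) - CCV(young)`,
#' standardizes the deltas to z-scores, and converts them to two-sided
#' p-values under a normal assumption on the z-scores. Genes with
#' `p < alpha` are flagged significant, with direction given by the sign of
#' delta.
#'
#' @param ccv_old,ccv_young Aligned per-gene numeric vectors (same
#'   pre-filtered gene set); names are carried through when present.
#' @param alpha Significance level (default 0.05).
#' @param robust If `TRUE`, standardize with median/MAD instead of
#'   mean/sd (off by default; the moment-based form is the literal
#'   procedure).
#' @return A `DVResult` data.frame with columns `gene_id`, `delta`, `z`,
#'   `p`, `direction` (`more_variable_in_old`, `more_variable_in_young`, or
#'   `none`), `significant`.
#' @export
dv_test <- function(ccv_old, ccv_young, alpha = 0.05, robust = FALSE) {
  if (length(ccv_old) != length(ccv_young))
    stop("ccv_old and ccv_young must be aligned (same length)")
  ok <- is.finite(ccv_old) & is.finite(ccv_young)
  if (!all(ok)) stop("non-finite CCV values; filter genes first")
  delta <- ccv_old - ccv_young
  ctr <- if (robust) stats::median(delta) else mean(delta)
  scl <- if (robust) stats::mad(delta) else stats::sd(delta)
  if (!is.finite(scl) || scl == 0)
    stop("delta has no spread (constant differences); cannot standardize")
  z <- (delta - ctr) / scl
  p <- 2 * stats::pnorm(-abs(z))
  sig <- p < alpha
  dir <- ifelse(!sig, "none",
                ifelse(delta > 0, "more_variable_in_old",
                       "more_variable_in_young"))
  ids <- names(ccv_old)
  if (is.null(ids)) ids <- paste0("gene", seq_along(delta))
  out <- data.frame(gene_id = ids, delta = delta, z = z, p = p,
                    direction = dir, significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("DVResult", class(out))
  out
}

#' End-to-end differential-variability pipeline
#'
#' Pools the two conditions' cells to apply a detection filter (genes
#' expressed in more than `min_frac` of all cells), computes the chosen
#' variability metric per condition on the surviving genes, and runs
#' [dv_test()] on the genes both conditions evaluated.
#'
#' @param counts_old,counts_young `CountMatrix` objects sharing gene ids.
#' @param metric Function `CountMatrix -> VariabilityResult` (default:
#'   mean-variance trend decomposition of log-CPM values).
#' @param min_frac Detection fraction applied to the pooled cells
#'   (default 0.05).
#' @param alpha Significance level passed to [dv_test()].
#' @return A `DVResult`.
#' @export
dv_pipeline <- function(counts_old, counts_young,
                        metric = function(cm) trend_decompose(log_cpm_normalize(cm))$result,
                        min_frac = 0.05, alpha = 0.05) {
  stopifnot(inherits(counts_old, "CountMatrix"),
            inherits(counts_young, "CountMatrix"))
  if (!identical(counts_old$gene_ids, counts_young$gene_ids))
    stop("the two conditions must share the same gene ids in the same order")
  pooled <- CountMatrix(cbind(counts_old$counts, counts_young$counts),
                        counts_old$gene_ids,
                        c(paste0("old_", counts_old$cell_ids),
                          paste0("young_", counts_young$cell_ids)))
  keep <- detection_filter(pooled, min_frac)
  if (!any(keep)) stop("no gene survives the detection filter at min_frac = ",
                       min_frac)
  old_f <- counts_old[keep, seq_len(ncol(counts_old$counts))]
  young_f <- counts_young[keep, seq_len(ncol(counts_young$counts))]
  r_old <- metric(old_f)
  r_young <- metric(young_f)
  joint <- r_old$evaluated & r_young$evaluated
  if (!any(joint)) stop("no gene evaluated by the metric in both conditions")
  vo <- r_old$values[joint]
  vy <- r_young$values[joint]
  names(vo) <- names(vy) <- old_f$gene_ids[joint]
  tryCatch(dv_test(vo, vy, alpha = alpha),
           error = function(e) stop("dv_test failed on ", sum(joint),
                                    " genes: ", conditionMessage(e)))
}

#' Classify variability trends along an ordered lineage
#'
#' Labels each gene's variability path across ordered differentiation
#' stages: strictly increasing across every consecutive stage pair is
#' `consistently_variable`, strictly decreasing is `consistently_stable`,
#' anything else `none`. An optional minimum total change `tau` on
#' `|last - first|` filters out flat-but-monotone paths.
#'
#' @param paths Genes x stages numeric matrix (>= 3 ordered stages), rows
#'   named by gene id.
#' @param tau Minimum absolute total change required (default 0).
#' @return A `TrendClassification` data.frame with columns `gene_id`,
#'   `pattern`, and one column per stage.
#' @export
consistent_trend <- function(paths, tau = 0) {
  paths <- as.matrix(paths)
  if (ncol(paths) < 3)
    stop("need at least 3 ordered stages, got ", ncol(paths))
  if (any(!is.finite(paths))) stop("paths must be finite")
  diffs <- paths[, -1, drop = FALSE] - paths[, -ncol(paths), drop = FALSE]
  total <- abs(paths[, ncol(paths)] - paths[, 1])
  up <- apply(diffs > 0, 1, all) & total >= tau
  down <- apply(diffs < 0, 1, all) & total >= tau
  pattern <- ifelse(up, "consistently_variable",
                    ifelse(down, "consistently_stable", "none"))
  ids <- rownames(paths)
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(paths)))
  out <- data.frame(gene_id = ids, pattern = pattern,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(paths, row.names = NULL))
  class(out) <- c("TrendClassification", class(out))
  out
}

#' Hypergeometric gene-set overlap test
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between two gene sets drawn from a common universe -- the
#' standard test for whether, e.g., differentially variable genes found in
#' two datasets overlap more than chance.
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector, the background gene ids.
#' @return A list with `overlap` (count) and `p` (upper-tail probability
#'   `P(X >= overlap)`).
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("universe must be non-empty")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), length(universe) - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p = p)
}
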