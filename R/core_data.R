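#' Construct a CountMatrix
#'
#' The universal input container: a genes x cells matrix of non-negative
#' integer counts with unique gene and cell identifiers. Internally the
#' counts are held as a sparse [Matrix::dgCMatrix] so that droplet-scale
#' sparsity costs nothing.
#'
#' @param counts A genes x cells matrix or sparse Matrix of non-negative
#'   integer counts.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#'   Defaults to `rownames(counts)`.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column. Defaults to `colnames(counts)`.
#' @return An object of class `CountMatrix`.
#' @examples
#' m <- matrix(rpois(12, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- CountMatrix(m)
#' dim(cm)
#' @export
CountMatrix <- function(counts, gene_ids = rownames(counts),
                        cell_ids = colnames(counts)) {
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("length(gene_ids) must equal nrow(counts)")
  if (length(cell_ids) != ncol(counts))
    stop("length(cell_ids) must equal ncol(counts)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids: ", paste(unique(gene_ids[duplicated(gene_ids)])[1:min(3, sum(duplicated(gene_ids)))], collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids: ", paste(unique(cell_ids[duplicated(cell_ids)])[1:min(3, sum(duplicated(cell_ids)))], collapse = ", "))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  vals <- counts@x
  if (length(vals)) {
    if (any(!is.finite(vals))) stop("counts contain non-finite values")
    if (any(vals < 0)) stop("counts contain negative values")
    if (any(vals != round(vals)))
      stop("counts contain non-integer values; first offender: ",
           vals[which(vals != round(vals))[1]])
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      format(100 * Matrix::nnzero(x$counts) / prod(dim(x$counts)), digits = 3),
      "% non-zero\n")
  invisible(x)
}

#' Subset a CountMatrix by gene and/or cell
#'
#' @param x A `CountMatrix`.
#' @param i,j Gene and cell indices (integer, logical, or character).
#' @param ... Ignored.
#' @param drop Ignored; a `CountMatrix` is always returned.
#' @return A `CountMatrix` restricted to the selected genes and cells.
#' @export
`[.CountMatrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  sub <- x$counts[i, j, drop = FALSE]
  CountMatrix(sub, rownames(sub), colnames(sub))
}

#' Per-cell library sizes
#'
#' @param counts A `CountMatrix`.
#' @return Named numeric vector of per-cell total counts.
#' @export
library_sizes <- function(counts) {
  stopifnot(inherits(counts, "CountMatrix"))
  ls <- Matrix::colSums(counts$counts)
  names(ls) <- counts$cell_ids
  ls
}

new_normalized_matrix <- function(values, scheme, gene_ids, cell_ids) {
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, scheme = scheme,
                 gene_ids = gene_ids, cell_ids = cell_ids),
            class = "NormalizedMatrix")
}

#' @export
dim.NormalizedMatrix <- function(x) dim(x$values)

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix (", x$scheme, "): ", nrow(x$values), " genes x ",
      ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

check_libsizes <- function(counts) {
  ls <- library_sizes(counts)
  bad <- which(ls <= 0)
  if (length(bad))
    stop("cells with zero library size: ",
         paste(utils::head(counts$cell_ids[bad], 5), collapse = ", "))
  ls
}

#' Log-CPM normalization
#'
#' Scales each cell to counts per million and applies `log2(1 + x)`. This is
#' the input convention for the generic and local-CV metric families.
#'
#' @param counts A `CountMatrix` in which every cell has library size > 0.
#' @return A `NormalizedMatrix` with `scheme = "log_cpm"` holding
#'   `log2(1 + 1e6 * count / libsize)`.
#' @export
log_cpm_normalize <- function(counts) {
  ls <- check_libsizes(counts)
  v <- as.matrix(counts$counts)
  v <- log2(1 + 1e6 * sweep(v, 2, ls, "/"))
  new_normalized_matrix(v, "log_cpm", counts$gene_ids, counts$cell_ids)
}

#' Library-size log-normalization
#'
#' Divides each cell's counts by its library size, multiplies by 10,000 and
#' applies `log(1 + x)` -- the convention used before binned-dispersion
#' variable-feature selection.
#'
#' @inheritParams log_cpm_normalize
#' @return A `NormalizedMatrix` with `scheme = "libsize_1e4_log"`.
#' @export
libsize_lognormalize <- function(counts) {
  ls <- check_libsizes(counts)
  v <- as.matrix(counts$counts)
  v <- log1p(1e4 * sweep(v, 2, ls, "/"))
  new_normalized_matrix(v, "libsize_1e4_log", counts$gene_ids, counts$cell_ids)
}

#' Detection-rate gene filter
#'
#' Keeps genes detected (count > 0) in strictly more than `min_frac` of
#' cells. The strict inequality reads "expressed in more than x% of cells"
#' literally, so a gene detected in exactly `min_frac * n_cells` cells is
#' dropped.
#'
#' @param counts A `CountMatrix`.
#' @param min_frac Detection fraction threshold in `[0, 1)`.
#' @return Named logical vector, `TRUE` for retained genes.
#' @export
detection_filter <- function(counts, min_frac) {
  stopifnot(inherits(counts, "CountMatrix"),
            is.numeric(min_frac), length(min_frac) == 1,
            min_frac >= 0, min_frac < 1)
  det <- Matrix::rowSums(counts$counts > 0) / ncol(counts$counts)
  keep <- det > min_frac
  names(keep) <- counts$gene_ids
  keep
}

#' Regress covariates out of normalized expression
#'
#' Per-gene ordinary-least-squares residuals of expression on a cells x
#' covariates design matrix, used e.g. to remove an age effect before
#' estimating variability on merged age groups. An intercept column is
#' always included (and added if absent), so residuals have per-gene mean
#' zero and are orthogonal to every design column.
#'
#' @param values A `NormalizedMatrix`.
#' @param design Numeric matrix, cells in rows, covariates in columns.
#'   Categorical covariates must already be numerically encoded (e.g.
#'   one-hot with first level dropped).
#' @return A `NormalizedMatrix` of residuals; scheme gains a `"+resid"`
#'   suffix.
#' @export
regress_out <- function(values, design) {
  stopifnot(inherits(values, "NormalizedMatrix"))
  design <- as.matrix(design)
  if (nrow(design) != ncol(values$values))
    stop("design rows (", nrow(design), ") must match number of cells (",
         ncol(values$values), ")")
  has_intercept <- any(apply(design, 2, function(col) all(col == col[1] & col[1] != 0)))
  X <- if (has_intercept) design else cbind(`(Intercept)` = 1, design)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", qrX$rank,
         " < ", ncol(X), " columns)")
  resid <- t(qr.resid(qrX, t(values$values)))
  new_normalized_matrix(resid, paste0(values$scheme, "+resid"),
                        values$gene_ids, values$cell_ids)
}

#' Per-gene summary statistics
#'
#' Mean, standard deviation (denominator n - 1), variance and zero fraction
#' for each gene. When called on a `NormalizedMatrix`, `pct_zero` is still a
#' zero fraction of the stored values; pass the raw `CountMatrix` to get the
#' dropout-relevant zero proportion.
#'
#' @param m A `CountMatrix` or `NormalizedMatrix` with at least 2 cells.
#' @return A data.frame with columns `gene_id`, `mean`, `sd`, `variance`,
#'   `pct_zero`.
#' @export
gene_summaries <- function(m) {
  if (inherits(m, "CountMatrix")) {
    x <- m$counts
  } else if (inherits(m, "NormalizedMatrix")) {
    x <- m$values
  } else stop("m must be a CountMatrix or NormalizedMatrix")
  n <- ncol(x)
  if (n < 2) stop("gene summaries need at least 2 cells, got ", n)
  mu <- as.numeric(Matrix::rowMeans(x))
  ex2 <- as.numeric(Matrix::rowMeans(x^2))
  v <- pmax(0, (ex2 - mu^2) * n / (n - 1))
  pz <- as.numeric(Matrix::rowSums(x == 0)) / n
  data.frame(gene_id = m$gene_ids,
             mean = mu, sd = sqrt(v), variance = v, pct_zero = pz,
             stringsAsFactors = FALSE)
}
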