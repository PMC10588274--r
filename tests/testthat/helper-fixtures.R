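# Shared fixture builders; everything is generated in code, no binary data.

make_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(mat)))
  CountMatrix(mat, genes, cells)
}

random_counts <- function(n_genes, n_cells, lambda = 5, seed = 1) {
  set.seed(seed)
  make_counts(matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells))
}

# Wrap arbitrary values as a NormalizedMatrix for unit-level metric tests.
as_norm <- function(mat, scheme = "log_cpm") {
  genes <- paste0("g", seq_len(nrow(mat)))
  cells <- paste0("c", seq_len(ncol(mat)))
  scvarkit:::new_normalized_matrix(mat, scheme, genes, cells)
}

random_lengths <- function(gene_ids, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = gene_ids,
             length_bp = sample(300:10000, length(gene_ids), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Independent brute-force two-sample KS oracle: scan every observed point.
ks_brute <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Independent running-median oracle: explicit window enumeration.
runmed_brute <- function(x, by, window) {
  n <- length(x)
  ord <- order(by)
  xs <- x[ord]
  half_lo <- floor((window - 1) / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_lo)
    hi <- min(n, i + (window - 1 - half_lo))
    out[i] <- median(xs[lo:hi])
  }
  res <- numeric(n)
  res[ord] <- out
  res
}
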