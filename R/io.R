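#' Read a count matrix from disk
#'
#' Supports a Matrix Market triplet directory (`matrix.mtx` plus
#' `genes.tsv`/`features.tsv` and `barcodes.tsv` sidecars, cellranger
#' style) or a dense CSV with gene ids in the first column and cell ids in
#' the header. Genes-by-cells orientation is enforced: if the sidecar
#' lengths identify the axes as transposed, the matrix is transposed with a
#' warning. Duplicate identifiers are de-duplicated by suffixing, with a
#' warning.
#'
#' @param path Directory (for `mtx_dir`) or file path (for `csv`).
#' @param format One of `"mtx_dir"`, `"csv"`.
#' @return A `CountMatrix`.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    if (!file.exists(mtx)) stop("no matrix.mtx under ", path)
    gf <- file.path(path, "genes.tsv")
    if (!file.exists(gf)) gf <- file.path(path, "features.tsv")
    bf <- file.path(path, "barcodes.tsv")
    if (!file.exists(gf)) stop("no genes.tsv or features.tsv under ", path)
    if (!file.exists(bf)) stop("no barcodes.tsv under ", path)
    m <- Matrix::readMM(mtx)
    genes <- utils::read.delim(gf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bf, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) == nrow(m) && length(cells) == ncol(m)) {
      # genes x cells already
    } else if (length(genes) == ncol(m) && length(cells) == nrow(m)) {
      warning("matrix stored cells x genes; transposing to genes x cells")
      m <- Matrix::t(m)
    } else {
      stop("sidecar lengths (", length(genes), " genes, ", length(cells),
           " barcodes) do not match matrix dimensions ", nrow(m), " x ",
           ncol(m))
    }
    vals <- m@x
    if (length(vals) && any(vals != round(vals)))
      stop("non-integer entry in matrix.mtx; first offender: ",
           vals[which(vals != round(vals))[1]])
  } else {
    tab <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    cells <- colnames(m)
    if (any(m != round(m)))
      stop("non-integer entry in ", path, "; first offender: ",
           m[which(m != round(m))[1]])
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene ids de-duplicated by suffixing")
    genes <- make.unique(genes)
  }
  if (anyDuplicated(cells)) {
    warning("duplicate cell ids de-duplicated by suffixing")
    cells <- make.unique(cells)
  }
  CountMatrix(m, genes, cells)
}

#' Write a count matrix (and optional simulation truth) to disk
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` under `dir`, plus
#' `truth.csv` when a `SimTruth` is supplied and `config.yaml` when a
#' `SimConfig` is supplied.
#'
#' @param counts A `CountMatrix`.
#' @param dir Output directory (created if absent).
#' @param truth Optional `SimTruth`.
#' @param config Optional `SimConfig`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(counts, dir, truth = NULL, config = NULL) {
  stopifnot(inherits(counts, "CountMatrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts$counts, file.path(dir, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(truth)) {
    tdf <- data.frame(gene_id = counts$gene_ids, hvg = truth$hvg_flags,
                      base_mean = truth$base_mean, bcv = truth$bcv)
    utils::write.csv(tdf, file.path(dir, "truth.csv"), row.names = FALSE)
    if (!is.null(truth$group_labels))
      utils::write.csv(data.frame(cell_id = counts$cell_ids,
                                  group = as.character(truth$group_labels)),
                       file.path(dir, "groups.csv"), row.names = FALSE)
  }
  if (!is.null(config))
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a simulation truth table written by [write_counts()]
#'
#' @param path Path to a `truth.csv`.
#' @return A `SimTruth`.
#' @export
read_truth <- function(path) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "hvg", "base_mean", "bcv")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop("truth table misses column(s): ",
                         paste(miss, collapse = ", "))
  tr <- SimTruth(as.logical(t$hvg), t$base_mean, t$bcv)
  names(tr$hvg_flags) <- t$gene_id
  tr
}

#' Read an annotation table
#'
#' Typed readers for the small plain-text tables used around the count
#' matrix. `gene_lengths` expects columns `gene_id`, `length_bp`;
#' `cell_metadata` expects `cell_id` plus any covariates; `tf_edges`
#' expects a two-column TF-to-target table; `gene_set` accepts a headerless
#' one-id-per-line file and returns a character vector.
#'
#' @param path File path (TSV or CSV; the delimiter is sniffed from the
#'   extension, default tab).
#' @param kind One of `"gene_lengths"`, `"gene_set"`, `"cell_metadata"`,
#'   `"tf_edges"`.
#' @return A data.frame (or character vector for `gene_set`).
#' @export
read_table <- function(path, kind = c("gene_lengths", "gene_set",
                                      "cell_metadata", "tf_edges")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (kind == "gene_set") {
    ids <- readLines(path)
    ids <- ids[nzchar(ids)]
    if (!length(ids)) warning("empty gene-set file: ", path)
    return(ids)
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) {
    warning("empty table: ", path)
    return(tab)
  }
  required <- switch(kind,
                     gene_lengths = c("gene_id", "length_bp"),
                     cell_metadata = "cell_id",
                     tf_edges = NULL)
  miss <- setdiff(required, names(tab))
  if (length(miss)) stop("missing required column(s) in ", path, ": ",
                         paste(miss, collapse = ", "))
  if (kind == "gene_lengths") {
    if (anyDuplicated(tab$gene_id))
      stop("duplicated gene_id in ", path, ": ",
           tab$gene_id[duplicated(tab$gene_id)][1])
    if (any(tab$length_bp <= 0)) stop("length_bp must be positive")
  }
  if (kind == "tf_edges" && ncol(tab) < 2)
    stop("tf_edges table needs two columns (TF, target)")
  tab
}

#' Run configuration
#'
#' A single YAML-serializable document capturing everything a run needs:
#' input location and format, normalization scheme, metric list with
#' parameters, evaluation toggles, simulator block, seed, and output
#' directory. Unknown keys are rejected so configs fail loudly rather than
#' silently ignoring typos.
#'
#' @param input Input path (mtx directory or csv file) or `NULL`.
#' @param format `"mtx_dir"` or `"csv"`.
#' @param normalization `"log_cpm"` or `"libsize_1e4_log"`.
#' @param metrics Character vector of metric names (see
#'   [run_all_metrics()]).
#' @param metric_params Named list of per-metric parameters.
#' @param criteria Character vector of evaluation criteria to compute.
#' @param sim Named list of [sim_config()] overrides.
#' @param seed Integer seed.
#' @param outdir Output directory.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(input = NULL, format = "mtx_dir",
                       normalization = "log_cpm",
                       metrics = c("sd", "mad", "iqr", "cv", "fano", "lcv",
                                   "dm", "trend", "mvp", "vst", "nb"),
                       metric_params = list(), criteria = character(0),
                       sim = list(), seed = 1L, outdir = ".") {
  cfg <- list(input = input, format = format, normalization = normalization,
              metrics = metrics, metric_params = metric_params,
              criteria = criteria, sim = sim, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown RunConfig key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param cfg A `RunConfig`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "RunConfig"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Serialize a metric panel to long format
#'
#' @param results Named list of `VariabilityResult` (from
#'   [run_all_metrics()]).
#' @param gene_ids Gene identifiers shared by all results.
#' @return Long-format data.frame `(gene_id, metric, value, evaluated)`.
#' @export
metrics_to_long <- function(results, gene_ids) {
  do.call(rbind, lapply(results, as.data.frame, gene_ids = gene_ids))
}
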