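#' Construct a VariabilityResult
#'
#' Container for one metric's per-gene cell-to-cell variability estimates.
#' Genes a metric could not evaluate (zero mean, missing gene length, ...)
#' carry `NA` in `values` and `FALSE` in `evaluated` rather than a sentinel,
#' so per-metric gene coverage is always recoverable.
#'
#' @param metric_name Metric label, e.g. `"sd"` or `"trend"`.
#' @param values Named per-gene numeric vector; `NA` where unevaluated.
#' @param evaluated Logical mask, same length and order as `values`.
#' @param input_scheme Normalization tag of the input (`"raw"`, `"log_cpm"`,
#'   `"libsize_1e4_log"`, ...).
#' @return An object of class `VariabilityResult`.
#' @export
VariabilityResult <- function(metric_name, values, evaluated, input_scheme) {
  stopifnot(length(values) == length(evaluated))
  values <- as.numeric(values)
  evaluated <- as.logical(evaluated)
  if (any(evaluated & !is.finite(values)))
    stop("non-finite values among evaluated genes in metric ", metric_name)
  values[!evaluated] <- NA_real_
  structure(list(metric_name = metric_name, values = values,
                 evaluated = evaluated, input_scheme = input_scheme),
            class = "VariabilityResult")
}

#' @export
print.VariabilityResult <- function(x, ...) {
  cat("VariabilityResult '", x$metric_name, "' (input: ", x$input_scheme,
      "): ", sum(x$evaluated), "/", length(x$values),
      " genes evaluated\n", sep = "")
  invisible(x)
}

#' @rdname VariabilityResult
#' @param x A `VariabilityResult`.
#' @param gene_ids Optional gene identifiers to attach.
#' @param ... Ignored.
#' @return For `as.data.frame`: long-format rows
#'   `(gene_id, metric, value, evaluated)`.
#' @export
as.data.frame.VariabilityResult <- function(x, gene_ids = NULL, ...) {
  ids <- if (!is.null(gene_ids)) gene_ids else
    if (!is.null(names(x$values))) names(x$values) else
      paste0("gene", seq_along(x$values))
  data.frame(gene_id = ids, metric = x$metric_name, value = x$values,
             evaluated = x$evaluated, row.names = NULL,
             stringsAsFactors = FALSE)
}

row_stats <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  list(mean = mu, var = v, sd = sqrt(v), n = n)
}

# Centered running statistic over a window of `window` neighbours in the
# ordering induced by `by`; windows truncate at the edges (never extended).
running_window_stat <- function(x, by, window, stat = stats::median) {
  n <- length(x)
  ord <- order(by)
  xs <- x[ord]
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half_lo)
    hi <- min(n, i + half_hi)
    out[i] <- stat(xs[lo:hi])
  }
  res <- numeric(n)
  res[ord] <- out
  res
}

#' Generic per-gene variability statistics
#'
#' SD, MAD and IQR summarize dispersion around the per-gene center; CV
#' (sigma/mu) and the Fano factor (sigma^2/mu) acknowledge the mean-variance
#' dependency of expression data. CV and Fano are undefined for genes with
#' zero mean, which are returned unevaluated.
#'
#' @param norm A `NormalizedMatrix` (log-CPM by convention) with >= 2 cells.
#' @param statistic One of `"sd"`, `"mad"`, `"iqr"`, `"cv"`, `"fano"`.
#' @return A `VariabilityResult`.
#' @export
generic_metric <- function(norm, statistic = c("sd", "mad", "iqr", "cv", "fano")) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  statistic <- match.arg(statistic)
  x <- norm$values
  if (ncol(x) < 2) stop("need at least 2 cells")
  st <- row_stats(x)
  vals <- switch(statistic,
    sd = st$sd,
    mad = apply(x, 1, stats::mad),
    iqr = apply(x, 1, stats::IQR),
    cv = st$sd / st$mean,
    fano = st$var / st$mean)
  evaluated <- if (statistic %in% c("cv", "fano")) st$mean > 0 else
    rep(TRUE, nrow(x))
  vals[!evaluated] <- NA_real_
  names(vals) <- norm$gene_ids
  VariabilityResult(statistic, vals, evaluated, norm$scheme)
}

round_half_up <- function(x) floor(x + 0.5)

#' Local coefficient of variation (LCV)
#'
#' Ranks each gene's CV against genes of similar mean expression: genes are
#' ordered by mean, and each gene receives the percentile rank of its CV
#' within a centered window of `window` genes (truncated at the edges),
#' mapped to the integers 1..100. Ties take the average rank's percentile,
#' rounded half-up. The output is therefore bounded in \[1, 100\] by
#' construction and invariant to any monotone rescaling of the CVs within a
#' window.
#'
#' @param norm A `NormalizedMatrix`.
#' @param window Window width in genes (default 100); must be >= 2 and not
#'   exceed the number of evaluable (positive-mean) genes.
#' @return A `VariabilityResult` of integer-valued percentiles in
#'   \[1, 100\]; zero-mean genes are unevaluated.
#' @export
lcv <- function(norm, window = 100) {
  stopifnot(inherits(norm, "NormalizedMatrix"), window >= 2)
  st <- row_stats(norm$values)
  ok <- st$mean > 0
  n_ok <- sum(ok)
  if (window > n_ok)
    stop("window (", window, ") exceeds number of evaluable genes (", n_ok, ")")
  cv <- (st$sd / st$mean)[ok]
  mu <- st$mean[ok]
  ord <- order(mu)
  cv_s <- cv[ord]
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1 - half_lo
  out_s <- numeric(n_ok)
  for (i in seq_len(n_ok)) {
    lo <- max(1L, i - half_lo)
    hi <- min(n_ok, i + half_hi)
    win <- cv_s[lo:hi]
    r <- rank(win, ties.method = "average")[i - lo + 1L]
    out_s[i] <- round_half_up(100 * r / length(win))
  }
  out_s <- pmin(100, pmax(1, out_s))
  vals_ok <- numeric(n_ok)
  vals_ok[ord] <- out_s
  vals <- rep(NA_real_, length(ok))
  vals[ok] <- vals_ok
  names(vals) <- norm$gene_ids
  VariabilityResult("lcv", vals, ok, norm$scheme)
}

#' Distance to median (DM)
#'
#' Expression-level- and gene-length-corrected heterogeneity: the distance
#' of each gene's log10 CV^2 from a running median over genes of similar
#' (log10) mean, further corrected by subtracting a running median of that
#' distance over genes of similar (log10) length. Genes with zero mean,
#' zero variance, or no length annotation are excluded (mask `FALSE`) --
#' on real annotation this exclusion can be substantial, which the
#' evaluation layer reports as gene coverage.
#'
#' @param counts A `CountMatrix` (DM operates on raw counts).
#' @param annot A data.frame with columns `gene_id` and `length_bp`.
#' @param window Running-median window in rank space (default 50 genes).
#' @param min_mean Optional mean-count pre-filter; genes at or below it are
#'   excluded (default 0, i.e. only zero-mean genes drop).
#' @return A `VariabilityResult` of corrected distances (unitless, log10
#'   scale).
#' @export
dm <- function(counts, annot, window = 50, min_mean = 0) {
  stopifnot(inherits(counts, "CountMatrix"))
  if (!all(c("gene_id", "length_bp") %in% names(annot)))
    stop("annot must have columns gene_id and length_bp")
  len <- annot$length_bp[match(counts$gene_ids, annot$gene_id)]
  if (all(is.na(len))) stop("no gene lengths available for any gene")
  st <- row_stats(as.matrix(counts$counts))
  ok <- st$mean > min_mean & st$var > 0 & !is.na(len) & len > 0
  if (sum(ok) < window)
    stop("fewer evaluable genes (", sum(ok), ") than the window (", window, ")")
  mu <- st$mean[ok]
  cv2 <- st$var[ok] / mu^2
  lcv2 <- log10(cv2)
  d <- lcv2 - running_window_stat(lcv2, log10(mu), window)
  corrected <- d - running_window_stat(d, log10(len[ok]), window)
  vals <- rep(NA_real_, length(ok))
  vals[ok] <- corrected
  names(vals) <- counts$gene_ids
  VariabilityResult("dm", vals, ok, "raw")
}

#' Construct a TrendFit
#'
#' A fitted mean-to-expected-variance (or dispersion) curve with clamped
#' extrapolation: queries outside the fit domain evaluate at the nearest
#' domain endpoint.
#'
#' @param fun Function of mean returning the fitted value.
#' @param domain Length-2 numeric, the fitted mean range.
#' @param span Smoothing parameter used (informational).
#' @param method Label of the fitting method used.
#' @return An object of class `TrendFit`; call `predict(fit, mean)` to
#'   evaluate it.
#' @export
TrendFit <- function(fun, domain, span = NA_real_, method = "loess") {
  structure(list(fun = fun, domain = domain, span = span, method = method),
            class = "TrendFit")
}

#' @rdname TrendFit
#' @param object A `TrendFit`.
#' @param newdata Numeric vector of means at which to evaluate the trend.
#' @param ... Ignored.
#' @export
predict.TrendFit <- function(object, newdata, ...) {
  x <- pmin(pmax(newdata, object$domain[1]), object$domain[2])
  object$fun(x)
}

fit_variance_trend <- function(mu, v, span = 0.3) {
  if (length(unique(mu)) < 3 || diff(range(mu)) == 0)
    stop("degenerate trend fit: gene means do not vary")
  dens <- stats::density(mu, n = 512)
  w <- 1 / pmax(stats::approx(dens$x, dens$y, xout = mu, rule = 2)$y, 1e-8)
  w <- w / mean(w)
  fit <- tryCatch({
    lo <- stats::loess(v ~ mu, span = span, degree = 2, weights = w,
                       family = "symmetric",
                       control = stats::loess.control(surface = "direct"))
    fn <- function(x) pmax(stats::predict(lo, data.frame(mu = x)), 0)
    TrendFit(fn, range(mu), span = span, method = "loess")
  }, error = function(e) NULL)
  if (is.null(fit)) {
    # parametric fallback: a*x / (x^n + b), monotone saturating curve
    start <- list(a = max(v) / stats::median(mu[mu > 0] + 1e-8), b = 1, n = 1)
    nl <- stats::nls(v ~ a * mu / (mu^n + b), start = start,
                     control = stats::nls.control(warnOnly = TRUE),
                     lower = c(a = 1e-8, b = 1e-8, n = 0.1), algorithm = "port")
    fn <- function(x) {
      cf <- as.list(stats::coef(nl))
      pmax(cf$a * x / (x^cf$n + cf$b), 0)
    }
    fit <- TrendFit(fn, range(mu), method = "parametric")
  }
  fit
}

#' Mean-variance trend decomposition
#'
#' Fits a nonparametric smooth of per-gene variance against per-gene mean of
#' log-normalized expression and reports, per gene, the residual total
#' variance minus fitted (technical) variance. Positive residuals indicate
#' biological variability above the mean-matched expectation; negative
#' residuals below it. Fitting weights are inversely proportional to the
#' local density of gene means so dense mean ranges do not dominate; if the
#' local regression fails, a monotone saturating curve `a*x/(x^n + b)` is
#' fitted instead.
#'
#' @param norm A `NormalizedMatrix` with >= 3 positive-mean genes.
#' @param span Local-regression span (default 0.3).
#' @return A list with elements `result` (a `VariabilityResult`, metric name
#'   `"trend"`) and `fit` (a `TrendFit`).
#' @export
trend_decompose <- function(norm, span = 0.3) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  st <- row_stats(norm$values)
  ok <- st$mean > 0
  if (sum(ok) < 3) stop("need at least 3 genes with positive mean")
  fit <- fit_variance_trend(st$mean[ok], st$var[ok], span = span)
  resid <- st$var[ok] - predict(fit, st$mean[ok])
  vals <- rep(NA_real_, length(ok))
  vals[ok] <- resid
  names(vals) <- norm$gene_ids
  list(result = VariabilityResult("trend", vals, ok, norm$scheme), fit = fit)
}

#' Binned dispersion z-scores (mean-variability-plot style)
#'
#' Computes a per-gene dispersion (Fano factor of the back-transformed,
#' `expm1`, normalized values), bins genes into `n_bins` equal-frequency
#' bins of mean back-transformed expression, and z-scores the dispersion
#' within each bin, controlling the strong mean dependency of dispersion.
#' Bins with a single gene or zero dispersion spread yield 0.
#'
#' @param norm A `NormalizedMatrix`; the library-size log scheme is the
#'   conventional input.
#' @param n_bins Number of equal-frequency mean bins (default 20).
#' @return A `VariabilityResult` (metric name `"mvp"`); zero-mean genes are
#'   unevaluated.
#' @export
mvp_dispersion <- function(norm, n_bins = 20) {
  stopifnot(inherits(norm, "NormalizedMatrix"), n_bins >= 1)
  bt <- expm1(norm$values)
  st <- row_stats(bt)
  ok <- st$mean > 0
  disp <- st$var[ok] / st$mean[ok]
  mu <- st$mean[ok]
  n_ok <- length(mu)
  bins <- ceiling(rank(mu, ties.method = "first") * min(n_bins, n_ok) / n_ok)
  z <- numeric(n_ok)
  for (b in unique(bins)) {
    idx <- bins == b
    if (sum(idx) < 2 || stats::sd(disp[idx]) == 0) {
      z[idx] <- 0
    } else {
      z[idx] <- (disp[idx] - mean(disp[idx])) / stats::sd(disp[idx])
    }
  }
  vals <- rep(NA_real_, length(ok))
  vals[ok] <- z
  names(vals) <- norm$gene_ids
  VariabilityResult("mvp", vals, ok, norm$scheme)
}

#' LOESS-standardized variance (vst style)
#'
#' Fits a LOESS trend of log10 variance on log10 mean of the raw counts,
#' standardizes each count by its gene's observed mean and trend-expected
#' standard deviation, clips standardized values at `sqrt(n_cells)`, and
#' reports the per-gene variance of the clipped standardized values. Genes
#' sitting on the trend whose values never clip score about 1.
#'
#' @param counts A `CountMatrix` with >= 3 genes of positive mean and
#'   variance.
#' @param span LOESS span (default 0.3).
#' @return A `VariabilityResult` (metric name `"vst"`); genes with zero mean
#'   or zero variance are unevaluated.
#' @export
vst_variance <- function(counts, span = 0.3) {
  stopifnot(inherits(counts, "CountMatrix"))
  x <- as.matrix(counts$counts)
  st <- row_stats(x)
  ok <- st$mean > 0 & st$var > 0
  if (sum(ok) < 3) stop("need at least 3 genes with positive mean and variance")
  lm10 <- log10(st$mean[ok])
  lv10 <- log10(st$var[ok])
  if (diff(range(lm10)) == 0) stop("degenerate fit: all gene means equal")
  lo <- stats::loess(lv10 ~ lm10, span = span, degree = 2)
  sd_hat <- sqrt(10^stats::predict(lo, data.frame(lm10 = lm10)))
  clip <- sqrt(ncol(x))
  n <- ncol(x)
  vals_ok <- numeric(sum(ok))
  idx_ok <- which(ok)
  for (k in seq_along(idx_ok)) {
    z <- (x[idx_ok[k], ] - st$mean[idx_ok[k]]) / sd_hat[k]
    z <- pmin(z, clip)
    vals_ok[k] <- stats::var(z)
  }
  vals <- rep(NA_real_, length(ok))
  vals[ok] <- vals_ok
  names(vals) <- counts$gene_ids
  VariabilityResult("vst", vals, ok, "raw")
}

#' Construct an NBDispersionFit
#'
#' Per-gene raw, trend, and shrunken negative-binomial dispersion estimates.
#' The shrunken estimate always lies (componentwise) between the raw
#' estimate and the trend.
#'
#' @param alpha Raw per-gene dispersion estimates (>= 0).
#' @param trend_alpha Trend (running-median) dispersion at each gene's mean.
#' @param shrunk_alpha Final shrunken estimates.
#' @return An object of class `NBDispersionFit`.
#' @export
NBDispersionFit <- function(alpha, trend_alpha, shrunk_alpha) {
  stopifnot(all(alpha >= 0, na.rm = TRUE),
            all(trend_alpha >= 0, na.rm = TRUE),
            all(shrunk_alpha >= 0, na.rm = TRUE))
  structure(list(alpha = alpha, trend_alpha = trend_alpha,
                 shrunk_alpha = shrunk_alpha),
            class = "NBDispersionFit")
}

#' Shrunken negative-binomial dispersion
#'
#' One estimator standing in for the NB-dispersion metric family: counts are
#' scaled by per-cell size factors (library size over mean library size), a
#' method-of-moments dispersion `alpha = max(0, (var - mean)/mean^2)` is
#' computed per gene (the NB identity `var = mu + alpha*mu^2`), a trend is
#' taken as the running median of `alpha` over genes ordered by mean, and
#' the final estimate shrinks the raw value geometrically toward the trend:
#' `exp((1-w)*log(alpha+eps) + w*log(trend+eps)) - eps`.
#'
#' @param counts A `CountMatrix` with >= 2 cells and positive library sizes.
#' @param shrink_weight Shrinkage weight `w` in \[0, 1\] toward the trend
#'   (default 0.5; 0 = raw moments, 1 = pure trend).
#' @param window Running-median window for the trend (default 50 genes).
#' @return A list with elements `result` (a `VariabilityResult`, metric name
#'   `"nb"`, values = shrunken alpha) and `fit` (an `NBDispersionFit`).
#' @export
nb_dispersion <- function(counts, shrink_weight = 0.5, window = 50) {
  stopifnot(inherits(counts, "CountMatrix"),
            shrink_weight >= 0, shrink_weight <= 1)
  if (ncol(counts$counts) < 2) stop("need at least 2 cells")
  ls <- check_libsizes(counts)
  sf <- ls / mean(ls)
  x <- sweep(as.matrix(counts$counts), 2, sf, "/")
  st <- row_stats(x)
  ok <- st$mean > 0
  eps <- 1e-8
  mu <- st$mean[ok]
  alpha <- pmax(0, (st$var[ok] - mu) / mu^2)
  n_ok <- length(alpha)
  w_len <- min(window, n_ok)
  trend <- running_window_stat(alpha, mu, w_len)
  shrunk <- pmax(0, exp((1 - shrink_weight) * log(alpha + eps) +
                          shrink_weight * log(trend + eps)) - eps)
  expand <- function(v) {
    out <- rep(NA_real_, length(ok))
    out[ok] <- v
    names(out) <- counts$gene_ids
    out
  }
  fit <- NBDispersionFit(expand(alpha), expand(trend), expand(shrunk))
  list(result = VariabilityResult("nb", expand(shrunk), ok, "raw"), fit = fit)
}

#' Run the full metric panel
#'
#' Wrapper running every configured metric with its conventional input
#' (generic statistics and LCV on log-CPM; binned dispersion on
#' library-size log normalization; DM, vst and NB dispersion on raw
#' counts). A metric that errors is recorded as a failure and skipped; the
#' remaining results are returned aligned to the input's gene ordering.
#'
#' @param counts A `CountMatrix`.
#' @param annot Optional gene annotation data.frame (`gene_id`,
#'   `length_bp`); required only by the DM metric.
#' @param config Named list overriding defaults: `metrics` (character
#'   vector), `lcv_window`, `dm_window`, `n_bins`, `shrink_weight`, `span`.
#' @return A named list of `VariabilityResult` objects with attribute
#'   `"failures"`, a named character vector of error messages for metrics
#'   that could not run.
#' @export
run_all_metrics <- function(counts, annot = NULL, config = list()) {
  stopifnot(inherits(counts, "CountMatrix"))
  defaults <- list(metrics = c("sd", "mad", "iqr", "cv", "fano", "lcv",
                               "dm", "trend", "mvp", "vst", "nb"),
                   lcv_window = 100, dm_window = 50, n_bins = 20,
                   shrink_weight = 0.5, span = 0.3)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!length(cfg$metrics)) stop("empty metric list")
  logcpm <- log_cpm_normalize(counts)
  liblog <- libsize_lognormalize(counts)
  runners <- list(
    sd = function() generic_metric(logcpm, "sd"),
    mad = function() generic_metric(logcpm, "mad"),
    iqr = function() generic_metric(logcpm, "iqr"),
    cv = function() generic_metric(logcpm, "cv"),
    fano = function() generic_metric(logcpm, "fano"),
    lcv = function() lcv(logcpm, window = cfg$lcv_window),
    dm = function() {
      if (is.null(annot)) stop("dm requires gene length annotation")
      dm(counts, annot, window = cfg$dm_window)
    },
    trend = function() trend_decompose(logcpm, span = cfg$span)$result,
    mvp = function() mvp_dispersion(liblog, n_bins = cfg$n_bins),
    vst = function() vst_variance(counts, span = cfg$span),
    nb = function() nb_dispersion(counts, shrink_weight = cfg$shrink_weight)$result
  )
  bad <- setdiff(cfg$metrics, names(runners))
  if (length(bad)) stop("unknown metrics: ", paste(bad, collapse = ", "))
  results <- list()
  failures <- character(0)
  for (m in cfg$metrics) {
    r <- tryCatch(runners[[m]](), error = function(e) e)
    if (inherits(r, "error")) {
      failures[m] <- conditionMessage(r)
    } else {
      results[[m]] <- r
    }
  }
  attr(results, "failures") <- failures
  results
}
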