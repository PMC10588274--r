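test_that("generic metrics match direct arithmetic and handle zero means", {
  vals <- matrix(c(5, 5, 5,
                   0, 0, 4,
                   0, 0, 0), 3, 3, byrow = TRUE)
  norm <- as_norm(vals)
  for (s in c("sd", "mad", "iqr", "cv", "fano")) {
    r <- generic_metric(norm, s)
    expect_equal(unname(r$values[1]), 0)       # constant gene
  }
  cv <- generic_metric(norm, "cv")
  fano <- generic_metric(norm, "fano")
  expect_equal(unname(cv$values[2]), sqrt(3), tolerance = 1e-12)
  expect_equal(unname(fano$values[2]), 4, tolerance = 1e-12)
  expect_false(cv$evaluated[3])                # zero-mean gene unevaluated
  expect_false(fano$evaluated[3])
  expect_true(generic_metric(norm, "sd")$evaluated[3])
})

test_that("Fano factor of Poisson data is about 1", {
  set.seed(11)
  vals <- matrix(rpois(3 * 1e5, 5), 3, 1e5)
  fano <- generic_metric(as_norm(vals, scheme = "raw"), "fano")
  expect_true(all(abs(fano$values - 1) < 0.05))
})

test_that("cv^2 equals fano/mean wherever both are evaluated", {
  cm <- random_counts(200, 40, lambda = 3, seed = 5)
  norm <- log_cpm_normalize(cm)
  mu <- rowMeans(norm$values)
  cv <- generic_metric(norm, "cv")
  fano <- generic_metric(norm, "fano")
  ok <- cv$evaluated & fano$evaluated
  expect_lt(max(abs(cv$values[ok]^2 - fano$values[ok] / mu[ok])), 1e-10)
})

test_that("metrics are invariant to cell and gene permutations", {
  cm <- random_counts(60, 25, seed = 9)
  set.seed(1)
  pc <- sample(25)
  pg <- sample(60)
  perm <- cm[pg, pc]
  for (fn in list(function(x) generic_metric(log_cpm_normalize(x), "fano"),
                  function(x) lcv(log_cpm_normalize(x), window = 20),
                  function(x) nb_dispersion(x)$result)) {
    a <- fn(cm)
    b <- fn(perm)
    expect_equal(unname(a$values[pg]), unname(b$values))
  }
})

test_that("LCV is a windowed percentile in [1, 100] with average-rank ties", {
  # 5 genes, window 5 (single global window): ranks map to percentiles
  vals <- rbind(c(1, 1.1, 0.9),   # distinct CVs via different spreads
                c(2, 2.8, 1.2),
                c(3, 5.2, 0.8),
                c(4, 8.0, 0.4),
                c(5, 11, 0.2))
  r <- lcv(as_norm(vals), window = 5)
  expect_true(all(r$values >= 1 & r$values <= 100))
  st <- scvarkit:::row_stats(vals)
  cv <- st$sd / st$mean
  expect_equal(unname(r$values[which.max(cv)]), 100)  # strict max scores 100
  # tied CVs with identical (full, interior) windows share one value
  same <- matrix(rep(c(1, 2, 3), 12), 12, 3, byrow = TRUE) * (1:12)
  rt <- lcv(as_norm(same), window = 4)
  expect_equal(length(unique(rt$values[3:10])), 1L)
  # invariance to monotone rescaling of the values (hence of CVs)
  cm <- random_counts(80, 30, seed = 3)
  n1 <- log_cpm_normalize(cm)
  r1 <- lcv(n1, window = 30)
  n2 <- n1
  n2$values <- n1$values * 7        # scales all CVs by 1, means by 7: same order
  r2 <- lcv(n2, window = 30)
  expect_equal(r1$values, r2$values)
  expect_error(lcv(n1, window = 1000), "exceeds")
})

test_that("DM running medians match brute force and lengths gate genes", {
  set.seed(21)
  cm <- random_counts(20, 40, lambda = 6, seed = 21)
  ann <- random_lengths(cm$gene_ids, seed = 2)
  r <- dm(cm, ann, window = 7)
  st <- scvarkit:::row_stats(as.matrix(cm$counts))
  lcv2 <- log10(st$var / st$mean^2)
  d <- lcv2 - runmed_brute(lcv2, log10(st$mean), 7)
  expected <- d - runmed_brute(d, log10(ann$length_bp), 7)
  expect_equal(unname(r$values), unname(expected), tolerance = 1e-12)
  # a gene without length is excluded
  ann2 <- ann[-3, ]
  r2 <- dm(cm, ann2, window = 7)
  expect_false(r2$evaluated[3])
  expect_true(is.na(r2$values[3]))
  expect_error(dm(cm, data.frame(gene_id = "zz", length_bp = 5)), "no gene lengths")
  # identical CV^2 everywhere: distances are exactly 0
  flat <- make_counts(matrix(rep(c(0L, 2L, 4L), 10), 10, 3, byrow = TRUE) *
                        rep(1:10))
  rf <- dm(flat, random_lengths(flat$gene_ids), window = 5)
  expect_equal(unname(rf$values[rf$evaluated]), rep(0, sum(rf$evaluated)))
})

test_that("trend decomposition residuals are signed deviations from the fit", {
  set.seed(31)
  n <- 300
  mu <- sort(runif(n, 1, 10))
  trend_true <- 2 * mu / (mu + 3)
  v <- trend_true * exp(rnorm(n, 0, 0.1))
  # synthesize a NormalizedMatrix whose row means/vars are exactly (mu, v)
  k <- 80
  base <- scale(matrix(rnorm(n * k), n, k))  # rows: mean 0, sd 1 (approx)
  base <- t(scale(t(base)))                  # exact row mean 0, sd 1
  vals <- sweep(sweep(base, 1, sqrt(v), "*"), 1, mu, "+")
  td <- trend_decompose(as_norm(vals))
  r <- td$result
  expect_s3_class(td$fit, "TrendFit")
  # residuals centered near zero relative to the trend scale
  expect_lt(abs(mean(r$values, na.rm = TRUE)), 0.05 * mean(trend_true))
  # above-trend genes positive, below-trend negative (clear cases)
  fitted <- predict(td$fit, mu)
  clear <- abs(v - fitted) > 0.2 * fitted
  expect_true(all(sign(r$values[clear]) == sign((v - fitted))[clear]))
  # extrapolation clamps to the fit domain
  expect_equal(predict(td$fit, 1e6), predict(td$fit, max(mu)))
  expect_error(trend_decompose(as_norm(matrix(1, 5, 4))), "degenerate|positive mean")
})

test_that("simulated HVGs sit above the trend on average", {
  sim <- simulate_counts(sim_config(seed = 17))
  r <- trend_decompose(log_cpm_normalize(sim$counts))$result
  hvg <- sim$truth$hvg_flags
  expect_gt(mean(r$values[hvg], na.rm = TRUE),
            mean(r$values[!hvg], na.rm = TRUE))
})

test_that("mvp z-scores are centered and scaled within bins", {
  cm <- random_counts(200, 50, lambda = 4, seed = 13)
  norm <- libsize_lognormalize(cm)
  r <- mvp_dispersion(norm, n_bins = 10)
  bt <- expm1(norm$values)
  st <- scvarkit:::row_stats(bt)
  ok <- st$mean > 0
  bins <- ceiling(rank(st$mean[ok], ties.method = "first") * 10 / sum(ok))
  for (b in unique(bins)) {
    z <- r$values[which(ok)[bins == b]]
    if (length(z) >= 2 && sd(z) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-10)
      expect_equal(sd(z), 1, tolerance = 1e-10)
    }
  }
  # singleton bins score 0
  small <- as_norm(matrix(c(1, 2, 6, 3, 5, 9), 2, 3, byrow = TRUE))
  rs <- mvp_dispersion(small, n_bins = 2)
  expect_equal(unname(rs$values), c(0, 0))
  expect_equal(formals(mvp_dispersion)$n_bins, 20)
})

test_that("vst variance is about 1 for on-trend genes and skips constants", {
  set.seed(41)
  # Poisson genes: variance tracks the mean, so all genes sit near the trend
  mu <- exp(runif(300, 0, 4))
  k <- t(vapply(mu, function(m) rpois(500, m), numeric(500)))
  cm <- make_counts(k)
  r <- vst_variance(cm)
  expect_true(median(abs(r$values - 1), na.rm = TRUE) < 0.15)
  # constant (zero-variance) gene is unevaluated
  k2 <- rbind(k[1:20, ], rep(3L, 500))
  r2 <- vst_variance(make_counts(k2))
  expect_false(r2$evaluated[21])
})

test_that("NB dispersion recovers moments and clamps underdispersion", {
  set.seed(51)
  # true NB gene, alpha = 0.5, no shrinkage: moment recovery; a ballast
  # gene equalizes library sizes so size factors are exactly 1
  g_nb <- rnbinom(50000, size = 1 / 0.5, mu = 20)
  g_po <- rpois(50000, 8)
  ballast <- max(g_nb + g_po) - g_nb - g_po
  cm <- make_counts(rbind(g_nb, g_po, ballast))
  fit <- nb_dispersion(cm, shrink_weight = 0, window = 2)
  expect_true(fit$fit$alpha[1] > 0.45 && fit$fit$alpha[1] < 0.55)
  expect_lt(fit$fit$alpha[2], 0.02)            # Poisson: no overdispersion
  # sigma^2 < mu clamps to zero (constant library sizes by construction)
  under <- make_counts(rbind(rep(c(4L, 5L), 10), rep(c(5L, 4L), 10)))
  f2 <- nb_dispersion(under, shrink_weight = 0, window = 2)
  expect_equal(unname(f2$fit$alpha), c(0, 0))
  # shrunken alpha lies between raw and trend, componentwise
  cm3 <- random_counts(100, 60, lambda = 3, seed = 52)
  f3 <- nb_dispersion(cm3, shrink_weight = 0.5)$fit
  ok <- !is.na(f3$alpha)
  lo <- pmin(f3$alpha[ok], f3$trend_alpha[ok])
  hi <- pmax(f3$alpha[ok], f3$trend_alpha[ok])
  expect_true(all(f3$shrunk_alpha[ok] >= lo - 1e-8 &
                    f3$shrunk_alpha[ok] <= hi + 1e-8))
})

test_that("run_all_metrics returns the panel and records failures", {
  sim <- simulate_counts(sim_config(n_genes = 300, n_cells = 80, n_hvg = 50,
                                    seed = 6))
  ann <- random_lengths(sim$counts$gene_ids)
  res <- run_all_metrics(sim$counts, annot = ann)
  expect_setequal(names(res), c("sd", "mad", "iqr", "cv", "fano", "lcv",
                                "dm", "trend", "mvp", "vst", "nb"))
  expect_true(all(vapply(res, function(r) length(r$values), 0L) == 300))
  expect_length(attr(res, "failures"), 0)
  # without lengths, dm fails but everything else still runs
  res2 <- run_all_metrics(sim$counts)
  expect_false("dm" %in% names(res2))
  expect_named(attr(res2, "failures"), "dm")
  expect_length(res2, 10)
  expect_error(run_all_metrics(sim$counts, config = list(metrics = character(0))),
               "empty metric list")
  expect_error(run_all_metrics(sim$counts, config = list(bogus = 1)), "unknown config")
})

test_that("sd, trend and vst each place at least half the true HVGs on top", {
  sim <- simulate_counts(sim_config(bcv_fold = 3, seed = 23))
  norm <- log_cpm_normalize(sim$counts)
  for (r in list(generic_metric(norm, "sd"),
                 trend_decompose(norm)$result,
                 vst_variance(sim$counts))) {
    expect_gte(hvg_rediscovery(r, sim$truth), 0.5)
  }
})
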