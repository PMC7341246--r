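strat_fixture <- function(n_per = 25, m = 400, fst_shift = 0.25, seed = 61) {
  set.seed(seed)
  p1 <- stats::runif(m, 0.2, 0.8)
  p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-1, 1), m, TRUE) * fst_shift))
  calls <- rbind(
    sapply(p1, function(p) stats::rbinom(n_per, 2, p)),
    sapply(p2, function(p) stats::rbinom(n_per, 2, p))
  )
  list(ds = make_geno(calls, chrom = rep(1:4, length.out = m)),
       pop = rep(c(0, 1), each = n_per))
}

test_that("stratification axes are orthonormal and separate subpopulations", {
  fx <- strat_fixture()
  ax <- stratification_axes(fx$ds, 3)
  sc <- attr(ax, "scores")
  expect_equal(crossprod(sc), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_gt(abs(stats::cor(sc[, 1], fx$pop)), 0.9)
  # sign convention: the largest-magnitude loading is positive
  for (j in 1:3) expect_gt(sc[which.max(abs(sc[, j])), j], 0)
  expect_error(stratification_axes(fx$ds, 60), "rank")
})

test_that("duplicated individuals receive identical scores", {
  set.seed(62)
  calls <- matrix(stats::rbinom(10 * 200, 2, 0.4), 10)
  calls <- rbind(calls, calls[3, ])
  ds <- make_geno(calls)
  sc <- attr(stratification_axes(ds, 2), "scores")
  expect_equal(sc[3, ], sc[11, ], tolerance = 1e-9)
})

test_that("with zero axes the scan reduces to the plain score test", {
  set.seed(63)
  n <- 30
  g <- matrix(stats::rbinom(n * 50, 2, 0.4), n)
  ds <- make_geno(g)
  y <- stats::rnorm(n)
  sc <- egscore_scan(tibble::tibble(animal = ds$samples, debv = y), ds,
                     opts = gwas_options(n_axes = 0))
  # oracle: (n - 1) * squared correlation, chi-square on 1 df
  r2 <- apply(g, 2, function(gg) stats::cor(gg, y)^2)
  expect_equal(sc$chi2, (n - 1) * r2, tolerance = 1e-10)
  expect_equal(sc$p, stats::pchisq((n - 1) * r2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("scan is invariant to sample order and phenotype rescaling", {
  fx <- strat_fixture(n_per = 20, m = 150, seed = 64)
  set.seed(64)
  y <- stats::rnorm(40)
  ph <- tibble::tibble(animal = fx$ds$samples, debv = y)
  s1 <- egscore_scan(ph, fx$ds)
  perm <- sample(40)
  s2 <- egscore_scan(ph[perm, ], subset_geno(fx$ds, samples = perm))
  expect_equal(s1$p, s2$p, tolerance = 1e-9)
  ph3 <- dplyr::mutate(ph, debv = 3 * debv + 7)
  s3 <- egscore_scan(ph3, fx$ds)
  expect_equal(s1$p, s3$p, tolerance = 1e-9)
  expect_equal(s3$beta, 3 * s1$beta, tolerance = 1e-9)
})

test_that("missing genotypes are handled per SNP without bias", {
  set.seed(65)
  n <- 36
  g <- matrix(stats::rbinom(n * 60, 2, 0.4), n)
  g[sample(length(g), 100)] <- NA
  ds <- make_geno(g)
  y <- stats::rnorm(n)
  sc <- egscore_scan(tibble::tibble(animal = ds$samples, debv = y), ds,
                     opts = gwas_options(n_axes = 0))
  # oracle per SNP on complete cases
  j <- which(colSums(is.na(g)) > 0)[1]
  ok <- !is.na(g[, j])
  r2 <- stats::cor(g[ok, j], y[ok])^2
  expect_equal(sc$chi2[sc$snp == ds$snps$id[j]], (sum(ok) - 1) * r2,
               tolerance = 1e-10)
})

test_that("null scans are calibrated and genomic control behaves", {
  set.seed(66)
  n <- 42
  g <- matrix(stats::rbinom(n * 1500, 2, 0.3), n)
  ds <- make_geno(g, chrom = rep(1:3, each = 500))
  sc <- egscore_scan(tibble::tibble(animal = ds$samples,
                                    debv = stats::rnorm(n)), ds)
  expect_gt(mean(sc$p < 0.05), 0.03)
  expect_lt(mean(sc$p < 0.05), 0.07)
  res <- genomic_control(sc)
  expect_gt(res$lambda, 0.85)
  expect_lt(res$lambda, 1.15)
  # doubling every chi-square doubles the median-method lambda
  sc2 <- sc
  sc2$chi2 <- sc$chi2 * 2
  expect_equal(genomic_control(sc2)$lambda, 2 * res$lambda,
               tolerance = 1e-12)
  # lambda exactly 1 leaves p untouched in multiply mode
  sc3 <- sc
  sc3$chi2 <- stats::qchisq(seq(0.001, 0.999, length.out = nrow(sc)), 1)
  res3 <- genomic_control(sc3)
  expect_equal(res3$lambda, 1, tolerance = 1e-3)
  expect_equal(res3$scan$p_adj, pmin(1, sc3$p * res3$lambda))
  # divide mode recomputes p from rescaled statistics
  res4 <- genomic_control(sc, gwas_options(lambda_mode = "divide"))
  expect_equal(res4$scan$p_adj,
               stats::pchisq(sc$chi2 / res4$lambda, 1, lower.tail = FALSE))
})

test_that("axes restore calibration under a confounded stratified null", {
  fx <- strat_fixture(n_per = 21, m = 800, fst_shift = 0.3, seed = 67)
  set.seed(67)
  y <- stats::rnorm(42) + 1.5 * fx$pop  # phenotype confounded with structure
  ph <- tibble::tibble(animal = fx$ds$samples, debv = y)
  lam_no <- genomic_control(
    egscore_scan(ph, fx$ds, opts = gwas_options(n_axes = 0)))$lambda
  lam_ax <- genomic_control(
    egscore_scan(ph, fx$ds, opts = gwas_options(n_axes = 3)))$lambda
  expect_gt(lam_no, lam_ax)
  expect_gt(lam_ax, 0.85)
  expect_lt(lam_ax, 1.15)
})

test_that("tier classification matches a brute-force comparator on a grid", {
  opts <- gwas_options()
  p <- c(10^seq(-9, 0, length.out = 200), 5e-6, 5e-5, 1)
  got <- classify_significance(p, opts)
  brute <- vapply(p, function(pp) {
    if (pp < 5e-6) "genome-wide" else if (pp < 5e-5) "suggestive" else "none"
  }, "")
  expect_identical(got, brute)
})

test_that("PVE plug-in identities hold", {
  expect_equal(estimate_pve(0, 0.3, 2), 0)
  expect_equal(estimate_pve(sqrt(2), 0.5, 2), 0.5)  # 2*0.25*beta^2 / 2
  expect_equal(estimate_pve(10, 0.5, 1), 1)  # capped
  expect_error(estimate_pve(1, 0, 1), "freq")
  expect_error(estimate_pve(1, 0.5, 0), "var_y")
  expect_equal(estimate_pve(NULL, NULL, NULL, method = "score",
                            chi2 = 10, n = 42), 10 / 50)
})

test_that("a planted QTL is recovered with an honest PVE estimate", {
  set.seed(68)
  n <- 200
  g <- matrix(stats::rbinom(n * 100, 2, 0.4), n)
  ds <- make_geno(g)
  q <- g[, 10]
  pq <- mean(q) / 2
  beta_true <- sqrt(0.2 / (2 * pq * (1 - pq)))
  y <- beta_true * (q - 2 * pq) + stats::rnorm(n, 0, sqrt(0.8))
  sc <- egscore_scan(tibble::tibble(animal = ds$samples, debv = y), ds,
                     opts = gwas_options(n_axes = 0))
  hit <- sc[sc$snp == ds$snps$id[10], ]
  expect_lt(hit$p, 1e-6)
  pve <- estimate_pve(hit$beta, hit$freq, stats::var(y))
  expect_gt(pve, 0.1)
  expect_lt(pve, 0.3)
})

test_that("GFF3 feature annotation distinguishes exon/intron/upstream", {
  skip_if_not_installed("rtracklayer")
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\ttest\tgene\t10000\t20000\t.\t+\t.\tID=gene1;Name=GENE1",
    "1\ttest\texon\t10000\t12000\t.\t+\t.\tID=exon1;Parent=gene1",
    "1\ttest\texon\t18000\t20000\t.\t+\t.\tID=exon2;Parent=gene1",
    "1\ttest\tgene\t50000\t60000\t.\t-\t.\tID=gene2;Name=GENE2",
    "1\ttest\texon\t50000\t60000\t.\t-\t.\tID=exon3;Parent=gene2"
  ), gff)
  snps <- tibble::tibble(
    snp = c("in_exon", "in_intron", "upstream_plus", "upstream_minus",
            "lonely"),
    chrom = 1L,
    bp = c(11000, 15000, 8000, 62000, 200000)
  )
  ann <- annotate_snp_feature(snps, gff, upstream_window = 5000)
  expect_equal(ann$feature_type,
               c("exon variant", "intron variant", "upstream gene variant",
                 "upstream gene variant", "intergenic"))
  expect_equal(ann$gene[1:4], c("GENE1", "GENE1", "GENE1", "GENE2"))
  expect_true(is.na(ann$gene[5]))
})
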