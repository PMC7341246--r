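#' Association-scan options
#'
#' @param n_axes Number of stratification axes regressed out (default 3).
#' @param lambda_method `"median"` (median observed chi-square over 0.4549)
#'   or `"regression"` (sorted observed on expected null quantiles through
#'   the origin).
#' @param lambda_mode `"multiply"` adjusts p-values as `min(1, p * lambda)`
#'   (the literal published rule, appropriate for deflation, `lambda < 1`);
#'   `"divide"` rescales the chi-square statistics by `lambda` (the
#'   conventional genomic-control direction for inflation).
#' @param threshold_genomewide,threshold_suggestive Significance tiers
#'   (genome-wide must be the smaller).
#' @param pve_method `"freq"` for `2 p (1-p) beta^2 / var(y)`, `"score"`
#'   for the statistic-based `chi2 / (chi2 + n - 2)`.
#' @return List of class `gwas_options`.
#' @export
gwas_options <- function(n_axes = 3L,
                         lambda_method = c("median", "regression"),
                         lambda_mode = c("multiply", "divide"),
                         threshold_genomewide = 5e-6,
                         threshold_suggestive = 5e-5,
                         pve_method = c("freq", "score")) {
  if (threshold_genomewide >= threshold_suggestive) {
    stop("genome-wide threshold must be below the suggestive one",
         call. = FALSE)
  }
  structure(list(n_axes = as.integer(n_axes),
                 lambda_method = match.arg(lambda_method),
                 lambda_mode = match.arg(lambda_mode),
                 threshold_genomewide = threshold_genomewide,
                 threshold_suggestive = threshold_suggestive,
                 pve_method = match.arg(pve_method)),
            class = "gwas_options")
}

#' Principal-component stratification axes
#'
#' Top eigenvectors of the sample covariance of genotype columns centred by
#' `2 p` and scaled by `sqrt(2 p (1 - p))` (missing calls are mean-imputed
#' for the decomposition only; monomorphic SNPs are dropped). Axes are
#' orthonormal and deterministic up to sign, fixed so each axis's
#' largest-magnitude loading is positive.
#'
#' @param ds A QC-passed [geno_dataset()].
#' @param n_axes Number of axes (must be below the matrix rank).
#' @return Tibble with `sample` and `axis1..axisK`; the numeric score
#'   matrix is attached as attribute `scores`.
#' @export
stratification_axes <- function(ds, n_axes = 3L) {
  validate_geno_dataset(ds)
  g <- ds$calls
  p <- colMeans(g, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g <- g[, keep, drop = FALSE]
  p <- p[keep]
  gs <- sweep(g, 2L, 2 * p)
  gs[is.na(gs)] <- 0  # mean imputation after centring
  gs <- sweep(gs, 2L, sqrt(2 * p * (1 - p)), "/")
  k <- tcrossprod(gs) / ncol(gs)
  ev <- eigen(k, symmetric = TRUE)
  rank <- sum(ev$values > max(ev$values) * 1e-9)
  if (n_axes >= rank) {
    stop("n_axes (", n_axes, ") must be below the covariance rank (", rank,
         ")", call. = FALSE)
  }
  axes <- ev$vectors[, seq_len(n_axes), drop = FALSE]
  for (j in seq_len(ncol(axes))) {
    if (axes[which.max(abs(axes[, j])), j] < 0) axes[, j] <- -axes[, j]
  }
  colnames(axes) <- paste0("axis", seq_len(n_axes))
  out <- tibble::as_tibble(axes)
  out <- dplyr::bind_cols(tibble::tibble(sample = ds$samples), out)
  attr(out, "scores") <- axes
  out
}

#' Stratification-corrected single-SNP score scan
#'
#' For every SNP, both the phenotype and the genotype dosage are
#' residualised on the stratification axes (with intercept); the score
#' statistic is `chi2 = (n - n_axes - 1) * r^2` of the residuals on one
#' degree of freedom, the slope is the residual regression coefficient and
#' `SE = |beta| / sqrt(chi2)`. With zero axes this reduces to the plain
#' single-SNP score test. Animals are matched between phenotype and
#' genotypes by an inner join; SNPs monomorphic in the joined set are
#' skipped.
#'
#' @param phenotypes Tibble with `animal` and a phenotype column (default
#'   name `debv`; use `trait_col` to pick another, e.g. a deregressed-EBV
#'   column from [deregress_ebv()]).
#' @param ds A QC-passed [geno_dataset()].
#' @param axes Axis tibble from [stratification_axes()], or `NULL` to
#'   compute `opts$n_axes` axes from `ds`. Use `n_axes = 0` for no
#'   correction.
#' @param opts A [gwas_options()] bundle.
#' @param trait_col Phenotype column name.
#' @return Tibble of class `gwas_scan` with one row per tested SNP: `snp`,
#'   `chrom`, `bp`, `freq` (A1 frequency in the joined set), `beta`, `se`,
#'   `chi2` and `p` (raw). Attributes: `n` (animals used), `n_axes`,
#'   `n_skipped` (monomorphic), `phenotype_var`.
#' @export
egscore_scan <- function(phenotypes, ds, axes = NULL, opts = gwas_options(),
                         trait_col = "debv") {
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!trait_col %in% names(phenotypes)) {
    stop("phenotypes lack column `", trait_col, "`", call. = FALSE)
  }
  common <- intersect(ds$samples, phenotypes$animal)
  if (length(common) < 5L) stop("fewer than 5 matched animals", call. = FALSE)
  ds <- subset_geno(ds, samples = common)
  y <- phenotypes[[trait_col]][match(ds$samples, phenotypes$animal)]
  n <- length(y)
  if (is.null(axes)) {
    axes_mat <- if (opts$n_axes > 0) {
      attr(stratification_axes(ds, opts$n_axes), "scores")
    } else NULL
  } else {
    am <- attr(axes, "scores")
    if (is.null(am)) am <- as.matrix(axes[match(ds$samples, axes$sample),
                                          -1, drop = FALSE])
    else am <- am[match(ds$samples, axes$sample), , drop = FALSE]
    axes_mat <- am
  }
  k <- if (is.null(axes_mat)) 0L else ncol(axes_mat)
  qq <- qr(cbind(rep(1, n), axes_mat))
  yr <- qr.resid(qq, y)
  g <- ds$calls
  # residualise genotypes; SNPs with missing calls handled per SNP
  has_na <- colSums(is.na(g)) > 0L
  gr <- matrix(NA_real_, n, ncol(g))
  if (any(!has_na)) {
    gr[, !has_na] <- qr.resid(qq, g[, !has_na, drop = FALSE])
  }
  yr_list <- NULL
  ss_y <- sum(yr^2)
  beta <- se <- chi2 <- pval <- rep(NA_real_, ncol(g))
  freq <- colMeans(g, na.rm = TRUE) / 2
  for (j in seq_len(ncol(g))) {
    if (has_na[j]) {
      okn <- !is.na(g[, j])
      if (sum(okn) < k + 3L) next
      qj <- qr(cbind(rep(1, sum(okn)), axes_mat[okn, , drop = FALSE]))
      grj <- qr.resid(qj, g[okn, j])
      yrj <- qr.resid(qj, y[okn])
      nj <- sum(okn)
    } else {
      grj <- gr[, j]
      yrj <- yr
      nj <- n
    }
    ssg <- sum(grj^2)
    if (ssg <= .Machine$double.eps * nj) next  # monomorphic after join
    sxy <- sum(grj * yrj)
    ssyj <- if (has_na[j]) sum(yrj^2) else ss_y
    r2 <- sxy^2 / (ssg * ssyj)
    chi2[j] <- (nj - k - 1) * r2
    beta[j] <- sxy / ssg
    se[j] <- if (chi2[j] > 0) abs(beta[j]) / sqrt(chi2[j]) else NA_real_
    pval[j] <- stats::pchisq(chi2[j], df = 1, lower.tail = FALSE)
  }
  ok <- !is.na(chi2)
  out <- tibble::tibble(
    snp = ds$snps$id[ok], chrom = ds$snps$chrom[ok], bp = ds$snps$bp[ok],
    freq = freq[ok], beta = beta[ok], se = se[ok], chi2 = chi2[ok],
    p = pval[ok]
  )
  attr(out, "n") <- n
  attr(out, "n_axes") <- k
  attr(out, "n_skipped") <- sum(!ok)
  attr(out, "phenotype_var") <- stats::var(y)
  class(out) <- c("gwas_scan", class(out))
  out
}

#' Genomic-control adjustment
#'
#' Estimates the inflation/deflation factor `lambda` of the scan statistics
#' (median observed chi-square over its null median 0.4549, or a
#' through-origin regression of sorted observed on expected quantiles) and
#' adjusts the p-values. The default mode multiplies p by `lambda` capped
#' at 1, exactly the published deflation rule; `"divide"` mode rescales the
#' chi-square by `lambda` instead. Q-Q coordinates (expected vs observed
#' `-log10 p`) are attached for plotting.
#'
#' @param scan A [egscore_scan()] table.
#' @param opts A [gwas_options()] bundle.
#' @return List of class `gwas_result`: `lambda`, `lambda_method`,
#'   `lambda_mode`, `scan` (the input tibble with `p_adj` and `tier`
#'   columns added) and `qq` (tibble `expected`, `observed`).
#' @export
genomic_control <- function(scan, opts = gwas_options()) {
  m <- nrow(scan)
  if (m < 1L) stop("empty scan", call. = FALSE)
  if (m < 100L) {
    warning("fewer than 100 SNPs; lambda estimate will be unstable",
            call. = FALSE)
  }
  null_med <- stats::qchisq(0.5, df = 1)
  lambda <- switch(
    opts$lambda_method,
    median = stats::median(scan$chi2) / null_med,
    regression = {
      expq <- stats::qchisq(stats::ppoints(m), df = 1)
      obs <- sort(scan$chi2)
      sum(expq * obs) / sum(expq^2)
    }
  )
  scan2 <- scan
  if (opts$lambda_mode == "multiply") {
    scan2$p_adj <- pmin(1, scan$p * lambda)
  } else {
    scan2$p_adj <- stats::pchisq(scan$chi2 / lambda, df = 1,
                                 lower.tail = FALSE)
  }
  scan2$tier <- classify_significance(scan2$p_adj, opts)
  qq <- tibble::tibble(
    expected = -log10(stats::ppoints(m)),
    observed = sort(-log10(scan$p), decreasing = TRUE)
  )
  structure(list(lambda = lambda, lambda_method = opts$lambda_method,
                 lambda_mode = opts$lambda_mode, scan = scan2, qq = qq),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("<gwas_result> lambda =", signif(x$lambda, 4), "(",
      x$lambda_method, "/", x$lambda_mode, ")\n")
  cat("  tiers:", sum(x$scan$tier == "genome-wide"), "genome-wide,",
      sum(x$scan$tier == "suggestive"), "suggestive of", nrow(x$scan),
      "SNPs\n")
  invisible(x)
}

#' @rdname genomic_control
#' @param x A `gwas_result`.
#' @param ... Unused.
#' @method tidy gwas_result
#' @export
tidy.gwas_result <- function(x, ...) x$scan

#' @rdname genomic_control
#' @method glance gwas_result
#' @export
glance.gwas_result <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_snps = nrow(x$scan),
                 n_genomewide = sum(x$scan$tier == "genome-wide"),
                 n_suggestive = sum(x$scan$tier == "suggestive"))
}

#' Significance tier of adjusted p-values
#'
#' `p < threshold_genomewide` is `"genome-wide"`, otherwise
#' `p < threshold_suggestive` is `"suggestive"`, otherwise `"none"`.
#'
#' @param p Vector of (adjusted) p-values in (0, 1].
#' @param opts A [gwas_options()] bundle carrying the two thresholds.
#' @return Character vector of tiers.
#' @export
#' @examples
#' classify_significance(c(9.53e-7, 2.72e-5, 1))
classify_significance <- function(p, opts = gwas_options()) {
  ifelse(p < opts$threshold_genomewide, "genome-wide",
         ifelse(p < opts$threshold_suggestive, "suggestive", "none"))
}

#' Per-SNP proportion of variance explained
#'
#' Default (`method = "freq"`): `PVE = 2 p (1-p) beta^2 / var_y`, capped at
#' 1. Alternative (`method = "score"`): `chi2 / (chi2 + n - 2)`, the
#' squared-correlation form derived from the test statistic itself.
#'
#' @param beta Allele-substitution slope(s).
#' @param freq A1 allele frequency(ies), strictly inside (0, 1).
#' @param var_y Phenotype variance (> 0).
#' @param method `"freq"` or `"score"`.
#' @param chi2,n Statistic and sample size, needed for `"score"`.
#' @return Numeric PVE in \[0, 1\].
#' @export
estimate_pve <- function(beta, freq, var_y, method = c("freq", "score"),
                         chi2 = NULL, n = NULL) {
  method <- match.arg(method)
  if (method == "freq") {
    if (any(freq <= 0 | freq >= 1)) stop("freq must be in (0,1)", call. = FALSE)
    if (var_y <= 0) stop("var_y must be > 0", call. = FALSE)
    pmin(1, 2 * freq * (1 - freq) * beta^2 / var_y)
  } else {
    if (is.null(chi2) || is.null(n)) {
      stop("method 'score' needs chi2 and n", call. = FALSE)
    }
    chi2 / (chi2 + n - 2)
  }
}

#' Annotate SNPs against a GFF3 gene model
#'
#' Interval lookup of each SNP against gene and exon features: inside a
#' gene the label is `"exon variant"` or `"intron variant"`; within
#' `upstream_window` bp 5' of a gene (strand-aware) it is
#' `"upstream gene variant"`; otherwise `"intergenic"`. The gene name is
#' attached for non-intergenic SNPs. Chromosome names are matched as
#' characters; a mismatch count is warned about.
#'
#' @param snps Tibble with `snp`, `chrom`, `bp` (e.g. a scan table).
#' @param gff3 Path to a GFF3 file with `gene` (and ideally `exon`)
#'   features.
#' @param upstream_window Upstream window in bp (default 5000).
#' @return `snps` with `feature_type` and `gene` columns appended.
#' @export
annotate_snp_feature <- function(snps, gff3, upstream_window = 5000) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package ", pkg, " is required for annotation", call. = FALSE)
    }
  }
  ann <- rtracklayer::import(gff3, format = "gff3")
  genes <- ann[ann$type == "gene"]
  exons <- ann[ann$type == "exon"]
  gene_name <- genes$Name
  if (is.null(gene_name)) gene_name <- genes$ID
  gene_name <- as.character(gene_name)
  snp_chr <- as.character(snps$chrom)
  unmatched <- sum(!snp_chr %in%
                     unique(as.character(GenomicRanges::seqnames(genes))))
  if (unmatched > 0L) {
    warning(unmatched, " SNP(s) on chromosomes absent from the annotation",
            call. = FALSE)
  }
  pts <- GenomicRanges::GRanges(snp_chr,
                                IRanges::IRanges(snps$bp, snps$bp))
  feature <- rep("intergenic", nrow(snps))
  gene <- rep(NA_character_, nrow(snps))

  in_gene <- GenomicRanges::findOverlaps(pts, genes, select = "first")
  hit <- !is.na(in_gene)
  in_exon <- IRanges::overlapsAny(pts, exons)
  feature[hit & in_exon] <- "exon variant"
  feature[hit & !in_exon] <- "intron variant"
  gene[hit] <- gene_name[in_gene[hit]]

  up <- GenomicRanges::promoters(genes, upstream = upstream_window,
                                 downstream = 0)
  in_up <- GenomicRanges::findOverlaps(pts, up, select = "first")
  uphit <- !hit & !is.na(in_up)
  feature[uphit] <- "upstream gene variant"
  gene[uphit] <- gene_name[in_up[uphit]]

  out <- tibble::as_tibble(snps)
  out$feature_type <- feature
  out$gene <- gene
  out
}
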