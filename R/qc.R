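#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of every heterozygote count that is no
#' more probable than the observed one, where the probability of `h`
#' heterozygotes among `n` diploids with `nA` copies of the rarer allele is
#' `2^h n! nA! na! / (((nA-h)/2)! h! ((na-h)/2)! (2n)!)`. Monomorphic tables
#' return 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, total > 0).
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(57, 14, 50)
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be > 0", call. = FALSE)
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0L) return(1)  # monomorphic
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(h) up to the shared normalising constant
  logp <- hs * log(2) - lgamma((rare - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((2L * n - rare - hs) / 2 + 1)
  logp <- logp - max(logp)
  p_h <- exp(logp) / sum(exp(logp))
  obs <- p_h[match(n_Aa, hs)]
  min(1, sum(p_h[p_h <= obs * (1 + 1e-12)]))
}

#' Quality-control parameters
#'
#' Bundle of the marker- and sample-level thresholds applied by
#' [qc_filter()] and the LD-pruning settings used by [ld_prune()]. Defaults
#' are the standard 50K-array settings: SNP and sample call rate >= 0.95,
#' MAF >= 0.01, HWE exact p > 0.001, pruning with 50-SNP windows shifted by
#' 5 SNPs at an r-squared ceiling of 0.5, autosomes 1-29 (cattle).
#'
#' @param min_call_rate_snp,min_call_rate_sample Minimum call fraction.
#' @param min_maf Minimum minor allele frequency.
#' @param hwe_alpha SNPs with exact HWE p <= `hwe_alpha` are removed.
#' @param autosomes Integer chromosome codes retained.
#' @param prune_window,prune_step,prune_r2 LD-pruning window (SNPs), shift
#'   (SNPs) and maximum pairwise r-squared.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_call_rate_snp = 0.95,
                      min_call_rate_sample = 0.95,
                      min_maf = 0.01,
                      hwe_alpha = 0.001,
                      autosomes = 1:29,
                      prune_window = 50L,
                      prune_step = 5L,
                      prune_r2 = 0.5) {
  fr <- c(min_call_rate_snp, min_call_rate_sample, min_maf, hwe_alpha)
  if (any(fr < 0 | fr > 1)) stop("rates must be in [0,1]", call. = FALSE)
  if (prune_step > prune_window) {
    stop("prune_step must be <= prune_window", call. = FALSE)
  }
  structure(
    list(min_call_rate_snp = min_call_rate_snp,
         min_call_rate_sample = min_call_rate_sample,
         min_maf = min_maf, hwe_alpha = hwe_alpha,
         autosomes = as.integer(autosomes),
         prune_window = as.integer(prune_window),
         prune_step = as.integer(prune_step),
         prune_r2 = prune_r2),
    class = "qc_params"
  )
}

#' Marker and sample quality control
#'
#' Applies the filters in a fixed, logged order: (1) drop non-autosomal or
#' unmapped SNPs, (2) drop samples with call rate below
#' `min_call_rate_sample`, (3) drop SNPs with call rate below
#' `min_call_rate_snp`, (4) drop SNPs with MAF below `min_maf` (computed on
#' non-missing calls), (5) drop SNPs with HWE exact p <= `hwe_alpha`.
#' Applying the filter twice yields the same dataset as once.
#'
#' @param ds A [geno_dataset()].
#' @param params A [qc_params()] bundle.
#' @return Object of class `qc_result`: a list with `data` (the filtered
#'   `geno_dataset`) and `report` (tibble of per-step removal tallies, also
#'   available via [tidy()][generics::tidy]).
#' @export
qc_filter <- function(ds, params = qc_params()) {
  validate_geno_dataset(ds)
  steps <- list()
  note <- function(step, axis, removed, retained) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      step = step, axis = axis, removed = removed, retained = retained
    )
  }

  keep <- ds$snps$chrom %in% params$autosomes & ds$snps$bp >= 1
  note("non_autosomal", "snp", sum(!keep), sum(keep))
  ds <- subset_geno(ds, snps = keep)

  cr_sample <- rowMeans(!is.na(ds$calls))
  keep_s <- cr_sample >= params$min_call_rate_sample
  note("sample_call_rate", "sample", sum(!keep_s), sum(keep_s))
  ds <- subset_geno(ds, samples = keep_s)
  if (n_samples(ds) == 0L) stop("no samples left after call-rate filter",
                                call. = FALSE)

  cr_snp <- colMeans(!is.na(ds$calls))
  keep <- cr_snp >= params$min_call_rate_snp
  note("snp_call_rate", "snp", sum(!keep), sum(keep))
  ds <- subset_geno(ds, snps = keep)

  keep <- !is.na(maf(ds)) & maf(ds) >= params$min_maf
  note("maf", "snp", sum(!keep), sum(keep))
  ds <- subset_geno(ds, snps = keep)

  hwe_p <- vapply(seq_len(n_snps(ds)), function(j) {
    g <- ds$calls[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    hwe_exact_test(sum(g == 2L), sum(g == 1L), sum(g == 0L))
  }, numeric(1))
  keep <- hwe_p > params$hwe_alpha
  note("hwe", "snp", sum(!keep), sum(keep))
  ds <- subset_geno(ds, snps = keep)

  if (n_snps(ds) == 0L) stop("no SNPs left after quality control",
                             call. = FALSE)
  structure(list(data = ds, report = dplyr::bind_rows(steps),
                 params = params),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(x$report)
  print(x$data)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname qc_filter
#' @param x A `qc_result`.
#' @param ... Unused.
#' @method tidy qc_result
#' @export
tidy.qc_result <- function(x, ...) x$report

#' Greedy windowed LD pruning
#'
#' Within every window of `window` consecutive SNPs (windows never span
#' chromosomes, advancing by `step`), while any retained pair has squared
#' genotype correlation above `r2_max`, one member of the currently worst
#' pair is removed: the lower-MAF SNP, with ties broken by removing the
#' later-positioned one. The retained set is reproducible for fixed input,
#' and afterwards no surviving within-window pair exceeds `r2_max`.
#'
#' @param ds A QC-passed [geno_dataset()].
#' @param window Window size in SNPs (>= 2).
#' @param step Window shift in SNPs.
#' @param r2_max Maximum tolerated pairwise r-squared.
#' @return Character vector of retained SNP IDs, in map order.
#' @export
ld_prune <- function(ds, window = 50L, step = 5L, r2_max = 0.5) {
  validate_geno_dataset(ds)
  if (window < 2L) stop("window must be >= 2 SNPs", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  keep <- rep(TRUE, n_snps(ds))
  snp_maf <- maf(ds)
  for (ch in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == ch)
    m <- length(idx)
    starts <- if (m <= window) 0L else seq.int(0L, m - window, by = step)
    if (m > window && (m - window) %% step != 0L) {
      starts <- c(starts, m - window)  # terminal window covers the tail
    }
    for (s in starts) {
      win <- idx[(s + 1L):min(s + window, m)]
      repeat {
        act <- win[keep[win]]
        if (length(act) < 2L) break
        r2 <- suppressWarnings(
          stats::cor(ds$calls[, act, drop = FALSE],
                     use = "pairwise.complete.obs")^2
        )
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        worst <- max(r2)
        if (worst <= r2_max) break
        hit <- which(r2 == worst, arr.ind = TRUE)[1L, ]
        pair <- act[sort(hit)]
        drop <- if (!isTRUE(all.equal(snp_maf[pair[1]], snp_maf[pair[2]])) &&
                    snp_maf[pair[1]] != snp_maf[pair[2]]) {
          pair[which.min(snp_maf[pair])]
        } else {
          pair[2L]  # equal MAF: drop the later-positioned SNP
        }
        keep[drop] <- FALSE
      }
    }
  }
  ds$snps$id[keep]
}
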