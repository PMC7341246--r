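#' Construct a genotype dataset
#'
#' The central container of the package: a samples-by-SNPs matrix of allele
#' dosages together with the SNP map. Dosages count copies of the A1 allele,
#' so each call is 0, 1, 2 or `NA` (missing). SNPs are kept strictly sorted
#' by chromosome then physical position; positions are 1-based (BIM
#' convention) and all intervals derived downstream inherit that convention.
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns. Values must
#'   be 0, 1, 2 or `NA`.
#' @param snps Data frame with one row per SNP and columns `id`, `chrom`
#'   (integer autosome code), `bp` (1-based position) and optionally `a1`,
#'   `a2` (allele labels, defaulting to `"A"`/`"B"`).
#' @param samples Character vector of unique sample IDs; defaults to the row
#'   names of `calls`.
#'
#' @return An object of class `geno_dataset` with fields `samples` (character
#'   vector), `snps` (tibble) and `calls` (integer matrix).
#' @export
#' @examples
#' g <- geno_dataset(
#'   calls = matrix(c(0L, 1L, 2L, NA, 2L, 0L), nrow = 2),
#'   snps = data.frame(id = c("s1", "s2", "s3"), chrom = 1L, bp = c(100, 200, 300)),
#'   samples = c("a", "b")
#' )
#' n_snps(g)
geno_dataset <- function(calls, snps, samples = rownames(calls)) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix", call. = FALSE)
  storage.mode(calls) <- "integer"
  snps <- tibble::as_tibble(snps)
  if (!all(c("id", "chrom", "bp") %in% names(snps))) {
    stop("`snps` needs columns id, chrom, bp", call. = FALSE)
  }
  if (!"a1" %in% names(snps)) snps$a1 <- "A"
  if (!"a2" %in% names(snps)) snps$a2 <- "B"
  snps$chrom <- as.integer(snps$chrom)
  snps$bp <- as.double(snps$bp)
  snps$id <- as.character(snps$id)
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(calls)))
  samples <- as.character(samples)
  ds <- structure(
    list(samples = samples, snps = snps, calls = unname(calls)),
    class = "geno_dataset"
  )
  validate_geno_dataset(ds)
}

#' Validate a genotype dataset's invariants
#'
#' Checks sample uniqueness, legal genotype codes, SNP sort order and the
#' absence of duplicate (chrom, bp, id) triples. Called by the constructor
#' and by the readers; users rarely need it directly.
#'
#' @param ds A `geno_dataset`.
#' @return `ds`, invisibly modified only by reordering checks (never data).
#' @export
validate_geno_dataset <- function(ds) {
  stopifnot(inherits(ds, "geno_dataset"))
  if (anyDuplicated(ds$samples)) {
    stop("duplicate sample IDs: ",
         paste(unique(ds$samples[duplicated(ds$samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ds$calls) != length(ds$samples)) {
    stop("call matrix rows (", nrow(ds$calls), ") != number of samples (",
         length(ds$samples), ")", call. = FALSE)
  }
  if (ncol(ds$calls) != nrow(ds$snps)) {
    stop("call matrix columns != number of SNPs", call. = FALSE)
  }
  bad <- !(ds$calls %in% c(0L, 1L, 2L) | is.na(ds$calls))
  if (any(bad)) stop("illegal genotype codes (must be 0/1/2/NA)", call. = FALSE)
  key <- order(ds$snps$chrom, ds$snps$bp)
  if (!identical(key, seq_len(nrow(ds$snps)))) {
    stop("SNPs must be sorted by (chromosome, bp)", call. = FALSE)
  }
  if (anyDuplicated(ds$snps[, c("chrom", "bp", "id")])) {
    stop("duplicate (chrom, bp, id) SNP entries", call. = FALSE)
  }
  if (any(ds$snps$bp < 1)) stop("bp positions must be >= 1", call. = FALSE)
  invisible(ds)
}

#' @export
print.geno_dataset <- function(x, ...) {
  cat("<geno_dataset> ", length(x$samples), " samples x ", nrow(x$snps),
      " SNPs on ", length(unique(x$snps$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing call rate: ", format(round(miss, 4)), "\n", sep = "")
  invisible(x)
}

#' Number of samples / SNPs in a genotype dataset
#' @param ds A `geno_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(ds) length(ds$samples)

#' @rdname n_samples
#' @export
n_snps <- function(ds) nrow(ds$snps)

#' Subset a genotype dataset
#'
#' @param ds A `geno_dataset`.
#' @param samples Character IDs or logical/integer index of samples to keep.
#' @param snps Character IDs or logical/integer index of SNPs to keep (order
#'   is preserved from the dataset, never from the index).
#' @return A new `geno_dataset`.
#' @export
subset_geno <- function(ds, samples = NULL, snps = NULL) {
  keep_s <- seq_along(ds$samples)
  if (!is.null(samples)) {
    keep_s <- if (is.character(samples)) which(ds$samples %in% samples) else
      keep_s[samples]
  }
  keep_m <- seq_len(nrow(ds$snps))
  if (!is.null(snps)) {
    keep_m <- if (is.character(snps)) which(ds$snps$id %in% snps) else keep_m[snps]
    keep_m <- sort(keep_m)
  }
  geno_dataset(ds$calls[keep_s, keep_m, drop = FALSE],
               ds$snps[keep_m, , drop = FALSE],
               samples = ds$samples[keep_s])
}

#' Per-SNP allele frequency of the A1 allele
#'
#' Computed over non-missing calls only. SNPs with no non-missing call get
#' `NA`.
#'
#' @param ds A `geno_dataset`.
#' @return Numeric vector of length `n_snps(ds)`.
#' @export
allele_freq <- function(ds) {
  colMeans(ds$calls, na.rm = TRUE) / 2
}

#' Per-SNP minor allele frequency
#' @param ds A `geno_dataset`.
#' @return Numeric vector; `pmin(p, 1 - p)` of the A1 frequency.
#' @export
maf <- function(ds) {
  p <- allele_freq(ds)
  pmin(p, 1 - p)
}

#' SNP-covered chromosome lengths
#'
#' The default denominator of F_ROH: for every chromosome the span from the
#' first to the last genotyped SNP, inclusive 1-based coordinates
#' (`last - first + 1`).
#'
#' @param ds A `geno_dataset`.
#' @return Tibble with columns `chrom` and `length_bp`.
#' @export
covered_genome <- function(ds) {
  ds$snps |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(length_bp = max(.data$bp) - min(.data$bp) + 1,
                     .groups = "drop")
}
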