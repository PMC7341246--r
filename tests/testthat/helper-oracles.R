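# Independent oracles and small fixture builders shared across tests.

# Dense additive relationship matrix by the tabular method (independent of
# the package's Meuwissen-Luo / Henderson implementation).
tabular_a <- function(ped) {
  ped <- herdgen::pedigree_table(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  s <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  d <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      aij <- 0
      if (s[i] > 0L) aij <- aij + 0.5 * A[j, s[i]]
      if (d[i] > 0L) aij <- aij + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

# HWE exact p-value by direct choose()-based enumeration (no log-gamma).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hs, function(h) {
    n1 <- (nA - h) / 2
    n2 <- (na - h) / 2
    # multinomial count of genotype configurations x 2^h, normalised below
    exp(lchoose(n, n1) + lchoose(n - n1, h) + h * log(2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# quick genotype dataset builder: calls is samples x SNPs
make_geno <- function(calls, chrom = NULL, bp = NULL, samples = NULL) {
  m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep(1L, m)
  ord <- order(chrom)
  chrom <- chrom[ord]
  calls <- calls[, ord, drop = FALSE]
  if (!is.null(bp)) bp <- bp[ord]
  if (is.null(bp)) {
    bp <- stats::ave(seq_len(m), chrom, FUN = function(ix) {
      seq(1e5, by = 1e5, length.out = length(ix))
    })
  }
  if (is.null(samples)) samples <- sprintf("ind%03d", seq_len(nrow(calls)))
  herdgen::geno_dataset(
    calls,
    data.frame(id = sprintf("snp%04d", seq_len(m)), chrom = chrom, bp = bp),
    samples = samples
  )
}

# random pedigree with some inbred loops, <= n animals, for oracle checks
random_pedigree <- function(n, seed = 1) {
  set.seed(seed)
  animal <- sprintf("p%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  n_base <- max(4L, n %/% 4L)
  for (i in (n_base + 1L):n) {
    pr <- sample(seq_len(i - 1L), 2L)
    sire[i] <- animal[pr[1]]
    dam[i] <- animal[pr[2]]
  }
  tibble::tibble(animal = animal, sire = sire, dam = dam)
}

# reciprocal-overlap sensitivity of detected vs true segments
segment_sensitivity <- function(truth, detected, min_overlap = 0.7) {
  hit <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cand <- detected[detected$sample == truth$sample[i] &
                       detected$chrom == truth$chrom[i], ]
    if (nrow(cand) == 0L) next
    ov <- pmin(cand$end_bp, truth$end_bp[i]) -
      pmax(cand$start_bp, truth$start_bp[i]) + 1
    hit[i] <- any(ov >= min_overlap * truth$length_bp[i] &
                    ov >= min_overlap * cand$length_bp)
  }
  mean(hit)
}
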