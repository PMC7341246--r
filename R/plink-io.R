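# PLINK binary (.bed/.bim/.fam) and text (.ped/.map) readers/writers.
# .bed layout: 3 magic bytes (0x6c 0x1b 0x01 = SNP-major), then per SNP
# ceil(n/4) bytes, 2 bits per sample starting at the least significant pair:
# 00 = homozygous A1 (dosage 2), 01 = missing, 10 = heterozygous (1),
# 11 = homozygous A2 (0).

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# 256 x 4 lookup: byte value -> dosages of the 4 packed samples (LSB first)
.bed_decode_table <- local({
  two_bit <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255) {
    tab[b + 1L, ] <- two_bit[c(
      bitwAnd(b, 3L),
      bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L),
      bitwAnd(bitwShiftR(b, 6L), 3L)
    ) + 1L]
  }
  tab
})

#' Read PLINK genotypes
#'
#' Reads a PLINK fileset into a [geno_dataset()]. Both the binary
#' (`.bed`/`.bim`/`.fam`, SNP-major) and the text (`.ped`/`.map`) layouts are
#' supported; the format is chosen from the files present (or forced with
#' `format`). SNPs are re-sorted by (chromosome, position) if needed.
#'
#' @param prefix Path prefix of the fileset (without extension).
#' @param format `"auto"` (default), `"bed"` or `"ped"`.
#' @return A `geno_dataset`. Dosages count A1 alleles as in the `.bim` file.
#' @export
read_plink <- function(prefix, format = c("auto", "bed", "ped")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (file.exists(paste0(prefix, ".bed"))) "bed" else "ped"
  }
  if (format == "bed") read_plink_bed(prefix) else read_plink_ped(prefix)
}

read_plink_bed <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  fam_tbl <- utils::read.table(fam, header = FALSE, colClasses = "character")
  samples <- fam_tbl[[2]]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", fam, call. = FALSE)
  }
  bim_tbl <- utils::read.table(
    bim, header = FALSE,
    col.names = c("chrom", "id", "cm", "bp", "a1", "a2"),
    colClasses = c("integer", "character", "numeric", "numeric",
                   "character", "character")
  )
  n <- length(samples)
  m <- nrow(bim_tbl)
  bpl <- (n + 3L) %/% 4L  # bytes per SNP
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || !identical(raw[1:3], .bed_magic)) {
    stop("not a SNP-major PLINK .bed file (bad magic bytes): ", bed,
         call. = FALSE)
  }
  payload <- raw[-(1:3)]
  if (length(payload) != bpl * m) {
    stop("truncated or oversized .bed payload: expected ", bpl * m,
         " bytes, found ", length(payload), call. = FALSE)
  }
  codes <- .bed_decode_table[as.integer(payload) + 1L, , drop = FALSE]
  # row-block per SNP: bpl bytes -> 4*bpl dosages, keep first n
  calls <- matrix(t(codes), nrow = 4L * bpl)[seq_len(n), , drop = FALSE]
  snps <- bim_tbl[, c("id", "chrom", "bp", "a1", "a2")]
  ord <- order(snps$chrom, snps$bp)
  geno_dataset(calls[, ord, drop = FALSE], snps[ord, ], samples = samples)
}

read_plink_ped <- function(prefix) {
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  for (f in c(ped, map)) {
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  }
  map_tbl <- utils::read.table(
    map, header = FALSE, col.names = c("chrom", "id", "cm", "bp"),
    colClasses = c("integer", "character", "numeric", "numeric")
  )
  lines <- readLines(ped)
  toks <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map_tbl)
  samples <- vapply(toks, `[[`, "", 2L)
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", ped, call. = FALSE)
  }
  allele_mat <- t(vapply(toks, function(tk) {
    if (length(tk) != 6L + 2L * m) {
      stop("ped row with ", length(tk), " fields; expected ", 6L + 2L * m,
           call. = FALSE)
    }
    tk[-(1:6)]
  }, character(2L * m)))
  a_1 <- allele_mat[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a_2 <- allele_mat[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  # allele labels per SNP: first non-missing allele seen is A1 unless the
  # column is labelled A/B, in which case A = A1
  calls <- matrix(NA_integer_, nrow(allele_mat), m)
  a1_lab <- character(m)
  a2_lab <- character(m)
  for (j in seq_len(m)) {
    al <- c(a_1[, j], a_2[, j])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2L) {
      stop("more than two alleles at SNP ", map_tbl$id[j], call. = FALSE)
    }
    a1_lab[j] <- if (length(obs) >= 1L) obs[1L] else "A"
    a2_lab[j] <- if (length(obs) == 2L) obs[2L] else "B"
    g <- (a_1[, j] == a1_lab[j]) + (a_2[, j] == a1_lab[j])
    g[a_1[, j] == "0" | a_2[, j] == "0"] <- NA_integer_
    calls[, j] <- g
  }
  snps <- tibble::tibble(id = map_tbl$id, chrom = map_tbl$chrom,
                         bp = map_tbl$bp, a1 = a1_lab, a2 = a2_lab)
  ord <- order(snps$chrom, snps$bp)
  geno_dataset(calls[, ord, drop = FALSE], snps[ord, ], samples = samples)
}

#' Write PLINK genotypes
#'
#' Writes a [geno_dataset()] as a PLINK fileset. The binary writer is the
#' exact inverse of the reader, so a write/read round trip preserves the
#' genotype payload bit for bit.
#'
#' @param ds A `geno_dataset`.
#' @param prefix Output path prefix.
#' @param format `"bed"` (binary, default) or `"ped"` (text).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix, format = c("bed", "ped")) {
  format <- match.arg(format)
  validate_geno_dataset(ds)
  if (format == "bed") write_plink_bed(ds, prefix) else write_plink_ped(ds, prefix)
  invisible(prefix)
}

write_plink_bed <- function(ds, prefix) {
  n <- n_samples(ds)
  m <- n_snps(ds)
  bpl <- (n + 3L) %/% 4L
  # dosage -> 2-bit code
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2L] <- 0L
    out[!is.na(g) & g == 1L] <- 2L
    out[!is.na(g) & g == 0L] <- 3L
    out
  }
  pad <- 4L * bpl - n
  payload <- vapply(seq_len(m), function(j) {
    cc <- c(code_of(ds$calls[, j]), rep(0L, pad))
    dim(cc) <- c(4L, bpl)
    as.raw(cc[1L, ] + 4L * cc[2L, ] + 16L * cc[3L, ] + 64L * cc[4L, ])
  }, raw(bpl))
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  writeBin(as.raw(payload), con)
  utils::write.table(
    data.frame(ds$snps$chrom, ds$snps$id, 0, ds$snps$bp, ds$snps$a1, ds$snps$a2),
    paste0(prefix, ".bim"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
  utils::write.table(
    data.frame(ds$samples, ds$samples, 0, 0, 0, -9),
    paste0(prefix, ".fam"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
}

write_plink_ped <- function(ds, prefix) {
  n <- n_samples(ds)
  m <- n_snps(ds)
  al <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    g <- ds$calls[, j]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1L, ds$snps$a1[j], ds$snps$a2[j]))
    second <- ifelse(is.na(g), "0", ifelse(g == 2L, ds$snps$a1[j], ds$snps$a2[j]))
    al[, 2L * j - 1L] <- first
    al[, 2L * j] <- second
  }
  rows <- cbind(ds$samples, ds$samples, "0", "0", "0", "-9", al)
  writeLines(apply(rows, 1L, paste, collapse = " "), paste0(prefix, ".ped"))
  utils::write.table(
    data.frame(ds$snps$chrom, ds$snps$id, 0, ds$snps$bp),
    paste0(prefix, ".map"),
    quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t"
  )
}

#' Read a pedigree table
#'
#' Reads a 3+-column whitespace/tab-delimited file (animal, sire, dam; `0` or
#' `NA` meaning unknown parent) into the tibble layout used by the
#' quantitative-genetics functions.
#'
#' @param path Path to the TSV. A header line is auto-detected.
#' @return Tibble with character columns `animal`, `sire`, `dam` (`NA` for
#'   unknown parents).
#' @export
read_pedigree <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  header <- any(tolower(first) %in% c("animal", "id", "sire", "dam"))
  tbl <- utils::read.table(path, header = header, colClasses = "character")
  if (ncol(tbl) < 3L) stop("pedigree needs >= 3 columns", call. = FALSE)
  out <- tibble::tibble(animal = tbl[[1]], sire = tbl[[2]], dam = tbl[[3]])
  out$sire[out$sire %in% c("0", "NA", "")] <- NA_character_
  out$dam[out$dam %in% c("0", "NA", "")] <- NA_character_
  out
}

#' Write a pedigree table
#' @param ped Tibble with columns `animal`, `sire`, `dam`.
#' @param path Output path; unknown parents are written as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(
    animal = ped$animal,
    sire = ifelse(is.na(ped$sire), "0", ped$sire),
    dam = ifelse(is.na(ped$dam), "0", ped$dam)
  )
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
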