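#' Runs-of-homozygosity detection parameters
#'
#' Sliding-window criteria for [detect_roh()]. Defaults follow common
#' 50K-array practice for cattle: 15-SNP windows, at least 40 SNPs and 4 Mb
#' per run, at least one SNP per 100 kb, and no gap above 1 Mb between
#' consecutive SNPs inside a run. A window is called homozygous when it
#' carries at most `max_het_per_window` heterozygous and
#' `max_miss_per_window` missing calls; a SNP enters run state when at least
#' `snp_homozygosity_threshold` of the windows covering it are homozygous.
#'
#' @param window_snps Sliding-window size in SNPs.
#' @param min_snps Minimum SNPs per emitted run (>= `window_snps`).
#' @param min_density Minimum SNP density inside a run (SNPs per bp).
#' @param max_gap Maximum gap between consecutive SNPs in a run (bp).
#' @param min_length Minimum run length (bp).
#' @param max_het_per_window,max_miss_per_window Window allowances.
#' @param snp_homozygosity_threshold Fraction of homozygous covering windows
#'   required for run state.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 15L,
                       min_snps = 40L,
                       min_density = 1 / 100000,
                       max_gap = 1e6,
                       min_length = 4e6,
                       max_het_per_window = 1L,
                       max_miss_per_window = 1L,
                       snp_homozygosity_threshold = 0.05) {
  if (min_length <= 0) stop("min_length must be > 0", call. = FALSE)
  if (window_snps > min_snps) {
    stop("window_snps must be <= min_snps", call. = FALSE)
  }
  structure(
    list(window_snps = as.integer(window_snps),
         min_snps = as.integer(min_snps),
         min_density = min_density, max_gap = max_gap,
         min_length = min_length,
         max_het_per_window = as.integer(max_het_per_window),
         max_miss_per_window = as.integer(max_miss_per_window),
         snp_homozygosity_threshold = snp_homozygosity_threshold),
    class = "roh_params"
  )
}

# run-state vector for one individual on one chromosome
.roh_run_state <- function(het, mis, p) {
  m <- length(het)
  w <- p$window_snps
  nw <- m - w + 1L
  if (nw < 1L) return(logical(m))
  ch <- c(0, cumsum(het))
  cm <- c(0, cumsum(mis))
  hom_win <- (ch[(w + 1L):(m + 1L)] - ch[1:nw]) <= p$max_het_per_window &
    (cm[(w + 1L):(m + 1L)] - cm[1:nw]) <= p$max_miss_per_window
  # SNP i is covered by windows max(1, i-w+1) .. min(i, nw)
  cw <- c(0, cumsum(hom_win))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  n_hom <- cw[hi + 1L] - cw[lo]
  frac <- n_hom / (hi - lo + 1L)
  frac >= p$snp_homozygosity_threshold
}

# split a candidate run of SNP indices at gaps > max_gap, then apply the
# count/length/density filters; returns list of index vectors
.roh_finalize <- function(run_idx, bp, p) {
  if (length(run_idx) == 0L) return(list())
  gaps <- diff(bp[run_idx])
  cut <- which(gaps > p$max_gap)
  starts <- c(1L, cut + 1L)
  ends <- c(cut, length(run_idx))
  pieces <- Map(function(s, e) run_idx[s:e], starts, ends)
  Filter(function(ix) {
    len <- bp[ix[length(ix)]] - bp[ix[1]] + 1
    length(ix) >= p$min_snps &&
      len >= p$min_length &&
      length(ix) / len >= p$min_density
  }, pieces)
}

#' Detect runs of homozygosity
#'
#' Sliding-window (consensus) ROH detection. For every individual and
#' chromosome a `window_snps`-wide window slides one SNP at a time; SNPs
#' whose covering windows are sufficiently often homozygous form candidate
#' runs, which are split at gaps above `max_gap` and then filtered on SNP
#' count, physical length and SNP density. Chromosomes with fewer SNPs than
#' one window are skipped with a warning. Intended input is the LD-pruned
#' dataset.
#'
#' @param ds A [geno_dataset()].
#' @param params A [roh_params()] bundle.
#' @return Tibble of class `roh_segments`, sorted by (sample, chrom, start),
#'   with columns `sample`, `chrom`, `start_bp`, `end_bp`, `n_snps` and
#'   `length_bp` (`end - start + 1`). The covered-genome table of `ds` is
#'   attached as attribute `covered_genome`.
#' @export
detect_roh <- function(ds, params = roh_params()) {
  validate_geno_dataset(ds)
  p <- params
  short <- character(0)
  rows <- list()
  for (ch in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == ch)
    if (length(idx) < p$window_snps) {
      short <- c(short, as.character(ch))
      next
    }
    bp <- ds$snps$bp[idx]
    calls <- ds$calls[, idx, drop = FALSE]
    for (s in seq_len(n_samples(ds))) {
      g <- calls[s, ]
      state <- .roh_run_state(!is.na(g) & g == 1L, is.na(g), p)
      r <- rle(state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        for (ix in .roh_finalize(starts[k]:ends[k], bp, p)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample = ds$samples[s], chrom = ch,
            start_bp = bp[ix[1]], end_bp = bp[ix[length(ix)]],
            n_snps = length(ix)
          )
        }
      }
    }
  }
  if (length(short) > 0L) {
    warning("chromosome(s) with fewer SNPs than one window skipped: ",
            paste(short, collapse = ", "), call. = FALSE)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(sample = character(), chrom = integer(),
                   start_bp = double(), end_bp = double(), n_snps = integer())
  out$length_bp <- out$end_bp - out$start_bp + 1
  out <- dplyr::arrange(out, .data$sample, .data$chrom, .data$start_bp)
  attr(out, "covered_genome") <- covered_genome(ds)
  attr(out, "samples") <- ds$samples
  class(out) <- c("roh_segments", class(out))
  out
}

#' Genomic inbreeding from ROH segments
#'
#' `F_ROH` for an individual is the summed length of its ROH segments at or
#' above `min_length`, divided by the total covered autosome length. An
#' individual without qualifying segments gets `F_ROH = 0`. Raising
#' `min_length` never increases `F_ROH`; the conventional 4 Mb and 8 Mb
#' variants are both obtained through this argument.
#'
#' @param segments ROH tibble from [detect_roh()] (or any tibble with
#'   `sample`, `chrom`, `length_bp`).
#' @param genome Per-chromosome covered lengths: tibble with `chrom` and
#'   `length_bp`. Defaults to the `covered_genome` attribute of `segments`.
#' @param min_length Minimum segment length counted (bp); default 4 Mb.
#' @param samples Samples to report (so 0 is returned for ROH-free
#'   individuals); defaults to the `samples` attribute of `segments`, else
#'   the samples present.
#' @return Tibble with `sample` and `froh`.
#' @export
compute_froh <- function(segments, genome = NULL, min_length = 4e6,
                         samples = NULL) {
  if (is.null(genome)) genome <- attr(segments, "covered_genome")
  if (is.null(genome)) stop("supply `genome` (chrom, length_bp)", call. = FALSE)
  if (is.null(samples)) samples <- attr(segments, "samples")
  if (is.null(samples)) samples <- unique(segments$sample)
  missing_chr <- setdiff(unique(segments$chrom), genome$chrom)
  if (length(missing_chr) > 0L) {
    stop("genome table lacks chromosome(s): ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  total <- sum(genome$length_bp)
  kept <- dplyr::filter(tibble::as_tibble(segments),
                        .data$length_bp >= min_length)
  agg <- kept |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(roh_bp = sum(.data$length_bp), .groups = "drop")
  out <- tibble::tibble(sample = samples) |>
    dplyr::left_join(agg, by = "sample") |>
    dplyr::mutate(froh = dplyr::coalesce(.data$roh_bp, 0) / total) |>
    dplyr::select("sample", "froh")
  out
}

#' ROH length-class table
#'
#' Bins segments into length categories (defaults: 4-8 Mb, >8-16 Mb,
#' >16 Mb; intervals are left-closed at the first edge, then open-left /
#' closed-right) and reports counts with percentage frequencies rounded to
#' one decimal.
#'
#' @param segments ROH tibble with a `length_bp` column.
#' @param bin_edges Increasing interior edges in bp; the last class is
#'   unbounded above.
#' @return Tibble with `class`, `n` and `freq_pct` (percentages truncated,
#'   not rounded, to one decimal, the convention evident in breed-survey
#'   tables; the three decimals can sum to slightly under 100). Empty input
#'   yields all-zero counts.
#' @export
length_class_table <- function(segments, bin_edges = c(4e6, 8e6, 16e6)) {
  edges <- sort(bin_edges)
  if (nrow(segments) > 0 && any(segments$length_bp < edges[1])) {
    stop("segments shorter than the smallest class edge", call. = FALSE)
  }
  labels <- c(
    paste0(edges[-length(edges)] / 1e6, "-", edges[-1] / 1e6, " Mb"),
    paste0(">", edges[length(edges)] / 1e6, " Mb")
  )
  labels[-1] <- sub("^(\\d)", ">\\1", labels[-1])
  cls <- cut(segments$length_bp, breaks = c(edges, Inf), labels = labels,
             include.lowest = TRUE, right = TRUE)
  n <- as.integer(table(cls))
  tot <- sum(n)
  tibble::tibble(
    class = labels,
    n = n,
    freq_pct = if (tot > 0) trunc(1000 * n / tot) / 10 else rep(0, length(n))
  )
}

#' Descriptive ROH statistics
#'
#' Cohort-level summary: `mn_roh` (mean number of segments per individual),
#' the mean/sd/min/max of segment length in Mb (`l_roh`) and of SNPs per
#' segment, and the per-individual count vs total-length table behind the
#' usual scatter diagnostic.
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param n_individuals Number of individuals in the cohort (segment-free
#'   individuals included).
#' @return List of class `roh_summary`: `stats` (tibble of the headline
#'   numbers) and `per_individual` (tibble with `sample`, `n_roh`,
#'   `total_length_mb`).
#' @export
roh_summary <- function(segments, n_individuals) {
  stopifnot(n_individuals >= 1)
  len_mb <- segments$length_bp / 1e6
  per_ind <- tibble::as_tibble(segments) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_roh = dplyr::n(),
                     total_length_mb = sum(.data$length_bp) / 1e6,
                     .groups = "drop")
  stats <- tibble::tibble(
    statistic = c("mn_roh", "l_roh_mb", "snps_per_roh"),
    mean = c(nrow(segments) / n_individuals, mean(len_mb), mean(segments$n_snps)),
    sd = c(stats::sd(per_ind$n_roh), stats::sd(len_mb),
           stats::sd(segments$n_snps)),
    min = c(min(per_ind$n_roh), min(len_mb), min(segments$n_snps)),
    max = c(max(per_ind$n_roh), max(len_mb), max(segments$n_snps))
  )
  structure(list(stats = stats, per_individual = per_ind,
                 n_segments = nrow(segments), n_individuals = n_individuals),
            class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("<roh_summary> ", x$n_segments, " segments over ", x$n_individuals,
      " individuals\n", sep = "")
  print(x$stats)
  invisible(x)
}

#' @rdname roh_summary
#' @param x A `roh_summary`.
#' @param ... Unused.
#' @method tidy roh_summary
#' @export
tidy.roh_summary <- function(x, ...) x$stats
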