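#' Within-chromosome pairwise linkage disequilibrium
#'
#' For every pair of SNPs on the same chromosome (optionally limited to
#' pairs closer than `max_distance`), computes `r2`, the squared Pearson
#' correlation of genotype dosages over the samples non-missing at both
#' SNPs. Pairs with fewer than two informative samples or with zero variance
#' at either SNP are skipped; the skipped count is attached as attribute
#' `n_skipped`.
#'
#' @param ds A QC-passed (unpruned) [geno_dataset()].
#' @param max_distance Maximum pair distance in bp, or `NULL` for all
#'   within-chromosome pairs.
#' @return Tibble with `chrom`, `dist_bp` and `r2`, one row per retained
#'   pair.
#' @export
pairwise_r2 <- function(ds, max_distance = NULL) {
  validate_geno_dataset(ds)
  out <- vector("list", 0L)
  skipped <- 0L
  use <- if (anyNA(ds$calls)) "pairwise.complete.obs" else "everything"
  for (ch in unique(ds$snps$chrom)) {
    idx <- which(ds$snps$chrom == ch)
    if (length(idx) < 2L) next
    bp <- ds$snps$bp[idx]
    r2 <- suppressWarnings(
      stats::cor(ds$calls[, idx, drop = FALSE], use = use)^2
    )
    pair <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(bp[pair[, 2L]] - bp[pair[, 1L]])
    v <- r2[pair]
    if (!is.null(max_distance)) {
      inr <- d <= max_distance
      v <- v[inr]
      d <- d[inr]
    }
    ok <- !is.na(v)
    skipped <- skipped + sum(!ok)
    out[[length(out) + 1L]] <- tibble::tibble(
      chrom = ch, dist_bp = d[ok], r2 = v[ok]
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chrom = integer(), dist_bp = double(), r2 = double())
  attr(res, "n_skipped") <- skipped
  attr(res, "n_samples") <- n_samples(ds)
  res
}

#' Bin LD by physical distance
#'
#' Averages pairwise `r2` in half-open distance bins
#' `[k*bin_width, (k+1)*bin_width)`; bins without pairs are omitted.
#'
#' @param pairs Tibble from [pairwise_r2()].
#' @param bin_width Bin width in bp (default 10 kb).
#' @return Tibble of class `ld_decay` with `bin_start`, `bin_end`,
#'   `midpoint_bp`, `mean_r2` and `n_pairs`. The sample count attribute of
#'   `pairs` is carried over when present.
#' @export
bin_ld_decay <- function(pairs, bin_width = 10000) {
  if (nrow(pairs) == 0L) {
    out <- tibble::tibble(bin_start = double(), bin_end = double(),
                          midpoint_bp = double(), mean_r2 = double(),
                          n_pairs = integer())
  } else {
    out <- pairs |>
      dplyr::mutate(.bin = floor(.data$dist_bp / bin_width)) |>
      dplyr::group_by(.data$.bin) |>
      dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n(),
                       .groups = "drop") |>
      dplyr::arrange(.data$.bin) |>
      dplyr::mutate(bin_start = .data$.bin * bin_width,
                    bin_end = (.data$.bin + 1) * bin_width,
                    midpoint_bp = .data$bin_start + bin_width / 2) |>
      dplyr::select("bin_start", "bin_end", "midpoint_bp", "mean_r2",
                    "n_pairs")
  }
  attr(out, "n_samples") <- attr(pairs, "n_samples")
  class(out) <- c("ld_decay", class(out))
  out
}

#' Options for LD-based effective population size estimation
#'
#' Settings of the Sved/Corbin-style inversion of binned LD into an
#' ancestral Ne trajectory. The defaults are the estimator's conventions:
#' constant map of 1 cM/Mb (`map_rate` in Morgans per bp), mutation
#' adjustment `alpha = 2`, `beta_phase = 2` for unphased genotype dosages,
#' and the linear mapping `f(c) = c` from physical-derived to effective
#' recombination distance (Haldane inverse optional).
#'
#' @param map_rate Morgans per bp (default 1e-8, i.e. 1 cM/Mb).
#' @param alpha Mutation adjustment; conventional choices 1, 2 or 2.2.
#' @param beta_phase 2 for unphased dosage data, 1 for phased haplotypes.
#' @param recomb_mapping `"linear"` (`f(c) = c`) or `"haldane"`
#'   (`f(c) = (1 - exp(-2c))/2`).
#' @param sample_size Number of genotyped individuals (required unless the
#'   bins carry it as an attribute).
#' @param min_pairs Bins with fewer pairs are suppressed from the
#'   trajectory.
#' @return A list of class `ne_options`.
#' @export
ne_options <- function(map_rate = 1e-8, alpha = 2, beta_phase = 2,
                       recomb_mapping = c("linear", "haldane"),
                       sample_size = NULL, min_pairs = 50L) {
  recomb_mapping <- match.arg(recomb_mapping)
  if (alpha < 1) stop("alpha must be >= 1", call. = FALSE)
  if (!is.null(sample_size) && sample_size < 2) {
    stop("sample_size must be >= 2", call. = FALSE)
  }
  structure(list(map_rate = map_rate, alpha = alpha,
                 beta_phase = beta_phase, recomb_mapping = recomb_mapping,
                 sample_size = sample_size, min_pairs = as.integer(min_pairs)),
            class = "ne_options")
}

#' Ancestral effective population size from binned LD decay
#'
#' Inverts the drift expectation of LD at genetic distance `c`. Per bin:
#' `c = midpoint * map_rate` mapped through `f(c)`; the sample-size bias is
#' removed as `r2_adj = mean_r2 - 1/(beta_phase * n)`; the bin dates to
#' `t = 1/(2 f(c))` generations ago and
#' `Ne(t) = (1/r2_adj - alpha) / (4 f(c))`. Bins whose adjusted LD gives a
#' non-positive `1/r2_adj - alpha` are dropped with a warning (never
#' clamped), as are bins with `f(c) = 0` or fewer than `min_pairs` pairs.
#'
#' @param bins An [bin_ld_decay()] table.
#' @param opts An [ne_options()] bundle; `sample_size` falls back to the
#'   `n_samples` attribute of `bins`.
#' @return Tibble of class `ne_trajectory`, sorted by `t` ascending, with
#'   `t` (generations ago), `ne`, `midpoint_bp`, `c` (mapped genetic
#'   distance), `mean_r2` and `n_pairs`.
#' @export
estimate_ne_trajectory <- function(bins, opts = ne_options()) {
  if (nrow(bins) == 0L) stop("empty LD bin table", call. = FALSE)
  n <- opts$sample_size %||% attr(bins, "n_samples")
  if (is.null(n)) stop("sample_size not set (ne_options or bins attribute)",
                       call. = FALSE)
  cc <- bins$midpoint_bp * opts$map_rate
  fc <- switch(opts$recomb_mapping,
               linear = cc,
               haldane = (1 - exp(-2 * cc)) / 2)
  r2_adj <- bins$mean_r2 - 1 / (opts$beta_phase * n)
  inv <- ifelse(r2_adj > 0, 1 / r2_adj - opts$alpha, -Inf)
  ok <- fc > 0 & r2_adj > 0 & inv > 0 & bins$n_pairs >= opts$min_pairs
  n_bad <- sum(fc > 0 & bins$n_pairs >= opts$min_pairs & !(r2_adj > 0 & inv > 0))
  if (n_bad > 0L) {
    warning(n_bad, " bin(s) dropped: adjusted r2 too high or non-positive",
            call. = FALSE)
  }
  out <- tibble::tibble(
    t = 1 / (2 * fc[ok]),
    ne = inv[ok] / (4 * fc[ok]),
    midpoint_bp = bins$midpoint_bp[ok],
    c = fc[ok],
    mean_r2 = bins$mean_r2[ok],
    n_pairs = bins$n_pairs[ok]
  ) |>
    dplyr::arrange(.data$t)
  class(out) <- c("ne_trajectory", class(out))
  out
}
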