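#' Simulation configuration
#'
#' Single bundle of settings for the synthetic-cohort generators. All
#' generators are deterministic given `seed`: an identical configuration
#' reproduces identical output byte for byte.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_founders Founders in the pedigree (>= 2).
#' @param n_generations Non-founder generations.
#' @param n_per_generation Offspring per generation (default `n_founders`).
#' @param close_kin_prob Probability that an offspring results from a
#'   full-sib mating (effective from the second non-founder generation on,
#'   when sib groups exist).
#' @param n_chrom,chrom_length_bp Chromosome count and length.
#' @param map_rate Morgans per bp (default 1e-8 = 1 cM/Mb).
#' @param snp_spacing_bp Mean SNP spacing (default 50 kb, 50K-chip density
#'   on a cattle-sized genome).
#' @param founder_maf Range of the uniform founder allele-frequency
#'   distribution.
#' @param ne Effective size for the drift simulator (scalar, or vector of
#'   per-generation sizes).
#' @param wf_generations Generations of Wright-Fisher drift.
#' @param sample_size Individuals sampled from the final drift generation.
#' @param trait List with `mean`, `var_p`, `h2`, and optionally `m2`,
#'   `r_am`, `c2` (variance fractions must sum to at most 1).
#' @param qtl Optional QTL spec: list with `n` and `pve` (per-QTL fraction
#'   of phenotypic variance).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 40L,
                       n_generations = 2L,
                       n_per_generation = n_founders,
                       close_kin_prob = 0,
                       n_chrom = 5L,
                       chrom_length_bp = 5e7,
                       map_rate = 1e-8,
                       snp_spacing_bp = 5e4,
                       founder_maf = c(0.05, 0.5),
                       ne = 100L,
                       wf_generations = 100L,
                       sample_size = 50L,
                       trait = list(mean = 0, var_p = 1, h2 = 0.3),
                       qtl = NULL) {
  if (n_founders < 2L) stop("n_founders must be >= 2", call. = FALSE)
  if (close_kin_prob < 0 || close_kin_prob > 1) {
    stop("close_kin_prob must be in [0,1]", call. = FALSE)
  }
  trait <- utils::modifyList(list(mean = 0, var_p = 1, h2 = 0.3, m2 = 0,
                                  r_am = 0, c2 = 0), trait)
  fr <- trait$h2 + trait$m2 + trait$c2
  if (fr > 1) stop("variance fractions h2 + m2 + c2 exceed 1", call. = FALSE)
  if (trait$r_am != 0 && trait$m2 == 0) {
    stop("r_am requires a maternal variance fraction m2 > 0", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_founders = as.integer(n_founders),
         n_generations = as.integer(n_generations),
         n_per_generation = as.integer(n_per_generation),
         close_kin_prob = close_kin_prob, n_chrom = as.integer(n_chrom),
         chrom_length_bp = chrom_length_bp, map_rate = map_rate,
         snp_spacing_bp = snp_spacing_bp, founder_maf = founder_maf,
         ne = ne, wf_generations = as.integer(wf_generations),
         sample_size = as.integer(sample_size), trait = trait, qtl = qtl),
    class = "sim_config"
  )
}

#' Simulate a generational pedigree
#'
#' Founders are paired into couples whose offspring form full-sib groups;
#' from the second non-founder generation on, each offspring results from a
#' full-sib mating with probability `close_kin_prob` and from an
#' across-group mating otherwise. Reproducible for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A [pedigree_table()] with an extra `generation` column
#'   (0 = founders).
#' @export
sim_pedigree <- function(cfg) {
  set.seed(cfg$seed * 7L + 101L)
  founders <- sprintf("F%03d", seq_len(cfg$n_founders))
  ped <- tibble::tibble(animal = founders, sire = NA_character_,
                        dam = NA_character_, generation = 0L)
  n_couples <- cfg$n_founders %/% 2L
  if (n_couples < 1L) stop("need at least one founder couple", call. = FALSE)
  prev_groups <- NULL  # sib groups of the previous generation
  for (g in seq_len(cfg$n_generations)) {
    ids <- sprintf("G%d_%03d", g, seq_len(cfg$n_per_generation))
    sires <- character(cfg$n_per_generation)
    dams <- character(cfg$n_per_generation)
    if (g == 1L) {
      # founder couples mate round-robin, creating full-sib groups
      k <- ((seq_len(cfg$n_per_generation) - 1L) %% n_couples) + 1L
      sires <- founders[2L * k - 1L]
      dams <- founders[2L * k]
    } else {
      big <- which(lengths(prev_groups) >= 2L)
      if (cfg$close_kin_prob > 0 && length(big) == 0L) {
        stop("close-kin mating requested but no sib group has two members",
             call. = FALSE)
      }
      for (i in seq_len(cfg$n_per_generation)) {
        if (stats::runif(1) < cfg$close_kin_prob) {
          grp <- prev_groups[[sample(big, 1L)]]
          pr <- sample(grp, 2L)
        } else {
          if (length(prev_groups) < 2L) {
            stop("cannot form an across-group mating with a single sib group",
                 call. = FALSE)
          }
          gs <- sample(length(prev_groups), 2L)
          pr <- c(sample(prev_groups[[gs[1]]], 1L),
                  sample(prev_groups[[gs[2]]], 1L))
        }
        sires[i] <- pr[1]
        dams[i] <- pr[2]
      }
    }
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      animal = ids, sire = sires, dam = dams, generation = g
    ))
    key <- paste(pmin(sires, dams), pmax(sires, dams), sep = "|")
    prev_groups <- split(ids, match(key, unique(key)))
  }
  out <- pedigree_table(ped[, c("animal", "sire", "dam")])
  out$generation <- ped$generation[match(out$animal, ped$animal)]
  out
}

# crossover mask for one meiosis: 0/1 per SNP choosing parental haplotype
.meiosis_mask <- function(pos, len_bp, map_rate) {
  n_xo <- stats::rpois(1L, len_bp * map_rate)
  start <- sample.int(2L, 1L) - 1L
  if (n_xo == 0L) return(rep.int(start, length(pos)))
  xo <- sort(stats::runif(n_xo, 0, len_bp))
  (findInterval(pos, xo) + start) %% 2L
}

# recombine a haplotype pair (rows r, r+1 of mat) under a mask
.recombine <- function(mat, r, mask) {
  out <- mat[r, ]
  sel <- mask == 1L
  if (any(sel)) out[sel] <- mat[r + 1L, sel]
  out
}

#' Gene-drop genotypes with exact identity-by-descent truth
#'
#' Drops founder haplotypes through a pedigree with Poisson (Haldane,
#' no-interference) crossovers on a constant genetic map. Founder alleles
#' carry unique labels, so the autozygous (both haplotypes descending from
#' one founder allele) segments of every sampled individual are known
#' exactly. SNP positions are uniform at roughly one per `snp_spacing_bp`;
#' founder frequencies are uniform on `founder_maf`.
#'
#' @param ped Pedigree from [sim_pedigree()] (any topologically valid
#'   pedigree tibble works).
#' @param cfg A [sim_config()].
#' @param samples Animals to genotype; default the last generation (animals
#'   that are nobody's parent).
#' @return List with `data` (a [geno_dataset()]) and `truth`: tibbles
#'   `ibd_segments` (sample, chrom, start_bp, end_bp, n_snps, length_bp),
#'   `autozygosity` (sample, autozygosity = IBD length over SNP-covered
#'   genome length), and `pedigree_f` from [pedigree_inbreeding()].
#' @export
gene_drop_genotypes <- function(ped, cfg, samples = NULL) {
  if (any(cfg$chrom_length_bp <= 0)) stop("zero-length chromosome",
                                          call. = FALSE)
  ped <- pedigree_table(ped)
  if (is.null(samples)) {
    samples <- setdiff(ped$animal, c(ped$sire, ped$dam))
  }
  stopifnot(all(samples %in% ped$animal))
  set.seed(cfg$seed * 7L + 202L)
  pi <- .ped_index(ped)
  n <- nrow(ped)
  samp_idx <- match(samples, ped$animal)
  chrom_len <- rep_len(cfg$chrom_length_bp, cfg$n_chrom)

  call_blocks <- vector("list", cfg$n_chrom)
  snp_blocks <- vector("list", cfg$n_chrom)
  seg_blocks <- vector("list", cfg$n_chrom)
  covered <- numeric(cfg$n_chrom)
  for (ch in seq_len(cfg$n_chrom)) {
    len <- chrom_len[ch]
    m <- max(2L, round(len / cfg$snp_spacing_bp))
    pos <- sort(unique(ceiling(stats::runif(m, 0, len))))
    m <- length(pos)
    p <- stats::runif(m, cfg$founder_maf[1], cfg$founder_maf[2])
    alle <- matrix(0L, 2L * n, m)
    orig <- matrix(0L, 2L * n, m)
    for (i in seq_len(n)) {
      r <- 2L * i - 1L
      if (pi$s[i] == 0L && pi$d[i] == 0L) {
        alle[r, ] <- stats::rbinom(m, 1L, p)
        alle[r + 1L, ] <- stats::rbinom(m, 1L, p)
        orig[r, ] <- 2L * i - 1L
        orig[r + 1L, ] <- 2L * i
      } else {
        for (h in 1:2) {
          par <- if (h == 1L) pi$s[i] else pi$d[i]
          if (par == 0L) {  # unknown parent: draw a fresh base haplotype
            alle[r + h - 1L, ] <- stats::rbinom(m, 1L, p)
            orig[r + h - 1L, ] <- 2L * i - 2L + h
          } else {
            mask <- .meiosis_mask(pos, len, cfg$map_rate)
            pr <- 2L * par - 1L
            alle[r + h - 1L, ] <- .recombine(alle, pr, mask)
            orig[r + h - 1L, ] <- .recombine(orig, pr, mask)
          }
        }
      }
    }
    call_blocks[[ch]] <- alle[2L * samp_idx - 1L, , drop = FALSE] +
      alle[2L * samp_idx, , drop = FALSE]
    snp_blocks[[ch]] <- tibble::tibble(
      id = sprintf("snp%d_%d", ch, pos), chrom = ch, bp = pos
    )
    covered[ch] <- max(pos) - min(pos) + 1
    segs <- list()
    for (k in seq_along(samp_idx)) {
      i <- samp_idx[k]
      eq <- orig[2L * i - 1L, ] == orig[2L * i, ]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values)
      if (length(keep)) {
        segs[[length(segs) + 1L]] <- tibble::tibble(
          sample = samples[k], chrom = ch,
          start_bp = pos[starts[keep]], end_bp = pos[ends[keep]],
          n_snps = (ends - starts + 1L)[keep]
        )
      }
    }
    seg_blocks[[ch]] <- if (length(segs)) dplyr::bind_rows(segs) else NULL
  }
  ds <- geno_dataset(do.call(cbind, call_blocks),
                     dplyr::bind_rows(snp_blocks), samples = samples)
  ibd <- dplyr::bind_rows(seg_blocks)
  if (nrow(ibd) == 0L) {
    ibd <- tibble::tibble(sample = character(), chrom = integer(),
                          start_bp = double(), end_bp = double(),
                          n_snps = integer())
  }
  ibd$length_bp <- ibd$end_bp - ibd$start_bp + 1
  auto <- tibble::tibble(sample = samples) |>
    dplyr::left_join(
      ibd |> dplyr::group_by(.data$sample) |>
        dplyr::summarise(ibd_bp = sum(.data$length_bp), .groups = "drop"),
      by = "sample"
    ) |>
    dplyr::mutate(autozygosity = dplyr::coalesce(.data$ibd_bp, 0) /
                    sum(covered)) |>
    dplyr::select("sample", "autozygosity")
  list(data = ds,
       truth = list(ibd_segments = ibd, autozygosity = auto,
                    pedigree_f = pedigree_inbreeding(ped)))
}

#' Wright-Fisher forward simulation of genotypes
#'
#' Discrete-generation drift of `2 Ne` haplotypes per chromosome with
#' Poisson recombination, started from linkage-equilibrium founders with
#' uniform allele frequencies, run for `wf_generations` generations
#' (`ne` may be a per-generation vector for a changing trajectory), with
#' `sample_size` diploids sampled from the final generation. The realised
#' LD decay of the sample reflects the simulated Ne history.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_dataset()]; SNPs sit on a regular grid of spacing
#'   `snp_spacing_bp`.
#' @export
sim_constant_ne_population <- function(cfg) {
  ne_t <- rep_len(cfg$ne, cfg$wf_generations)
  if (any(ne_t < 2)) stop("ne must be >= 2 throughout", call. = FALSE)
  if (cfg$sample_size > utils::tail(ne_t, 1L)) {
    stop("sample_size exceeds the final population size", call. = FALSE)
  }
  set.seed(cfg$seed * 7L + 303L)
  chrom_len <- rep_len(cfg$chrom_length_bp, cfg$n_chrom)
  samp <- NULL
  call_blocks <- vector("list", cfg$n_chrom)
  snp_blocks <- vector("list", cfg$n_chrom)
  for (ch in seq_len(cfg$n_chrom)) {
    len <- chrom_len[ch]
    pos <- seq(cfg$snp_spacing_bp %/% 2, len, by = cfg$snp_spacing_bp)
    m <- length(pos)
    p <- stats::runif(m, cfg$founder_maf[1], cfg$founder_maf[2])
    n0 <- ne_t[1]
    H <- matrix(stats::rbinom(2L * n0 * m, 1L, rep(p, each = 2L * n0)),
                nrow = 2L * n0, ncol = m)
    l_morgans <- len * cfg$map_rate
    n_prev <- n0
    for (g in seq_len(cfg$wf_generations)) {
      n_now <- ne_t[g]
      par <- sample.int(n_prev, 2L * n_now, replace = TRUE)
      starth <- sample.int(2L, 2L * n_now, replace = TRUE) - 1L
      nxo <- stats::rpois(2L * n_now, l_morgans)
      rows <- 2L * (par - 1L) + 1L + starth
      H_new <- matrix(0L, 2L * n_now, m)
      plain <- nxo == 0L
      H_new[plain, ] <- H[rows[plain], , drop = FALSE]
      for (i in which(!plain)) {
        xo <- sort(stats::runif(nxo[i], 0, len))
        mask <- (findInterval(pos, xo) + starth[i]) %% 2L
        hap <- H[2L * par[i] - 1L, ]
        sel <- mask == 1L
        hap[sel] <- H[2L * par[i], sel]
        H_new[i, ] <- hap
      }
      H <- H_new
      n_prev <- n_now
    }
    if (is.null(samp)) samp <- sample.int(n_prev, cfg$sample_size)
    call_blocks[[ch]] <- H[2L * samp - 1L, , drop = FALSE] +
      H[2L * samp, , drop = FALSE]
    snp_blocks[[ch]] <- tibble::tibble(
      id = sprintf("snp%d_%d", ch, pos), chrom = ch, bp = pos
    )
  }
  geno_dataset(do.call(cbind, call_blocks), dplyr::bind_rows(snp_blocks),
               samples = sprintf("W%03d", seq_len(cfg$sample_size)))
}

#' Simulate phenotypes, true breeding values and EBVs
#'
#' Draws true breeding values down the pedigree (bivariate direct-maternal
#' when `m2 > 0`, with inbreeding-adjusted Mendelian-sampling variances),
#' optionally overlays additive QTL effects on supplied gene-dropped
#' genotypes, builds one phenotypic record per animal under the configured
#' trait architecture, and (optionally) runs the animal model at the true
#' variance components to attach EBVs and reliabilities — a full
#' end-to-end fixture.
#'
#' @param ped Pedigree tibble.
#' @param cfg A [sim_config()]; the `trait` entry fixes the architecture.
#' @param genotypes Optional [geno_dataset()] for QTL effects (required
#'   when `cfg$qtl` is set).
#' @param record_animals Animals receiving a phenotypic record; default all
#'   animals (restricted to those with known dams when maternal terms are
#'   on).
#' @param run_blup Attach BLUP EBVs and reliabilities?
#' @return List with `records` (animal, dam, value), `truth` (animal, tbv,
#'   and maternal `mbv` when fitted), `vc` (the generating
#'   [variance_components()]), `qtl` (tibble of planted QTL, or `NULL`) and
#'   `ebv` (animal, ebv, reliability; `NULL` unless `run_blup`).
#' @export
sim_phenotypes_and_ebv <- function(ped, cfg, genotypes = NULL,
                                   record_animals = NULL, run_blup = TRUE) {
  tr <- cfg$trait
  if (tr$r_am != 0 && tr$m2 == 0) {
    stop("r_am set without a maternal term", call. = FALSE)
  }
  if (!is.null(cfg$qtl) && is.null(genotypes)) {
    stop("QTL spec requires gene-dropped `genotypes`", call. = FALSE)
  }
  set.seed(cfg$seed * 7L + 404L)
  ped <- pedigree_table(ped)
  fi <- pedigree_inbreeding(ped)
  pi <- .ped_index(ped)
  n <- nrow(ped)
  s2p <- tr$var_p
  qtl_tbl <- NULL
  s2a_qtl <- 0
  if (!is.null(cfg$qtl)) {
    p_all <- allele_freq(genotypes)
    cand <- which(p_all > 0.1 & p_all < 0.9)
    pick <- sample(cand, cfg$qtl$n)
    pve <- rep_len(cfg$qtl$pve, cfg$qtl$n)
    bq <- sqrt(pve * s2p / (2 * p_all[pick] * (1 - p_all[pick])))
    qtl_tbl <- tibble::tibble(snp = genotypes$snps$id[pick],
                              chrom = genotypes$snps$chrom[pick],
                              bp = genotypes$snps$bp[pick],
                              freq = p_all[pick], beta = bq, pve = pve)
    s2a_qtl <- sum(pve) * s2p
    if (s2a_qtl > tr$h2 * s2p) {
      stop("QTL variance exceeds the h2 budget", call. = FALSE)
    }
  }
  s2a <- tr$h2 * s2p - s2a_qtl  # polygenic remainder
  s2m <- tr$m2 * s2p
  sam <- if (s2m > 0) tr$r_am * sqrt(tr$h2 * s2p * s2m) else 0
  s2pe <- tr$c2 * s2p
  s2e <- s2p - tr$h2 * s2p - s2m - sam - s2pe
  if (s2e <= 0) stop("residual variance non-positive; shrink fractions",
                     call. = FALSE)
  use_m <- s2m > 0
  g0 <- if (use_m) matrix(c(s2a, sam, sam, s2m), 2) else
    matrix(s2a, 1)
  ch_g0 <- chol(g0 + diag(nrow(g0)) * 1e-12)
  bv <- matrix(0, n, nrow(g0))
  f0 <- function(j) if (j == 0L) -1 else fi$f[j]
  for (i in seq_len(n)) {
    pa <- if (pi$s[i] > 0L) bv[pi$s[i], ] else 0
    ma <- if (pi$d[i] > 0L) bv[pi$d[i], ] else 0
    d_i <- 0.5 - 0.25 * (f0(pi$s[i]) + f0(pi$d[i]))
    bv[i, ] <- 0.5 * (pa + ma) +
      sqrt(d_i) * drop(crossprod(ch_g0, stats::rnorm(nrow(g0))))
  }
  tbv <- bv[, 1]
  if (!is.null(qtl_tbl)) {
    gm <- genotypes$calls[, match(qtl_tbl$snp, genotypes$snps$id),
                          drop = FALSE]
    gm <- sweep(gm, 2L, 2 * qtl_tbl$freq)
    add <- drop(gm %*% qtl_tbl$beta)
    gi <- match(genotypes$samples, ped$animal)
    tbv[gi] <- tbv[gi] + add
  }
  if (is.null(record_animals)) {
    record_animals <- if (use_m || tr$c2 > 0) {
      ped$animal[!is.na(ped$dam)]
    } else ped$animal
  }
  ri <- match(record_animals, ped$animal)
  dam_of <- ped$dam[ri]
  pe <- stats::rnorm(n, 0, sqrt(s2pe))
  di <- pi$d[ri]
  mat_part <- if (use_m) ifelse(di > 0L, bv[pmax(di, 1L), 2], 0) else 0
  pe_part <- if (tr$c2 > 0) ifelse(di > 0L, pe[pmax(di, 1L)], 0) else 0
  y <- tr$mean + tbv[ri] + mat_part + pe_part +
    stats::rnorm(length(ri), 0, sqrt(s2e))
  records <- tibble::tibble(animal = record_animals, dam = dam_of, value = y)
  vc <- variance_components(sigma2_a = tr$h2 * s2p, sigma2_e = s2e,
                            sigma2_m = s2m, sigma_am = sam, sigma2_p = s2pe)
  truth <- tibble::tibble(animal = ped$animal, tbv = tbv)
  if (use_m) truth$mbv <- bv[, 2]
  ebv <- NULL
  if (run_blup) {
    spec <- model_spec("value", maternal = use_m,
                       permanent = if (tr$c2 > 0) "dam" else "none",
                       covariance_am = use_m && sam != 0)
    fit <- solve_mme(records, ped, vc, spec)
    ebv <- fit$ebv[, c("animal", "ebv", "reliability")]
  }
  list(records = records, truth = truth, vc = vc, qtl = qtl_tbl, ebv = ebv)
}
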