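test_that("generators are seed-deterministic", {
  cfg <- sim_config(seed = 71, n_founders = 12, n_generations = 2,
                    close_kin_prob = 0.4, n_chrom = 2,
                    chrom_length_bp = 1e7)
  p1 <- sim_pedigree(cfg)
  p2 <- sim_pedigree(cfg)
  expect_identical(p1, p2)
  g1 <- gene_drop_genotypes(p1, cfg)
  g2 <- gene_drop_genotypes(p2, cfg)
  expect_identical(g1$data$calls, g2$data$calls)
  expect_identical(g1$truth$ibd_segments, g2$truth$ibd_segments)
  cfgw <- sim_config(seed = 72, n_chrom = 2, chrom_length_bp = 5e6,
                     ne = 20, wf_generations = 10, sample_size = 10)
  expect_identical(sim_constant_ne_population(cfgw)$calls,
                   sim_constant_ne_population(cfgw)$calls)
  # different seed, different draw
  cfgw2 <- sim_config(seed = 73, n_chrom = 2, chrom_length_bp = 5e6,
                      ne = 20, wf_generations = 10, sample_size = 10)
  expect_false(identical(sim_constant_ne_population(cfgw)$calls,
                         sim_constant_ne_population(cfgw2)$calls))
})

test_that("mating scheme controls pedigree inbreeding", {
  # no close kin: every animal non-inbred
  cfg0 <- sim_config(seed = 74, n_founders = 16, n_generations = 1)
  expect_true(all(pedigree_inbreeding(sim_pedigree(cfg0))$f == 0))
  # forced full-sib matings: all final-generation animals F = 0.25
  cfg1 <- sim_config(seed = 75, n_founders = 16, n_generations = 2,
                     close_kin_prob = 1)
  ped1 <- sim_pedigree(cfg1)
  f1 <- pedigree_inbreeding(ped1)
  expect_true(all(f1$f[match(ped1$animal[ped1$generation == 2],
                             f1$animal)] == 0.25))
  # mean F increases with the close-kin probability
  mean_f <- function(p, seed) {
    cfg <- sim_config(seed = seed, n_founders = 20, n_generations = 2,
                      n_per_generation = 40, close_kin_prob = p)
    ped <- sim_pedigree(cfg)
    fi <- pedigree_inbreeding(ped)
    mean(fi$f[match(ped$animal[ped$generation == 2], fi$animal)])
  }
  grid <- vapply(c(0, 0.3, 0.8), function(p) {
    mean(vapply(1:8, function(s) mean_f(p, 1000 * p + s), 0))
  }, 0)
  expect_true(all(diff(grid) > 0))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_founders = 1), "n_founders")
  expect_error(sim_config(close_kin_prob = 1.2), "close_kin_prob")
  expect_error(sim_config(trait = list(h2 = 0.6, m2 = 0.3, c2 = 0.3)),
               "exceed")
  expect_error(sim_config(trait = list(h2 = 0.3, r_am = 0.5)), "r_am")
})

test_that("founders carry no autozygosity and IBD truth is consistent", {
  cfg <- sim_config(seed = 76, n_founders = 10, n_generations = 2,
                    close_kin_prob = 0.6, n_chrom = 3,
                    chrom_length_bp = 3e7)
  ped <- sim_pedigree(cfg)
  gd <- gene_drop_genotypes(ped, cfg, samples = ped$animal)
  auto <- gd$truth$autozygosity
  founders <- ped$animal[is.na(ped$sire) & is.na(ped$dam)]
  expect_true(all(auto$autozygosity[auto$sample %in% founders] == 0))

  # no heterozygote can sit inside a true autozygous segment
  segs <- gd$truth$ibd_segments
  for (k in seq_len(nrow(segs))) {
    i <- match(segs$sample[k], gd$data$samples)
    inside <- gd$data$snps$chrom == segs$chrom[k] &
      gd$data$snps$bp >= segs$start_bp[k] &
      gd$data$snps$bp <= segs$end_bp[k]
    expect_false(any(gd$data$calls[i, inside] == 1L))
  }

  # autozygosity fraction equals independent interval-union arithmetic
  cov_len <- sum(vapply(split(gd$data$snps$bp, gd$data$snps$chrom),
                        function(b) max(b) - min(b) + 1, 0))
  for (s in unique(segs$sample)[1:3]) {
    ss <- segs[segs$sample == s, ]
    # segments of one haplotype pair never overlap; union = plain sum
    expect_equal(auto$autozygosity[auto$sample == s],
                 sum(ss$end_bp - ss$start_bp + 1) / cov_len)
  }
})

test_that("realised autozygosity tracks pedigree F across seeds", {
  diffs <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 500 + s, n_founders = 20, n_generations = 2,
                      n_per_generation = 40, close_kin_prob = 0.4,
                      n_chrom = 6, chrom_length_bp = 9e7)
    ped <- sim_pedigree(cfg)
    cohort <- ped$animal[ped$generation == 2]
    gd <- gene_drop_genotypes(ped, cfg, samples = cohort)
    fi <- gd$truth$pedigree_f
    mean(gd$truth$autozygosity$autozygosity) -
      mean(fi$f[match(cohort, fi$animal)])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.03)
})

test_that("Wright-Fisher guards and equilibrium sanity hold", {
  expect_error(sim_constant_ne_population(
    sim_config(ne = 20, sample_size = 30)), "sample_size")
  expect_error(gene_drop_genotypes(
    tibble::tibble(animal = "a", sire = NA, dam = NA),
    sim_config(chrom_length_bp = 0)), "zero-length")
})

test_that("phenotype simulation matches its target architecture", {
  # h2 = 0: no genetic signal, EBVs collapse to zero
  cfg0 <- sim_config(seed = 81, n_founders = 20, n_generations = 2,
                     n_per_generation = 30,
                     trait = list(var_p = 4, h2 = 0))
  ped0 <- sim_pedigree(cfg0)
  sim0 <- sim_phenotypes_and_ebv(ped0, cfg0, run_blup = FALSE)
  expect_lt(max(abs(sim0$truth$tbv)), 1e-4)

  # realised Var(TBV)/var_p close to h2 across seeds
  ratios <- vapply(1:6, function(s) {
    cfg <- sim_config(seed = 600 + s, n_founders = 30, n_generations = 2,
                      n_per_generation = 80,
                      trait = list(var_p = 2, h2 = 0.35))
    ped <- sim_pedigree(cfg)
    sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = FALSE)
    stats::var(sim$truth$tbv) / 2
  }, 0)
  expect_equal(mean(ratios), 0.35, tolerance = 0.07)

  # phenotypic variance matches var_p
  cfg <- sim_config(seed = 82, n_founders = 40, n_generations = 2,
                    n_per_generation = 200,
                    trait = list(var_p = 5, h2 = 0.3, mean = 100))
  ped <- sim_pedigree(cfg)
  sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = FALSE)
  expect_equal(stats::var(sim$records$value), 5, tolerance = 1.2)
  expect_equal(mean(sim$records$value), 100, tolerance = 0.5)
})

test_that("EBV attachment produces usable reliabilities", {
  cfg <- sim_config(seed = 83, n_founders = 20, n_generations = 2,
                    n_per_generation = 40,
                    trait = list(var_p = 4, h2 = 0.4))
  ped <- sim_pedigree(cfg)
  sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = TRUE)
  expect_true(all(sim$ebv$reliability >= 0 & sim$ebv$reliability <= 1))
  # recorded animals carry information: their EBVs correlate with TBV
  j <- match(sim$records$animal, sim$ebv$animal)
  k <- match(sim$records$animal, sim$truth$animal)
  expect_gt(stats::cor(sim$ebv$ebv[j], sim$truth$tbv[k]), 0.4)
})

test_that("QTL overlay preserves the variance budget", {
  cfg <- sim_config(seed = 84, n_founders = 20, n_generations = 2,
                    n_per_generation = 40, n_chrom = 2,
                    chrom_length_bp = 2e7,
                    trait = list(var_p = 1, h2 = 0.4),
                    qtl = list(n = 2, pve = 0.1))
  ped <- sim_pedigree(cfg)
  gd <- gene_drop_genotypes(ped, cfg, samples = ped$animal)
  sim <- sim_phenotypes_and_ebv(ped, cfg, genotypes = gd$data,
                                run_blup = FALSE)
  expect_equal(nrow(sim$qtl), 2L)
  expect_error(sim_phenotypes_and_ebv(ped, cfg, run_blup = FALSE),
               "genotypes")
  # variance including QTL still near target h2
  expect_equal(stats::var(sim$truth$tbv), 0.4, tolerance = 0.15)
})
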