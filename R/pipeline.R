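#' Pipeline configuration
#'
#' Builds (and validates) the configuration consumed by [run_pipeline()]:
#' input paths, per-stage parameter bundles and the output directory. Every
#' omitted option falls back to the package defaults (the standard
#' 50K-array settings). A YAML file with the same structure can be loaded
#' with `pipeline_config(yaml = "config.yml")`.
#'
#' @param genotypes PLINK prefix of the input genotypes.
#' @param pedigree Optional pedigree TSV (animal, sire, dam).
#' @param ebv Optional named list: trait name -> TSV with columns `animal`,
#'   `ebv`, `reliability`. Absent EBVs skip the deregression/GWAS stages.
#' @param gff3 Optional GFF3 annotation for SNP feature labels.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed echoed into the report.
#' @param qc,roh,ne,gwas Lists of overrides for [qc_params()],
#'   [roh_params()], [ne_options()], [gwas_options()].
#' @param froh_min_lengths F_ROH thresholds in bp (default 4 Mb and 8 Mb).
#' @param ld_max_distance,ld_bin_width Pair-distance cap and bin width of
#'   the LD-decay stage.
#' @param deregress_c Garrick `c` constant (default 0.10).
#' @param yaml Optional YAML path; file entries are overridden by
#'   explicitly supplied arguments.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, pedigree = NULL, ebv = NULL,
                            gff3 = NULL, out_dir = "herdgen_out", seed = 1L,
                            qc = list(), roh = list(), ne = list(),
                            gwas = list(), froh_min_lengths = c(4e6, 8e6),
                            ld_max_distance = 5e6, ld_bin_width = 1e4,
                            deregress_c = 0.10, yaml = NULL) {
  cfg <- list(genotypes = genotypes, pedigree = pedigree, ebv = ebv,
              gff3 = gff3, out_dir = out_dir, seed = as.integer(seed),
              qc = qc, roh = roh, ne = ne, gwas = gwas,
              froh_min_lengths = froh_min_lengths,
              ld_max_distance = ld_max_distance,
              ld_bin_width = ld_bin_width, deregress_c = deregress_c)
  if (!is.null(yaml)) {
    from_file <- yaml::read_yaml(yaml)
    supplied <- names(as.list(match.call()))[-1]
    keep <- setdiff(names(from_file), setdiff(supplied, "yaml"))
    cfg[keep] <- from_file[keep]
  }
  if (is.null(cfg$genotypes)) stop("`genotypes` prefix is required",
                                   call. = FALSE)
  for (f in paste0(cfg$genotypes, c(".bed", ".ped"))) {
    if (file.exists(f)) break
  }
  if (!file.exists(paste0(cfg$genotypes, ".bed")) &&
      !file.exists(paste0(cfg$genotypes, ".ped"))) {
    stop("no PLINK fileset at prefix: ", cfg$genotypes, call. = FALSE)
  }
  for (p in c(cfg$pedigree, cfg$gff3, unlist(cfg$ebv))) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path does not exist: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  path
}

#' Run the full genomic-management pipeline
#'
#' Executes the stages in their fixed routing: quality control feeds an
#' LD-pruned subset into ROH/F_ROH, while the unpruned QC-passed set feeds
#' the LD-decay/Ne and deregression/GWAS branches. All intermediate tables
#' are written as TSV under `out_dir` and a consolidated JSON report is
#' produced; rerunning with an identical configuration and seed reproduces
#' the report byte for byte (timestamps excluded). A stage failure aborts
#' with the stage name; outputs written so far remain on disk next to a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `run_report`: `qc` (removal tallies),
#'   `roh` (summary, class table, per-individual F_ROH), `ne` (trajectory),
#'   `gwas` (per-trait lambda and significant SNPs, or a skip marker),
#'   `config` echo and a software fingerprint.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  done <- FALSE
  on.exit({
    if (!done) writeLines("pipeline aborted; partial outputs", fail_marker)
  })
  set.seed(config$seed)

  qc_p <- do.call(qc_params, config$qc)
  roh_p <- do.call(roh_params, config$roh)
  gwas_o <- do.call(gwas_options, config$gwas)

  ds_raw <- .stage("read", read_plink(config$genotypes))
  qc <- .stage("qc", qc_filter(ds_raw, qc_p))
  .write_tsv(qc$report, file.path(config$out_dir, "qc_report.tsv"))

  pruned_ids <- .stage("prune", ld_prune(qc$data, window = qc_p$prune_window,
                                         step = qc_p$prune_step,
                                         r2_max = qc_p$prune_r2))
  ds_pruned <- subset_geno(qc$data, snps = pruned_ids)

  segments <- .stage("roh", detect_roh(ds_pruned, roh_p))
  froh <- lapply(config$froh_min_lengths, function(thr) {
    compute_froh(segments, min_length = thr)
  })
  names(froh) <- paste0("froh_", config$froh_min_lengths / 1e6, "mb")
  froh_tbl <- froh[[1]]
  for (k in seq_along(froh)[-1]) {
    froh_tbl[[names(froh)[k]]] <- froh[[k]]$froh
  }
  names(froh_tbl)[2] <- names(froh)[1]
  cls_edges <- sort(unique(c(roh_p$min_length,
                             c(8e6, 16e6)[c(8e6, 16e6) > roh_p$min_length])))
  class_tbl <- length_class_table(segments, bin_edges = cls_edges)
  summ <- roh_summary(segments, n_individuals = n_samples(ds_pruned))
  .write_tsv(segments, file.path(config$out_dir, "roh_segments.tsv"))
  .write_tsv(froh_tbl, file.path(config$out_dir, "froh.tsv"))
  .write_tsv(class_tbl, file.path(config$out_dir, "roh_length_classes.tsv"))

  pairs <- .stage("ld", pairwise_r2(qc$data,
                                    max_distance = config$ld_max_distance))
  bins <- bin_ld_decay(pairs, bin_width = config$ld_bin_width)
  ne_o <- do.call(ne_options, config$ne)
  if (is.null(ne_o$sample_size)) ne_o$sample_size <- n_samples(qc$data)
  traj <- .stage("ne", estimate_ne_trajectory(bins, ne_o))
  .write_tsv(bins, file.path(config$out_dir, "ld_decay.tsv"))
  .write_tsv(traj, file.path(config$out_dir, "ne_trajectory.tsv"))

  gwas_out <- list(skipped = TRUE)
  if (!is.null(config$ebv) && length(config$ebv) > 0) {
    gwas_out <- list(skipped = FALSE, traits = list())
    axes <- .stage("axes", stratification_axes(qc$data, gwas_o$n_axes))
    for (trait in names(config$ebv)) {
      ebv_tbl <- readr::read_tsv(config$ebv[[trait]],
                                 show_col_types = FALSE)
      debv <- .stage(paste0("deregress:", trait),
                     deregress_ebv(ebv_tbl, c = config$deregress_c))
      scan <- .stage(paste0("gwas:", trait),
                     egscore_scan(debv, qc$data, axes = axes, opts = gwas_o))
      res <- genomic_control(scan, gwas_o)
      tab <- res$scan
      sig <- tab$tier != "none"
      tab$pve <- NA_real_
      tab$pve[sig] <- estimate_pve(tab$beta[sig], tab$freq[sig],
                                   attr(scan, "phenotype_var"))
      if (!is.null(config$gff3) && any(sig)) {
        ann <- annotate_snp_feature(tab[sig, c("snp", "chrom", "bp")],
                                    config$gff3)
        tab$feature_type <- tab$gene <- NA_character_
        tab$feature_type[sig] <- ann$feature_type
        tab$gene[sig] <- ann$gene
      }
      .write_tsv(tab, file.path(config$out_dir,
                                paste0("gwas_", trait, ".tsv")))
      .write_tsv(res$qq, file.path(config$out_dir,
                                   paste0("qq_", trait, ".tsv")))
      gwas_out$traits[[trait]] <- list(
        lambda = res$lambda,
        n_debv = nrow(debv),
        significant = tab[sig, , drop = FALSE]
      )
    }
  }

  report <- list(
    qc = qc$report,
    roh = list(summary = summ$stats, classes = class_tbl,
               froh_mean = vapply(froh, function(f) mean(f$froh), 0),
               n_segments = nrow(segments)),
    ne = list(n_bins = nrow(bins),
              trajectory = traj[, c("t", "ne", "n_pairs")]),
    gwas = if (gwas_out$skipped) list(skipped = TRUE) else
      list(skipped = FALSE,
           lambda = vapply(gwas_out$traits, `[[`, 0, "lambda"),
           n_significant = vapply(gwas_out$traits,
                                  function(t) nrow(t$significant), 0L)),
    config = unclass(config),
    fingerprint = list(package = "herdgen",
                       version = as.character(utils::packageVersion("herdgen")))
  )
  jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  done <- TRUE
  out <- c(report, list(froh = froh_tbl, segments = segments,
                        gwas_detail = gwas_out))
  class(out) <- "run_report"
  invisible(out)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n  SNP QC:\n")
  print(x$qc)
  cat("  mean F_ROH:", signif(x$roh$froh_mean, 3), "over", x$roh$n_segments,
      "segments\n")
  if (isTRUE(x$gwas$skipped)) cat("  GWAS: skipped (no EBV inputs)\n")
  else cat("  GWAS lambda:", signif(x$gwas$lambda, 3), "\n")
  invisible(x)
}

#' Generate a ready-to-run synthetic fixture
#'
#' Wraps the synthetic-cohort generators into a directory holding PLINK
#' genotypes, a pedigree TSV, per-trait EBV TSVs and the simulation truth
#' (autozygosity, pedigree inbreeding, IBD segments), all consumed through
#' the same readers as real data. `"small"` builds in seconds;
#' `"breed-scale"` emulates a 42-bull cohort on 29 chromosomes at 50K-chip
#' density with close-kin matings (mean true autozygosity around 0.09).
#'
#' @param scale `"small"` or `"breed-scale"`.
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, a list with the `dir`, the [sim_config()] used, the
#'   genotyped `samples` and the `truth` tables.
#' @export
make_fixture <- function(scale = c("small", "breed-scale"), seed = 1L,
                         dir = tempfile("herdgen_fixture")) {
  scale <- match.arg(scale)
  cfg <- if (scale == "small") {
    sim_config(seed = seed, n_founders = 20L, n_generations = 2L,
               n_per_generation = 20L, close_kin_prob = 0.3,
               n_chrom = 3L, chrom_length_bp = 3e7,
               trait = list(var_p = 20, h2 = 0.28, mean = 75))
  } else {
    sim_config(seed = seed, n_founders = 60L, n_generations = 2L,
               n_per_generation = 60L, close_kin_prob = 0.36,
               n_chrom = 29L, chrom_length_bp = 9e7,
               trait = list(var_p = 20, h2 = 0.28, mean = 75))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim_pedigree(cfg)
  last_gen <- ped$animal[ped$generation == max(ped$generation)]
  samples <- if (scale == "breed-scale") last_gen[seq_len(42L)] else last_gen
  gd <- gene_drop_genotypes(ped, cfg, samples = samples)
  write_plink(gd$data, file.path(dir, "genotypes"))
  write_pedigree(ped, file.path(dir, "pedigree.tsv"))
  sim <- sim_phenotypes_and_ebv(ped, cfg, run_blup = TRUE)
  .write_tsv(sim$ebv, file.path(dir, "ebv_type_score.tsv"))
  .write_tsv(sim$records, file.path(dir, "records_type_score.tsv"))
  .write_tsv(gd$truth$ibd_segments, file.path(dir, "truth_ibd_segments.tsv"))
  jsonlite::write_json(
    list(autozygosity = gd$truth$autozygosity,
         pedigree_f = gd$truth$pedigree_f,
         config = unclass(cfg)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(list(dir = dir, config = cfg, samples = samples,
                 truth = gd$truth))
}
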