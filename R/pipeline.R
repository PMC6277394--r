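default_pipeline_config <- function() {
  list(
    genome = list(n_chromosomes = 24, chrom_length = 25e6, sex_chrom = 21,
                  sd_region = c(13e6, 23e6), diagnostic_density = 5),
    cross = list(generations = 100, brood_size = 20, n_f1 = 4, n_bc1 = 16,
                 n_bc100 = 18, translocation = TRUE, dest_chrom = 2,
                 dest_start = 8e6, trans_generation = 1),
    zw_pop = list(n_f = 30, n_m = 30, snp_density = 2),
    coverage = list(n_loci = 3000, w_fraction = 0.05, z_fraction = 0.15,
                    mean_depth = 20, dispersion = 5, n_f = 30, n_m = 30),
    sexassoc = list(alpha = 0.05, suggestive_p = 1e-4,
                    window_sizes = c(1e3, 1e4, 1e5)),
    covsex = list(min_mean = 3, max_mean = 400, w_female_min = 7,
                  w_male_max = 2, z_ratio_min = 1.9),
    ancestry = list(block_min_freq = 0.5, block_max_gap = 2,
                    block_min_sites = 10),
    nulltest = list(N = 10, generations = 100, reps = 10000)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the five analysis stages end to end on synthetic data: simulate
#' (parents, backcross pedigree, a single-species ZW population and RAD
#' coverage), the sex-association scan with windowed F_ST, the
#' coverage-based W/Z classification, diagnostic-allele sorting with
#' segregation tables and block detection, and the neutral-drift excess
#' test. All outputs are TSV/VCF/JSON files under `out_dir`, tied together
#' by a run manifest recording the seed, a config checksum and per-file md5
#' checksums.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stage.
#' @param config nested list overriding entries of the default
#'   configuration (see `hybridsex:::default_pipeline_config()`).
#' @param config_file optional YAML file with the same structure; file
#'   values are applied before `config` overrides.
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1, config = list(), config_file = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(config_file)) cfg <- merge_config(cfg, yaml::read_yaml(config_file))
  cfg <- merge_config(cfg, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  add <- function(path) { outputs[length(outputs) + 1] <<- path; path }

  ## -- simulate ----------------------------------------------------------
  g <- cfg$genome
  genome <- genome_model(g$n_chromosomes, g$chrom_length, g$sex_chrom,
                         unlist(g$sd_region), g$diagnostic_density)
  parents <- make_parents(genome, seed = seed)
  cr <- cfg$cross
  trans <- if (isTRUE(cr$translocation))
    translocation_event(dest_chrom = cr$dest_chrom, dest_start = cr$dest_start,
                        generation = cr$trans_generation) else NULL
  cross <- simulate_cross(parents, cross_design(
    generations = cr$generations, brood_size = cr$brood_size,
    n_f1 = cr$n_f1, n_bc1 = cr$n_bc1, n_bc100 = cr$n_bc100,
    translocation = trans, seed = seed + 1))
  zw <- simulate_zw_population(genome, cfg$zw_pop$n_f, cfg$zw_pop$n_m,
                               cfg$zw_pop$snp_density, seed = seed + 2)
  loci <- sample_rad_loci(genome, cfg$coverage$n_loci, cfg$coverage$w_fraction,
                          cfg$coverage$z_fraction, seed = seed + 3)
  cov <- simulate_coverage(loci$sex_linkage, cfg$coverage$n_f, cfg$coverage$n_m,
                           coverage_model(cfg$coverage$mean_depth,
                                          cfg$coverage$dispersion),
                           seed = seed + 4, locus_ids = loci$locus)

  add(write_vcf(cross$geno, file.path(out_dir, "cross.vcf.gz"), seed = seed))
  add(write_sample_sheet(cross$geno$samples, file.path(out_dir, "cross_samples.tsv")))
  add(write_tsv(cross$truth$sites, file.path(out_dir, "cross_truth.tsv")))
  add(write_vcf(zw$geno, file.path(out_dir, "zw_pop.vcf.gz"), seed = seed))
  add(write_sample_sheet(zw$geno$samples, file.path(out_dir, "zw_samples.tsv")))
  add(write_coverage_matrix(cov$counts, file.path(out_dir, "coverage.tsv")))
  add(write_locus_map(loci, file.path(out_dir, "locus_map.tsv")))

  ## -- sexassoc ----------------------------------------------------------
  sa <- cfg$sexassoc
  scan <- sex_scan(zw$geno, alpha = sa$alpha, suggestive_p = sa$suggestive_p)
  add(write_tsv(scan, file.path(out_dir, "sexassoc_sites.tsv")))
  fst <- wc_fst(zw$geno)
  thresholds <- list(genomewide_p = attr(scan, "genomewide_p"),
                     suggestive_p = attr(scan, "suggestive_p"))
  for (ws in sa$window_sizes) {
    wf <- windowed_fst(fst, genome$chrom_lengths, ws)
    add(write_tsv(wf, file.path(out_dir, sprintf("fst_windows_%g.tsv", ws))))
    thresholds[[sprintf("fst_top1pct_%g", ws)]] <-
      top_threshold(wf$fst_weighted, 0.99)
  }

  ## -- covsex ------------------------------------------------------------
  cs <- cfg$covsex
  cova <- covsex_analysis(cov$counts, cov$samples$sex, locus_map = loci,
                          min_mean = cs$min_mean, max_mean = cs$max_mean,
                          w_female_min = cs$w_female_min,
                          w_male_max = cs$w_male_max,
                          z_ratio_min = cs$z_ratio_min)
  add(write_tsv(cova$calls, file.path(out_dir, "covsex_calls.tsv")))
  if (!is.null(cova$w_test))
    add(write_tsv(cova$w_test, file.path(out_dir, "covsex_w_overrep.tsv")))
  if (!is.null(cova$z_test))
    add(write_tsv(cova$z_test, file.path(out_dir, "covsex_z_overrep.tsv")))

  ## -- ancestry ----------------------------------------------------------
  an <- cfg$ancestry
  diag <- select_diagnostic_sites(cross$geno)
  add(write_tsv(diag, file.path(out_dir, "diagnostic_sites.tsv")))
  seg <- segregation_table(cross$geno, diag)
  add(write_tsv(seg, file.path(out_dir, "segregation_table.tsv")))
  bc_group <- if ("BC100_pigm" %in% cross$geno$samples$group) "BC100_pigm" else "BC1_pigm"
  prof <- ancestry_profile(cross$geno, diag, bc_group)
  add(write_tsv(prof$profile, file.path(out_dir, "ancestry_profile.tsv")))
  add(write_tsv(prof$per_chrom, file.path(out_dir, "ancestry_per_chrom.tsv")))
  blocks <- detect_blocks(prof$profile, an$block_min_freq, an$block_max_gap,
                          an$block_min_sites)
  add(write_tsv(blocks, file.path(out_dir, "maternal_blocks.tsv")))
  if (nrow(blocks)) {
    mask <- data.frame(chrom = blocks$chrom, start = blocks$start - 1L,
                       end = blocks$end)
    add(write_region_mask(mask, file.path(out_dir, "block_mask.bed")))
  } else mask <- NULL

  ## observed retained maternal loci outside detected blocks, both BC100 groups
  wt_group <- sub("_pigm", "_wt", bc_group)
  retained <- 0L
  for (grp in intersect(c(bc_group, wt_group), cross$geno$samples$group)) {
    pr <- ancestry_profile(cross$geno, diag, grp, mask = mask)$profile
    retained <- retained + sum(pr$n_maternal > 0)
  }

  ## -- nulltest ----------------------------------------------------------
  nt <- cfg$nulltest
  null <- simulate_drift(N = nt$N, generations = nt$generations,
                         reps = nt$reps, seed = seed + 5,
                         keep_trajectories = FALSE)
  ex <- excess_test(observed = max(retained, 0), null = null,
                    sites_per_genome = nrow(diag))
  summary <- list(seed = seed, thresholds = thresholds,
                  n_diagnostic_sites = nrow(diag),
                  n_blocks = nrow(blocks),
                  observed_retained_masked = retained,
                  null = list(N = nt$N, generations = nt$generations,
                              reps = nt$reps,
                              frac_absorbed = mean(!is.na(null$absorption_gen)),
                              max_terminal_p = max(null$terminal_p)),
                  excess_p = ex$p_value)
  sm_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sm_path, auto_unbox = TRUE, digits = NA)
  add(sm_path)

  ## -- manifest ----------------------------------------------------------
  cfg_tmp <- tempfile()
  yaml::write_yaml(cfg, cfg_tmp)
  manifest <- list(
    tool = "hybridsex",
    version = as.character(utils::packageVersion("hybridsex")),
    subcommand = "all", seed = seed,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
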