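test_that("parental strains are fixed for alternative alleles at every site", {
  g <- genome_model(n_chromosomes = 2, chrom_length = 10e6, sex_chrom = 2,
                    sd_region = c(5e6, 9e6), diagnostic_density = 10)
  par <- make_parents(g, seed = 42)
  expect_equal(nrow(par$geno$gt), 200)  # 2 x 10 Mb x 10/Mb
  grp <- par$geno$samples$group
  gm <- par$geno$gt[, grp == "parentM", drop = FALSE]
  gp <- par$geno$gt[, grp == "parentP", drop = FALSE]
  expect_true(all(gm %in% c(0L, 2L)) && all(gp %in% c(0L, 2L)))
  expect_true(all(gm[, 1] == 2L - gp[, 1]))           # fixed difference
  expect_true(all(gm == gm[, 1]) && all(gp == gp[, 1]))
  # site coordinates sorted within chromosome
  for (ch in unique(par$geno$sites$chrom))
    expect_false(is.unsorted(par$geno$sites$pos[par$geno$sites$chrom == ch]))
  # maternal allele recorded consistently with parentM genotypes
  expect_equal(par$truth$maternal,
               ifelse(par$truth$maternal_is_alt, par$geno$sites$alt,
                      par$geno$sites$ref))
})

test_that("genome model rejects degenerate configurations", {
  expect_error(genome_model(chrom_length = 0), "zero-length")
  expect_error(genome_model(sd_region = c(30e6, 40e6)), "sd_region")
  expect_error(genome_model(diagnostic_density = 0), "diagnostic_density")
})

test_that("synthetic outputs are deterministic under a fixed seed", {
  g <- small_genome()
  p1 <- make_parents(g, seed = 9)
  p2 <- make_parents(g, seed = 9)
  expect_identical(p1, p2)
  c1 <- simulate_cross(p1, cross_design(generations = 3, n_bc1 = 6, n_bc100 = 6, seed = 4))
  c2 <- simulate_cross(p2, cross_design(generations = 3, n_bc1 = 6, n_bc100 = 6, seed = 4))
  expect_identical(c1$geno$gt, c2$geno$gt)
  expect_identical(c1$breakpoints, c2$breakpoints)
  v1 <- tempfile(fileext = ".vcf.gz"); v2 <- tempfile(fileext = ".vcf.gz")
  write_vcf(c1$geno, v1, seed = 4); write_vcf(c2$geno, v2, seed = 4)
  expect_identical(readLines(v1, warn = FALSE), readLines(v2, warn = FALSE))
})

test_that("F1 individuals are heterozygous at every diagnostic site", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 2),
                       cross_design(generations = 0, n_f1 = 4, seed = 3))
  f1 <- cr$geno$gt[, cr$geno$samples$group == "F1", drop = FALSE]
  expect_true(all(f1 == 1L))
  # maternal fraction exactly 0.5 for F1-only designs
  expect_equal(mean(cr$truth$dosage[, cr$geno$samples$group == "F1"]) / 2, 0.5)
})

test_that("neutral BC1 maternal fraction matches the Mendelian 0.25", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 5),
                       cross_design(generations = 1, selection = FALSE,
                                    n_bc1 = 4000, seed = 6))
  bc <- cr$geno$samples$group %in% c("BC1_wt", "BC1_pigm")
  per_ind <- colMeans(cr$truth$dosage[, bc]) / 2
  se <- stats::sd(per_ind) / sqrt(length(per_ind))
  expect_lt(abs(mean(per_ind) - 0.25), 3 * se)
})

test_that("allele counts are conserved at every site (Mendelian bookkeeping)", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 7),
                       cross_design(generations = 2, n_bc1 = 8, n_bc100 = 8, seed = 8))
  dose <- cr$truth$dosage
  n_ind <- ncol(dose)
  maternal <- rowSums(dose)
  paternal <- rowSums(2L - dose)
  expect_true(all(maternal + paternal == 2L * n_ind))
})

test_that("suppressed translocation keeps breakpoints out and moves the block", {
  g <- genome_model(n_chromosomes = 3, chrom_length = 25e6, sex_chrom = 3,
                    sd_region = c(13e6, 23e6), diagnostic_density = 5)
  tr <- translocation_event(dest_chrom = 2, dest_start = 8e6, generation = 1)
  cr <- simulate_cross(make_parents(g, seed = 11),
                       cross_design(generations = 20, n_bc1 = 6, n_bc100 = 10,
                                    translocation = tr, seed = 12))
  # no crossover ever lands inside the suppressed destination interval
  bp2 <- cr$breakpoints[cr$breakpoints$chrom == "LG2", ]
  expect_gt(nrow(bp2), 0)
  expect_false(any(bp2$pos >= 8e6 & bp2$pos < 18e6))
  # every selected carrier holds a contiguous heterozygous maternal block on
  # LG2 (native destination sites inside the suppressed interval)
  pig <- cr$geno$samples$group == "BC100_pigm"
  native <- cr$truth$sites$chrom == "LG2" &
    pos_in_interval(cr$truth$sites$pos, 8e6, 18e6)
  expect_true(all(cr$truth$dosage[native, pig] == 1L))
  # and non-carriers hold none
  wt <- cr$geno$samples$group == "BC100_wt"
  expect_true(all(cr$truth$dosage[native, wt] == 0L))
})

test_that("hybrid sex follows presence of the maternal SD block", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 21),
                       cross_design(generations = 2, n_bc1 = 10, n_bc100 = 10,
                                    seed = 22))
  marker <- which(cr$truth$sites$is_marker)
  bc <- grepl("^BC", cr$geno$samples$group)
  carrier <- cr$truth$dosage[marker, bc] == 1L
  expect_equal(unname(cr$geno$samples$sex[bc] == "F"), unname(carrier))
})

test_that("coverage counts follow the dosage model", {
  labels <- c(rep("A", 300), rep("W", 100), rep("Z", 100))
  cov <- simulate_coverage(labels, n_f = 40, n_m = 40,
                           model = coverage_model(mean_depth = 20, dispersion = 5),
                           seed = 31)
  sex <- cov$samples$sex
  mF <- rowMeans(cov$counts[, sex == "F"]); mM <- rowMeans(cov$counts[, sex == "M"])
  expect_lt(abs(mean(mF[labels == "A"]) - 20), 1)
  expect_lt(abs(mean(mM[labels == "A"]) - 20), 1)
  expect_lt(abs(mean(mF[labels == "W"]) - 10), 1)
  expect_lt(mean(mM[labels == "W"]), 1)       # residual mismapping only
  expect_lt(abs(mean(mM[labels == "Z"]) / mean(mF[labels == "Z"]) - 2), 0.15)
  # determinism
  cov2 <- simulate_coverage(labels, 40, 40,
                            coverage_model(20, 5), seed = 31)
  expect_identical(cov$counts, cov2$counts)
})
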