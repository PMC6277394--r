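test_that("the three diagnostic criteria select exactly the textbook sites", {
  geno <- toy_pedigree()
  diag <- select_diagnostic_sites(geno, completeness = 0)
  expect_equal(diag$id, c("s1", "s5"))
  expect_equal(diag$maternal, c("T", "A"))   # s5 has maternal = REF
  expect_equal(diag$paternal, c("A", "T"))
  att <- attr(diag, "attrition")
  expect_equal(unname(att["criterion1"]), 4)   # s2 fails fixed-difference
  expect_equal(unname(att["criterion12"]), 3)  # s3 fails F1 heterozygosity
  expect_equal(unname(att["criterion123"]), 2) # s4 fails the paternal-allele rule
  # missing F1 group is a hard error
  no_f1 <- subset_group(geno, c("parentM", "parentP", "BC1_wt"))
  expect_error(select_diagnostic_sites(no_f1), "F1")
})

test_that("diagnostic selection on simulated crosses recovers the truth set", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 3),
                       cross_design(generations = 2, n_bc1 = 8, n_bc100 = 8, seed = 4))
  diag <- select_diagnostic_sites(cr$geno)
  expect_equal(nrow(diag), nrow(cr$truth$sites))      # 100% of truth recovered
  expect_equal(diag$maternal, cr$truth$sites$maternal)
  # with missing genotypes the selection stays a subset of the truth set
  cr2 <- simulate_cross(make_parents(g, seed = 3),
                        cross_design(generations = 2, n_bc1 = 8, n_bc100 = 8,
                                     missing_rate = 0.05, seed = 4))
  diag2 <- select_diagnostic_sites(cr2$geno)
  expect_lte(nrow(diag2), nrow(cr2$truth$sites))
  expect_true(all(diag2$id %in% cr2$truth$sites$id))
  m <- match(diag2$id, cr2$truth$sites$id)
  expect_equal(diag2$maternal, cr2$truth$sites$maternal[m])
})

test_that("allele tallies and frequencies follow the counting rules", {
  geno <- toy_pedigree()
  diag <- select_diagnostic_sites(geno, completeness = 0)
  # F1: heterozygous at every diagnostic site by criterion 2
  f1 <- tally_alleles(geno, diag, "F1")
  expect_equal(f1$prop_maternal, 0.5)
  expect_equal(f1$maternal + f1$paternal, f1$total)
  expect_equal(f1$total, 2L * 2L * nrow(diag))
  # 8 diploids with 2 heterozygotes at one site: frequency 2/16 = 0.125
  gt <- matrix(0L, 1, 8); gt[1, 1:2] <- 1L
  g8 <- geno_set(gt, data.frame(id = "q", chrom = "LG1", pos = 9L,
                                ref = "A", alt = "T"),
                 data.frame(sample = paste0("x", 1:8), sex = "U",
                            group = "BC100_wt"))
  d8 <- data.frame(id = "q", chrom = "LG1", pos = 9L, maternal = "T",
                   paternal = "A", maternal_is_alt = TRUE)
  t8 <- tally_alleles(g8, d8, "BC100_wt")
  expect_equal(t8$maternal / t8$total, 0.125)
  pr <- ancestry_profile(g8, d8, "BC100_wt")
  expect_equal(pr$profile$freq, 0.125)
  # empty group: zero-filled row
  t0 <- tally_alleles(geno, diag, "BC100_pigm")
  expect_equal(t0$total, 0L)
})

test_that("expected backcross counts reproduce Mendelian halving", {
  e1 <- expected_counts(1, 355252)
  expect_equal(e1$paternal, 266439)
  expect_equal(e1$maternal, 88813)
  e0 <- expected_counts(0, 260758)
  expect_equal(c(e0$paternal, e0$maternal), c(130379, 130379))
  # a .5 expectation truncates toward zero
  e1b <- expected_counts(1, 436414)
  expect_equal(c(e1b$paternal, e1b$maternal), c(327310, 109103))
  # generation 100: maternal expectation below one allele
  e100 <- expected_counts(100, 525502)
  expect_equal(e100$maternal, 0)
  expect_lt(0.5^101 * 525502, 1)
})

test_that("segregation table lines up observed and expected by group", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 19),
                       cross_design(generations = 2, n_bc1 = 10, n_bc100 = 10,
                                    seed = 20))
  diag <- select_diagnostic_sites(cr$geno)
  seg <- segregation_table(cr$geno, diag)
  expect_setequal(seg$group, c("F1", "BC1_wt", "BC1_pigm", "BC100_wt", "BC100_pigm"))
  f1 <- seg[seg$group == "F1", ]
  expect_equal(f1$prop_maternal, 0.5)
  expect_equal(f1$expected_maternal, f1$maternal)
  expect_equal(seg$expected_prop_maternal[seg$group == "BC1_wt"], 0.25)
  expect_true(all(seg$maternal + seg$paternal == seg$total))
})

test_that("ancestry profiles count maternal-carrying sites per chromosome", {
  g <- small_genome()
  cr <- simulate_cross(make_parents(g, seed = 23),
                       cross_design(generations = 1, n_bc1 = 8, seed = 24))
  diag <- select_diagnostic_sites(cr$geno)
  # F1: every chromosome's maternal-site count equals its diagnostic count
  pf <- ancestry_profile(cr$geno, diag, "F1")
  tab <- table(diag$chrom)
  expect_equal(pf$per_chrom$n_sites_maternal,
               as.integer(tab[pf$per_chrom$chrom]))
  expect_true(all(pf$profile$freq == 0.5))
  # parentP carries no maternal alleles anywhere
  pp <- ancestry_profile(cr$geno, diag, "parentP")
  expect_true(all(pp$profile$n_maternal == 0))
  expect_true(all(pp$per_chrom$n_sites_maternal == 0))
})

test_that("block detection follows the run/gap/minimum-site rules", {
  prof <- data.frame(id = paste0("s", 1:30), chrom = "LG2",
                     pos = seq(1e6, 30e6, by = 1e6),
                     n_maternal = 0L, n_alleles = 20L,
                     freq = c(rep(0, 5), rep(0.6, 12), 0, 0, rep(0.7, 3),
                              rep(0, 8)))
  # sites 6..17 pass; the 2-site gap bridges to sites 20..22
  b <- detect_blocks(prof, min_freq = 0.5, max_gap_sites = 2, min_block_sites = 10)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_sites, 15)
  expect_equal(c(b$start, b$end), c(6e6, 22e6))
  # a wider gap splits the run, leaving only the 12-site block
  b2 <- detect_blocks(prof, min_freq = 0.5, max_gap_sites = 1, min_block_sites = 10)
  expect_equal(b2$n_sites, 12)
  # all-zero frequencies: no blocks; an isolated site never forms a block
  prof0 <- transform(prof, freq = 0)
  expect_equal(nrow(detect_blocks(prof0)), 0)
  prof1 <- transform(prof, freq = c(1, rep(0, 29)))
  expect_equal(nrow(detect_blocks(prof1)), 0)
})

test_that("a translocated block is recovered at its destination and maskable", {
  g <- genome_model(n_chromosomes = 4, chrom_length = 25e6, sex_chrom = 4,
                    sd_region = c(13e6, 23e6), diagnostic_density = 5)
  tr <- translocation_event(dest_chrom = 2, dest_start = 8e6)
  cr <- simulate_cross(make_parents(g, seed = 33),
                       cross_design(generations = 30, n_bc1 = 8, n_bc100 = 10,
                                    translocation = tr, seed = 34))
  diag <- select_diagnostic_sites(cr$geno)
  prof <- ancestry_profile(cr$geno, diag, "BC100_pigm")
  blocks <- detect_blocks(prof$profile)
  b2 <- blocks[blocks$chrom == "LG2", ]
  expect_equal(nrow(b2), 1)
  expect_gte(interval_jaccard(b2$start, b2$end, 8e6 + 1, 18e6), 0.85)
  # masking the detected block leaves only residual maternal counts on LG2
  mask <- data.frame(chrom = "LG2", start = b2$start - 1, end = b2$end)
  masked <- ancestry_profile(cr$geno, diag, "BC100_pigm", mask = mask)
  lg2 <- masked$per_chrom[masked$per_chrom$chrom == "LG2", ]
  expect_lt(lg2$n_sites_maternal, b2$n_sites)
})
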