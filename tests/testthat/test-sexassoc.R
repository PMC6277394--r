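test_that("allelic 2x2 tables count allele copies per sex", {
  # 2 het females, 2 hom-ref males
  tab <- allele_table(c(1, 1, 0, 0), c("F", "F", "M", "M"))
  expect_equal(unname(tab), rbind(c(2, 2), c(4, 0)))
  # monomorphic: all hom-ref
  tab2 <- allele_table(c(0, 0, 0, 0), c("F", "F", "M", "M"))
  expect_equal(unname(tab2), rbind(c(4, 0), c(4, 0)))
  expect_equal(fisher_exact_2x2(tab2), 1)
  # 30 het females vs 30 hom-ref males
  tab3 <- allele_table(rep(c(1, 0), each = 30), rep(c("F", "M"), each = 30))
  expect_equal(unname(tab3), rbind(c(30, 30), c(60, 0)))
  # margins equal twice the non-missing diploids per sex
  tab4 <- allele_table(c(1, NA, 2, 0, NA, 1), c("F", "F", "F", "M", "M", "M"))
  expect_equal(unname(rowSums(tab4)), c(4, 4))
  # a sex with only missing genotypes skips the site
  expect_message(res <- allele_table(c(NA, NA, 0, 1), c("F", "F", "M", "M")),
                 "missing in sex F")
  expect_null(res)
})

test_that("exact test matches hand-enumerated values and conventions", {
  expect_equal(fisher_exact_2x2(rbind(c(1, 1), c(1, 1))), 1)
  # all 3 tables with margins (2,2,2,2): probabilities 1/6, 4/6, 1/6
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3)
  # extreme sex-linked table is far beyond the genome-wide threshold
  p <- fisher_exact_2x2(rbind(c(30, 30), c(60, 0)))
  expect_lt(p, 7.64e-7)
  expect_equal(p, fisher_oracle(rbind(c(30, 30), c(60, 0))), tolerance = 1e-12)
  # zero margin: p = 1 by convention
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 2))), 1)
})

test_that("transposing the 2x2 table leaves the p-value unchanged", {
  set.seed(7)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_exact_2x2(t(tab)),
                 tolerance = 1e-12)
  }
})

test_that("exact test agrees with the enumeration oracle on moderate tables", {
  # spot-check grid; the exhaustive sweep runs in the acceptance suite
  set.seed(3)
  for (i in 1:200) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-9,
                 info = paste(tab, collapse = ","))
  }
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(signif(genomewide_threshold(0.05, 65417), 3), 7.64e-7)
  expect_equal(genomewide_threshold(0.05, 1), 0.05)
  expect_equal(genomewide_threshold(0.05, 5e5), 1e-7)
  expect_error(genomewide_threshold(0, 10))
})

test_that("scan flags the SD region with female heterozygosity excess", {
  g <- genome_model()
  zw <- simulate_zw_population(g, n_f = 30, n_m = 30, seed = 5)
  scan <- sex_scan(zw$geno)
  sd <- zw$truth$sex_linkage == "SD"
  expect_gte(mean(scan$passes_genomewide[sd]), 0.95)
  expect_true(all(scan$het_F[sd] > scan$het_M[sd]))
  expect_equal(sum(scan$passes_genomewide[!sd]), 0)
  # monomorphic single site: p = 1, no flags
  mono <- geno_set(matrix(0L, 1, 6),
                   data.frame(id = "m", chrom = "LG1", pos = 1L, ref = "A", alt = "T"),
                   data.frame(sample = paste0("s", 1:6),
                              sex = rep(c("F", "M"), 3), group = "pop"))
  sm <- sex_scan(mono)
  expect_equal(sm$p, 1)
  expect_false(sm$passes_genomewide | sm$passes_suggestive)
})

test_that("permuted sex labels produce at most alpha expected hits", {
  g <- genome_model(n_chromosomes = 2, chrom_length = 10e6, sex_chrom = 2,
                    sd_region = c(9.8e6, 10e6), diagnostic_density = 10)
  zw <- simulate_zw_population(g, n_f = 30, n_m = 30, seed = 8)
  # drop the (few) genuinely sex-linked sites; permute labels on the rest
  keep <- zw$truth$sex_linkage == "A"
  geno <- geno_set(zw$geno$gt[keep, ], zw$geno$sites[keep, ], zw$geno$samples)
  set.seed(42)
  hits <- replicate(100, {
    perm <- geno
    perm$samples$sex <- sample(perm$samples$sex)
    sum(sex_scan(perm)$passes_genomewide)
  })
  expect_lte(mean(hits), 0.05)
})

test_that("Weir-Cockerham components match the ANOVA oracle and edge cases", {
  mk <- function(gF, gM) {
    gt <- matrix(c(gF, gM), nrow = 1)
    geno_set(gt, data.frame(id = "x", chrom = "LG1", pos = 1L, ref = "A", alt = "T"),
             data.frame(sample = paste0("s", seq_along(gt)),
                        sex = rep(c("F", "M"), c(length(gF), length(gM))),
                        group = "pop"))
  }
  # fixed difference, 30/30 diploids: theta = 1
  f <- wc_fst(mk(rep(2L, 30), rep(0L, 30)))
  expect_equal(f$theta, 1)
  # identical genotype vectors in both groups: never counted as differentiated
  f2 <- wc_fst(mk(c(0L, 1L, 2L, 1L, 0L), c(0L, 1L, 2L, 1L, 0L)))
  expect_true(is.na(f2$theta) || f2$theta <= 0)
  # monomorphic: undefined and unusable
  f3 <- wc_fst(mk(rep(0L, 10), rep(0L, 10)))
  expect_true(is.na(f3$theta))
  expect_false(f3$usable)
  # random polymorphic sites agree with the independent ANOVA route
  set.seed(17)
  for (i in 1:25) {
    gF <- as.integer(rbinom(12, 2, runif(1, 0.2, 0.8)))
    gM <- as.integer(rbinom(9, 2, runif(1, 0.2, 0.8)))
    if (sum(gF) + sum(gM) %in% c(0, 2 * (12 + 9))) next
    f <- wc_fst(mk(gF, gM))
    o <- wc_anova_oracle(gF, gM)
    expect_equal(f$a, o$a, tolerance = 1e-10)
    expect_equal(f$b, o$b, tolerance = 1e-10)
    expect_equal(f$c, o$c, tolerance = 1e-10)
    if (f$usable) expect_equal(f$theta, o$theta, tolerance = 1e-10)
  }
})

test_that("windowed F_ST aggregates and thresholds by nearest rank", {
  # a window whose only site has theta matches the per-site value
  fst <- data.frame(id = "x", chrom = "LG1", pos = 500L, a = 0.3, b = 0.1,
                    c = 0.2, theta = 0.5, usable = TRUE)
  w <- windowed_fst(fst, c(LG1 = 2000), 1000)
  expect_equal(nrow(w), 2)
  expect_equal(w$fst_weighted[1], 0.5)
  expect_equal(w$fst_mean[1], 0.5)
  expect_true(is.na(w$fst_weighted[2]))
  # all-theta-1 window
  fst2 <- data.frame(id = c("a", "b"), chrom = "LG1", pos = c(100L, 900L),
                     a = c(0.2, 0.4), b = 0, c = 0, theta = 1, usable = TRUE)
  expect_equal(windowed_fst(fst2, c(LG1 = 1000), 1000)$fst_weighted, 1)
  # nearest-rank percentile on 1..100
  expect_equal(top_threshold(1:100, 0.99), 99)
  expect_equal(top_threshold(c(1:100, NA), 0.99), 99)
})

test_that("flagged windows concentrate on the sex-determining region", {
  g <- genome_model()
  zw <- simulate_zw_population(g, seed = 5)
  wf <- windowed_fst(wc_fst(zw$geno), g$chrom_lengths, 1e5)
  th <- top_threshold(wf$fst_weighted, 0.99)
  flagged <- wf[!is.na(wf$fst_weighted) & wf$fst_weighted >= th, ]
  on_sd <- flagged$chrom == "LG21" & flagged$start >= 13e6 & flagged$start < 23e6
  expect_gte(mean(on_sd), 0.8)
})
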