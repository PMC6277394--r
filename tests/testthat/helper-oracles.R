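# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher p by explicit hypergeometric enumeration over the table
# support, independent of stats::fisher.test.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  d <- dhyper(support, r1, r2, c1)
  d0 <- dhyper(tab[1, 1], r1, r2, c1)
  sum(d[d <= d0 * (1 + 1e-7)])
}

# Weir-Cockerham components via the nested ANOVA on raw allele copies
# (mean-squares route), independent of the closed-form moment estimator.
wc_anova_oracle <- function(gF, gM) {
  gF <- gF[!is.na(gF)]; gM <- gM[!is.na(gM)]
  pops <- list(gF, gM)
  n_i <- lengths(pops)
  r <- 2
  copies <- function(g) cbind(pmin(g, 1), pmax(g - 1, 0)) # dosage -> 2 allele copies
  ind_means <- unlist(lapply(pops, function(g) g / 2))
  pop_of <- rep(1:2, n_i)
  pop_means <- vapply(1:2, function(i) mean(pops[[i]]) / 2, numeric(1))
  x <- do.call(rbind, lapply(pops, copies))
  ssw <- sum((x - ind_means)^2)
  ssi <- 2 * sum((ind_means - pop_means[pop_of])^2)
  grand <- sum(n_i * pop_means) / sum(n_i)
  ssp <- 2 * sum(n_i * (pop_means - grand)^2)
  n_tot <- sum(n_i)
  msw <- ssw / n_tot
  msi <- ssi / (n_tot - r)
  msp <- ssp / (r - 1)
  nbar <- n_tot / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  c_ <- msw
  b_ <- (msi - msw) / 2
  a_ <- (msp - msi) / (2 * nc)
  list(a = a_, b = b_, c = c_, theta = a_ / (a_ + b_ + c_))
}

# Interval Jaccard overlap for 1-based inclusive intervals.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  union <- (e1 - s1 + 1) + (e2 - s2 + 1) - inter
  inter / union
}

# A small three-chromosome genome for fast simulations.
small_genome <- function(density = 4) {
  genome_model(n_chromosomes = 3, chrom_length = 5e6, sex_chrom = 2,
               sd_region = c(2e6, 4e6), diagnostic_density = density)
}

# Hand-built pedigree genotype set exercising the diagnostic criteria.
# Site patterns (dosage of ALT), samples: 2 parentM, 2 parentP, 2 F1, 2 BC1_wt:
#   s1: textbook diagnostic (M=2/2, P=0/0, F1=1/1, BC ok)
#   s2: parents share the allele       -> fails criterion 1
#   s3: F1 not heterozygous            -> fails criterion 2
#   s4: one BC homozygous-maternal     -> fails criterion 3
#   s5: diagnostic with maternal = REF
toy_pedigree <- function() {
  gt <- rbind(
    s1 = c(2, 2, 0, 0, 1, 1, 1, 0),
    s2 = c(2, 2, 2, 2, 1, 1, 0, 0),
    s3 = c(2, 2, 0, 0, 1, 2, 1, 0),
    s4 = c(2, 2, 0, 0, 1, 1, 2, 1),
    s5 = c(0, 0, 2, 2, 1, 1, 1, 2))
  sites <- data.frame(id = rownames(gt), chrom = "LG1",
                      pos = c(100L, 200L, 300L, 400L, 500L),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = c("m1", "m2", "p1", "p2", "f1a", "f1b", "b1", "b2"),
    sex = c("F", "M", "F", "M", "F", "F", "M", "M"),
    group = c("parentM", "parentM", "parentP", "parentP", "F1", "F1",
              "BC1_wt", "BC1_wt"),
    stringsAsFactors = FALSE)
  geno_set(gt, sites, samples)
}

# Plain-text VCF writer for fixtures (deliberately simple; tests only).
write_plain_vcf <- function(path, chrom, pos, id, ref, alt, gt_strings,
                            sample_names) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i)
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_strings[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}
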