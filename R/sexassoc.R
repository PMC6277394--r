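#' Allelic 2x2 table for one site
#'
#' Counts REF and ALT allele copies among female and male diploids (the
#' allelic case/control encoding used by standard association tools in
#' Fisher mode). Missing genotypes contribute nothing; each non-missing
#' diploid contributes two alleles, so every row margin equals twice the
#' number of non-missing samples of that sex.
#'
#' @param gt integer vector of ALT dosages (0/1/2/NA) at one site.
#' @param sex character vector of the same length with entries "F"/"M"
#'   (other labels are ignored).
#' @return 2x2 integer matrix with rows F/M and columns REF/ALT, or `NULL`
#'   (with a message) if either sex has only missing genotypes.
#' @export
allele_table <- function(gt, sex) {
  fm <- sex %in% c("F", "M")
  gt <- gt[fm]; sex <- sex[fm]
  out <- matrix(0L, 2, 2, dimnames = list(c("F", "M"), c("REF", "ALT")))
  for (s in c("F", "M")) {
    g <- gt[sex == s & !is.na(gt)]
    if (!length(g)) {
      message("site skipped: all genotypes missing in sex ", s)
      return(NULL)
    }
    out[s, "ALT"] <- sum(g)
    out[s, "REF"] <- 2L * length(g) - sum(g)
  }
  out
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Exact conditional test: sums hypergeometric probabilities of all tables
#' (given the margins) whose probability does not exceed the observed
#' table's, with the usual relative tie tolerance of 1e-7. A table with a
#' zero margin is uninformative and returns p = 1 by convention.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
genomewide_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Per-SNP exact allelic sex-association scan
#'
#' Runs [allele_table()] + [fisher_exact_2x2()] at every site, reports the
#' heterozygosity in each sex and its excess direction, and flags sites
#' against the Bonferroni genome-wide threshold (`alpha/m`) and a
#' suggestive threshold. A site is a genome-wide hit when p is below the
#' threshold *and* females show excess heterozygosity (`het_F > het_M`),
#' the signature of a ZW system.
#'
#' @param geno a [geno_set()]; sexes are taken from the sample sheet.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests for the Bonferroni correction; defaults to the
#'   number of sites scanned.
#' @param suggestive_p suggestive threshold (default 1e-4).
#' @param genotypic logical; use the 3x2 genotypic encoding instead of the
#'   allelic 2x2 (default FALSE).
#' @return data.frame with one row per scanned site: `id`, `chrom`, `pos`,
#'   `p`, `neg_log10_p`, `het_F`, `het_M`, `het_excess_F`,
#'   `passes_genomewide`, `passes_suggestive`. The thresholds used are
#'   attached as attributes `"genomewide_p"` and `"suggestive_p"`.
#' @export
sex_scan <- function(geno, alpha = 0.05, m = NULL, suggestive_p = 1e-4,
                     genotypic = FALSE) {
  sex <- geno$samples$sex
  if (sum(sex == "F") < 2 || sum(sex == "M") < 2)
    stop("need at least 2 samples of each sex")
  gt <- geno$gt
  n <- nrow(gt)
  p <- rep(NA_real_, n)
  hF <- rep(NA_real_, n); hM <- rep(NA_real_, n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    g <- gt[i, ]
    if (genotypic) {
      tab <- table(factor(g, levels = 0:2), factor(sex, levels = c("F", "M")))
      if (any(colSums(tab) == 0)) next
      key <- paste(tab, collapse = ",")
      p[i] <- if (!is.null(cache[[key]])) cache[[key]] else {
        pv <- if (any(rowSums(tab) > 0)) stats::fisher.test(tab)$p.value else 1
        cache[[key]] <- pv; pv
      }
    } else {
      tab <- allele_table(g, sex)
      if (is.null(tab)) next
      key <- paste(tab, collapse = ",")
      p[i] <- if (!is.null(cache[[key]])) cache[[key]] else {
        pv <- fisher_exact_2x2(tab)
        cache[[key]] <- pv; pv
      }
    }
    hF[i] <- mean(g[sex == "F" & !is.na(g)] == 1)
    hM[i] <- mean(g[sex == "M" & !is.na(g)] == 1)
  }
  if (is.null(m)) m <- sum(!is.na(p))
  gw <- genomewide_threshold(alpha, m)
  res <- data.frame(id = geno$sites$id, chrom = geno$sites$chrom,
                    pos = geno$sites$pos, p = p, neg_log10_p = -log10(p),
                    het_F = hF, het_M = hM, het_excess_F = hF > hM,
                    passes_genomewide = !is.na(p) & p < gw & hF > hM,
                    passes_suggestive = !is.na(p) & p < suggestive_p,
                    stringsAsFactors = FALSE)
  attr(res, "genomewide_p") <- gw
  attr(res, "suggestive_p") <- suggestive_p
  res
}

#' Per-site Weir-Cockerham variance components between the sexes
#'
#' Computes, for every site, the three variance components of the
#' Weir & Cockerham F_ST estimator for two groups (females and males):
#' `a` (among groups), `b` (among individuals within groups) and `c`
#' (within individuals), plus the per-site estimate
#' `theta = a / (a + b + c)`. Sites where a group has fewer than two
#' non-missing diploids, or where `a + b + c == 0` (monomorphic), get
#' `NA` theta and are excluded from windowed summaries.
#'
#' @param geno a [geno_set()].
#' @return data.frame with columns `id`, `chrom`, `pos`, `a`, `b`, `c`,
#'   `theta`, `usable`.
#' @export
wc_fst <- function(geno) {
  sex <- geno$samples$sex
  gt <- geno$gt
  gF <- gt[, sex == "F", drop = FALSE]
  gM <- gt[, sex == "M", drop = FALSE]
  n1 <- rowSums(!is.na(gF)); n2 <- rowSums(!is.na(gM))
  p1 <- rowSums(gF, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gM, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(gF == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(gM == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(is.finite(denom) & denom != 0, a / denom, NA_real_)
  ok <- n1 >= 2 & n2 >= 2
  theta[!ok] <- NA_real_
  data.frame(id = geno$sites$id, chrom = geno$sites$chrom,
             pos = geno$sites$pos,
             a = ifelse(ok, a, NA_real_), b = ifelse(ok, b, NA_real_),
             c = ifelse(ok, cc, NA_real_), theta = theta,
             usable = ok & is.finite(denom) & denom != 0,
             stringsAsFactors = FALSE)
}

#' Windowed F_ST over non-overlapping tiling windows
#'
#' Aggregates per-site Weir-Cockerham components into non-overlapping
#' windows of a fixed size tiling each chromosome. The window estimate is
#' the ratio of sums `sum(a) / sum(a + b + c)` over usable sites (the
#' weighted estimator); the mean of per-site theta is reported alongside.
#' Windows with no usable site are emitted with `NA` F_ST and are excluded
#' from percentile thresholds.
#'
#' @param fst per-site component table from [wc_fst()].
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window_size window width in bp (e.g. 1e3, 1e4, 1e5).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `n_sites`, `fst_weighted`, `fst_mean`.
#' @export
windowed_fst <- function(fst, chrom_lengths, window_size) {
  stopifnot(window_size > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    n_win <- ceiling(chrom_lengths[[ch]] / window_size)
    win <- data.frame(chrom = ch,
                      start = (seq_len(n_win) - 1) * window_size,
                      end = pmin(seq_len(n_win) * window_size, chrom_lengths[[ch]]),
                      n_sites = 0L, fst_weighted = NA_real_, fst_mean = NA_real_,
                      stringsAsFactors = FALSE)
    f <- fst[fst$chrom == ch & fst$usable, , drop = FALSE]
    if (nrow(f)) {
      wi <- floor((f$pos - 1) / window_size) + 1L
      num <- tapply(f$a, wi, sum)
      den <- tapply(f$a + f$b + f$c, wi, sum)
      mth <- tapply(f$theta, wi, mean)
      cnt <- tapply(f$theta, wi, length)
      idx <- as.integer(names(num))
      win$n_sites[idx] <- as.integer(cnt)
      win$fst_weighted[idx] <- ifelse(den != 0, num / den, NA_real_)
      win$fst_mean[idx] <- mth
    }
    win
  })
  do.call(rbind, out)
}

#' Nearest-rank upper-percentile threshold
#'
#' The q-th percentile by the nearest-rank convention: the
#' `ceiling(q * n)`-th order statistic of the non-missing values.
#'
#' @param values numeric vector (NAs dropped).
#' @param q quantile level (default 0.99).
#' @return the threshold value.
#' @export
top_threshold <- function(values, q = 0.99) {
  v <- sort(values[!is.na(values)])
  if (!length(v)) return(NA_real_)
  v[ceiling(q * length(v))]
}
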