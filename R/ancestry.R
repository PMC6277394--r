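#' Select species-diagnostic sites through the pedigree
#'
#' Applies the three fixed-difference criteria to a pedigree genotype set:
#' (1) all non-missing genotypes are homozygous within each parental strain
#' and the two strains carry different alleles; (2) every non-missing F1
#' genotype is heterozygous (hence carries both parental variants); (3)
#' every non-missing backcross individual, over all BC groups present,
#' carries at least one paternal allele (i.e. is never homozygous for the
#' maternal allele). Only sites passing all three are returned, with the
#' maternal/paternal allele assignment taken from the parental strains.
#'
#' @param geno a [geno_set()] containing `parentM`, `parentP` and `F1`
#'   samples (BC groups optional; criterion 3 is applied over whichever are
#'   present).
#' @param completeness minimum fraction of non-missing genotypes per site
#'   across all samples (default 0.8); sites below it are dropped first.
#' @return data.frame of diagnostic sites: `id`, `chrom`, `pos`, `maternal`,
#'   `paternal`, `maternal_is_alt`. Per-criterion attrition counts are
#'   attached as attribute `"attrition"`.
#' @export
select_diagnostic_sites <- function(geno, completeness = 0.8) {
  grp <- geno$samples$group
  if (!any(grp == "parentM") || !any(grp == "parentP"))
    stop("both parental strains required")
  if (!any(grp == "F1")) stop("no F1 samples: criterion 2 cannot be evaluated")
  gt <- geno$gt
  n0 <- nrow(gt)
  keep <- rowMeans(!is.na(gt)) >= completeness
  gt <- gt[keep, , drop = FALSE]
  sites <- geno$sites[keep, , drop = FALSE]

  gm <- gt[, grp == "parentM", drop = FALSE]
  gp <- gt[, grp == "parentP", drop = FALSE]
  hom_fixed <- function(g) {
    # all non-missing genotypes homozygous and identical; NA if no data
    mx <- apply(g, 1, function(x) {
      x <- x[!is.na(x)]
      if (!length(x) || any(x == 1L) || length(unique(x)) > 1) NA_integer_ else x[1]
    })
    mx
  }
  am <- hom_fixed(gm)
  ap <- hom_fixed(gp)
  c1 <- !is.na(am) & !is.na(ap) & am != ap

  gf <- gt[, grp == "F1", drop = FALSE]
  c2 <- apply(gf, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && all(x == 1L)
  })

  bc <- grp %in% c("BC1_wt", "BC1_pigm", "BC100_wt", "BC100_pigm")
  if (any(bc)) {
    gb <- gt[, bc, drop = FALSE]
    ## maternal hom dosage per site (am is maternal allele's dosage code)
    mat_hom <- am   # 0 or 2 (NA where c1 fails)
    c3 <- vapply(seq_len(nrow(gb)), function(i) {
      if (is.na(mat_hom[i])) return(FALSE)
      x <- gb[i, ]
      x <- x[!is.na(x)]
      !any(x == mat_hom[i])   # nobody homozygous-maternal
    }, logical(1))
  } else c3 <- rep(TRUE, nrow(gt))

  pass <- c1 & c2 & c3
  out <- data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos,
                    maternal = ifelse(am == 2L, sites$alt, sites$ref),
                    paternal = ifelse(am == 2L, sites$ref, sites$alt),
                    maternal_is_alt = am == 2L,
                    stringsAsFactors = FALSE)[pass, , drop = FALSE]
  attr(out, "attrition") <- c(input = n0, complete = nrow(gt),
                              criterion1 = sum(c1),
                              criterion12 = sum(c1 & c2),
                              criterion123 = sum(pass))
  rownames(out) <- NULL
  out
}

## maternal-allele dosage matrix at diagnostic sites for a set of samples
maternal_dosage <- function(geno, diag_sites, samples_keep) {
  gt <- geno$gt[match(diag_sites$id, geno$sites$id), samples_keep, drop = FALSE]
  flip <- !diag_sites$maternal_is_alt
  gt[flip, ] <- 2L - gt[flip, , drop = FALSE]
  gt   # now counts maternal-allele copies; NA preserved
}

#' Tally maternal and paternal alleles in one pedigree group
#'
#' Sums maternal-allele copies over all diagnostic sites and non-missing
#' genotypes of the group. Proportions are reported to three decimals
#' (half-even rounding, as customarily printed).
#'
#' @param geno a [geno_set()].
#' @param diag_sites diagnostic sites from [select_diagnostic_sites()].
#' @param group pedigree group label to tally.
#' @return one-row data.frame: `group`, `n_samples`, `paternal`, `maternal`
#'   (allele counts), `total`, `prop_paternal`, `prop_maternal`,
#'   `n_sites_maternal` (sites with at least one maternal allele).
#' @export
tally_alleles <- function(geno, diag_sites, group) {
  keep <- geno$samples$group == group
  if (!any(keep))
    return(data.frame(group = group, n_samples = 0L, paternal = 0L,
                      maternal = 0L, total = 0L, prop_paternal = NA_real_,
                      prop_maternal = NA_real_, n_sites_maternal = 0L))
  md <- maternal_dosage(geno, diag_sites, keep)
  mat <- sum(md, na.rm = TRUE)
  tot <- 2L * sum(!is.na(md))
  data.frame(group = group, n_samples = sum(keep),
             paternal = tot - mat, maternal = mat, total = tot,
             prop_paternal = round((tot - mat) / tot, 3),
             prop_maternal = round(mat / tot, 3),
             n_sites_maternal = sum(rowSums(md, na.rm = TRUE) > 0L),
             stringsAsFactors = FALSE)
}

#' Expected backcross segregation counts
#'
#' Under Mendelian backcrossing the expected maternal-allele proportion at
#' backcross generation g is `0.5^(g+1)` (g = 0 denotes the F1). Expected
#' counts are the proportions applied to the observed allele total and
#' truncated toward zero to whole alleles.
#'
#' @param g backcross generation (0 = F1).
#' @param total total number of observed alleles.
#' @return data.frame with `paternal`, `maternal` expected counts and
#'   `prop_paternal`, `prop_maternal`.
#' @export
expected_counts <- function(g, total) {
  stopifnot(g >= 0, total >= 0)
  p_mat <- 0.5^(g + 1)
  data.frame(paternal = trunc((1 - p_mat) * total),
             maternal = trunc(p_mat * total),
             prop_paternal = 1 - p_mat, prop_maternal = p_mat)
}

group_generation <- c(F1 = 0, BC1_wt = 1, BC1_pigm = 1,
                      BC100_wt = 100, BC100_pigm = 100)

#' Observed-versus-expected segregation table across pedigree groups
#'
#' Builds the per-group observed maternal/paternal tallies and the matching
#' Mendelian expectations (F1 at generation 0, BC1 at 1, BC100 at 100).
#'
#' @param geno a [geno_set()].
#' @param diag_sites diagnostic sites from [select_diagnostic_sites()].
#' @param groups groups to include; defaults to all pedigree groups present
#'   beyond the parents.
#' @return data.frame with observed and expected counts and proportions per
#'   group.
#' @export
segregation_table <- function(geno, diag_sites, groups = NULL) {
  if (is.null(groups))
    groups <- intersect(names(group_generation), unique(geno$samples$group))
  rows <- lapply(groups, function(g) {
    obs <- tally_alleles(geno, diag_sites, g)
    exp <- expected_counts(group_generation[[g]], obs$total)
    cbind(obs, expected_paternal = exp$paternal, expected_maternal = exp$maternal,
          expected_prop_maternal = exp$prop_maternal)
  })
  do.call(rbind, rows)
}

#' Maternal-ancestry profile of a pedigree group
#'
#' Per-site maternal-ancestry frequency (maternal alleles over non-missing
#' alleles) for one group, sorted by position, with per-chromosome counts
#' of sites carrying at least one maternal allele. An optional region mask
#' is applied first (see [apply_mask()]).
#'
#' @param geno a [geno_set()].
#' @param diag_sites diagnostic sites from [select_diagnostic_sites()].
#' @param group pedigree group label.
#' @param mask optional mask data.frame (`chrom`, `start`, `end`).
#' @return list with `profile` (data.frame: `id`, `chrom`, `pos`, `n_maternal`,
#'   `n_alleles`, `freq`) and `per_chrom` (data.frame: `chrom`,
#'   `n_sites`, `n_sites_maternal`).
#' @export
ancestry_profile <- function(geno, diag_sites, group, mask = NULL) {
  sites <- apply_mask(diag_sites, mask)
  keep <- geno$samples$group == group
  if (!any(keep)) stop("no samples in group ", group)
  md <- maternal_dosage(geno, sites, keep)
  n_mat <- rowSums(md, na.rm = TRUE)
  n_all <- 2L * rowSums(!is.na(md))
  prof <- data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos,
                     n_maternal = n_mat, n_alleles = n_all,
                     freq = ifelse(n_all > 0, n_mat / n_all, NA_real_),
                     stringsAsFactors = FALSE)
  prof <- prof[order(prof$chrom, prof$pos), , drop = FALSE]
  rownames(prof) <- NULL
  per_chrom <- aggregate(cbind(n_sites = freq, n_sites_maternal = n_maternal) ~ chrom,
                         data = transform(prof, freq = 1L,
                                          n_maternal = as.integer(n_maternal > 0L)),
                         FUN = sum)
  list(profile = prof, per_chrom = per_chrom)
}

#' Detect retained maternal-ancestry blocks
#'
#' Scans each chromosome's ordered diagnostic sites for maximal runs with
#' maternal-ancestry frequency at or above `min_freq`, tolerating
#' interruptions of up to `max_gap_sites` consecutive below-threshold
#' sites inside a block. Blocks with fewer than `min_block_sites`
#' above-threshold sites are discarded. Block bounds are the first and last
#' above-threshold site positions.
#'
#' @param profile the `profile` element of [ancestry_profile()].
#' @param min_freq frequency threshold (default 0.5).
#' @param max_gap_sites maximum consecutive below-threshold sites bridged
#'   (default 2).
#' @param min_block_sites minimum above-threshold sites per block
#'   (default 10).
#' @return data.frame with `chrom`, `start`, `end` (1-based inclusive
#'   positions), `n_sites`, `mean_freq`, `span_mb`.
#' @export
detect_blocks <- function(profile, min_freq = 0.5, max_gap_sites = 2,
                          min_block_sites = 10) {
  out <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, , drop = FALSE]
    pr <- pr[order(pr$pos), , drop = FALSE]
    hit <- !is.na(pr$freq) & pr$freq >= min_freq
    i <- which(hit)
    if (!length(i)) next
    ## split above-threshold sites wherever more than max_gap_sites
    ## below-threshold sites (or any NA-frequency site) intervene
    brk <- which(diff(i) > max_gap_sites + 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(i))
    for (b in seq_along(starts)) {
      idx <- i[starts[b]:ends[b]]
      if (length(idx) < min_block_sites) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = pr$pos[idx[1]], end = pr$pos[idx[length(idx)]],
        n_sites = length(idx), mean_freq = mean(pr$freq[idx]),
        span_mb = (pr$pos[idx[length(idx)]] - pr$pos[idx[1]]) / 1e6,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sites = integer(), mean_freq = numeric(),
                      span_mb = numeric()))
  do.call(rbind, out)
}
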