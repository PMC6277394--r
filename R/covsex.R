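#' Median-ratio size factors for a coverage matrix
#'
#' Median-of-ratios normalization: the per-locus reference is the geometric
#' mean across samples, computed over loci with no zero count; the factor
#' for sample j is the median over those loci of `count[i, j] / ref[i]`.
#' Normalized counts are `raw / factor`.
#'
#' @param counts locus x sample matrix of raw read counts.
#' @return numeric vector of per-sample size factors.
#' @export
mrn_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  log_geo <- rowMeans(log(counts))
  ref_ok <- is.finite(log_geo)          # loci with no zero count
  if (!any(ref_ok))
    stop("no locus with nonzero counts in every sample; ",
         "consider a pseudo-reference fallback (drop all-zero-prone loci)")
  ref <- exp(log_geo[ref_ok])
  apply(counts[ref_ok, , drop = FALSE], 2,
        function(cnts) median(cnts / ref))
}

#' @rdname mrn_size_factors
#' @return `mrn_normalize()` returns the matrix of normalized counts.
#' @export
mrn_normalize <- function(counts) {
  sf <- mrn_size_factors(counts)
  sweep(as.matrix(counts), 2, sf, "/")
}

#' Mean-coverage locus filter
#'
#' Retains loci whose overall mean coverage (across all samples) lies in
#' `[min_mean, max_mean]`. Only loci strictly below the lower bound (likely
#' mapping errors) or strictly above the upper bound (repetitive elements)
#' are removed; boundary values are kept.
#'
#' @param norm normalized locus x sample matrix.
#' @param min_mean,max_mean inclusive bounds (defaults 3 and 400).
#' @return character vector of retained locus ids (rownames of `norm`).
#' @export
filter_loci <- function(norm, min_mean = 3, max_mean = 400) {
  stopifnot(min_mean < max_mean, min_mean > 0)
  mu <- rowMeans(norm)
  rownames(norm)[mu >= min_mean & mu <= max_mean]
}

#' Classify loci as W-linked, Z-linked or neither from coverage dosage
#'
#' W-linked loci are present only in ZW females: mean coverage in females
#' above `w_female_min` and in males below `w_male_max`. Z-linked loci have
#' two copies in ZZ males versus one in females: male/female mean ratio
#' above `z_ratio_min`. The two calls are mutually exclusive with W taking
#' priority; a locus with zero female mean is ineligible for the ratio
#' rule. All thresholds are strict inequalities.
#'
#' @param norm normalized locus x sample matrix (see `use_raw` note in the
#'   package vignette; pass a raw matrix to classify on raw counts).
#' @param sex per-sample sex vector ("F"/"M") aligned with the columns.
#' @param w_female_min,w_male_max,z_ratio_min thresholds
#'   (defaults 7, 2, 1.9).
#' @return data.frame with `locus`, `mean_F`, `mean_M`, `ratio_MF`, `call`
#'   (one of "W", "Z", "none").
#' @export
classify_sex_linked <- function(norm, sex, w_female_min = 7, w_male_max = 2,
                                z_ratio_min = 1.9) {
  stopifnot(any(sex == "F"), any(sex == "M"),
            w_female_min > 0, w_male_max > 0, z_ratio_min > 0)
  mF <- rowMeans(norm[, sex == "F", drop = FALSE])
  mM <- rowMeans(norm[, sex == "M", drop = FALSE])
  ratio <- ifelse(mF > 0, mM / mF, NA_real_)
  call <- rep("none", nrow(norm))
  is_w <- mF > w_female_min & mM < w_male_max
  is_z <- !is_w & !is.na(ratio) & ratio > z_ratio_min
  call[is_w] <- "W"
  call[is_z] <- "Z"
  data.frame(locus = rownames(norm), mean_F = mF, mean_M = mM,
             ratio_MF = ratio, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-chromosome over-representation of candidate sex-linked loci
#'
#' For each chromosome, builds the 2x2 table (called vs not called) x (on
#' this chromosome vs elsewhere) over the mapped background loci and runs a
#' two-sided Fisher exact test; Bonferroni-adjusted p-values across
#' chromosomes are reported alongside the share of called loci on each
#' chromosome.
#'
#' @param called_chrom chromosome labels of the called (candidate) loci.
#' @param background_chrom chromosome labels of all retained, mapped loci
#'   (must include the called ones).
#' @return data.frame with `chrom`, `n_called`, `share_called`,
#'   `n_background`, `p`, `p_bonferroni`, sorted by p. Empty if there are
#'   no called loci.
#' @export
overrepresentation <- function(called_chrom, background_chrom) {
  if (!length(called_chrom))
    return(data.frame(chrom = character(), n_called = integer(),
                      share_called = numeric(), n_background = integer(),
                      p = numeric(), p_bonferroni = numeric()))
  chroms <- sort(unique(background_chrom))
  skipped <- setdiff(unique(called_chrom), chroms)
  if (length(skipped))
    message("called loci on chromosome(s) absent from background skipped: ",
            paste(skipped, collapse = ", "))
  called_chrom <- called_chrom[called_chrom %in% chroms]
  n_call <- length(called_chrom)
  n_bg <- length(background_chrom)
  rows <- lapply(chroms, function(ch) {
    k <- sum(called_chrom == ch)
    b <- sum(background_chrom == ch)
    tab <- matrix(c(k, n_call - k, b - k, (n_bg - b) - (n_call - k)), 2, 2)
    data.frame(chrom = ch, n_called = k, share_called = k / n_call,
               n_background = b, p = fisher_exact_2x2(tab),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * length(chroms))
  out[order(out$p), , drop = FALSE]
}

#' Full coverage-based sex-linkage analysis
#'
#' Convenience wrapper: normalizes raw counts by median-ratio size factors,
#' applies the mean-coverage filter, classifies W/Z-linked loci, and (if a
#' locus map is given) tests per-chromosome over-representation of the
#' candidates.
#'
#' @param counts raw locus x sample count matrix.
#' @param sex per-sample sex vector aligned with columns.
#' @param locus_map optional data.frame (`locus`, `chrom`) mapping loci to
#'   chromosomes.
#' @param min_mean,max_mean,w_female_min,w_male_max,z_ratio_min thresholds,
#'   see [filter_loci()] and [classify_sex_linked()].
#' @param use_raw classify on raw rather than normalized counts
#'   (default FALSE).
#' @return list with `size_factors`, `retained` (locus ids), `calls`
#'   (classification table restricted to retained loci), `w_test`/`z_test`
#'   (over-representation tables, or NULL without a locus map).
#' @export
covsex_analysis <- function(counts, sex, locus_map = NULL,
                            min_mean = 3, max_mean = 400,
                            w_female_min = 7, w_male_max = 2,
                            z_ratio_min = 1.9, use_raw = FALSE) {
  sf <- mrn_size_factors(counts)
  norm <- sweep(as.matrix(counts), 2, sf, "/")
  keep <- filter_loci(norm, min_mean, max_mean)
  mat <- if (use_raw) as.matrix(counts)[keep, , drop = FALSE]
         else norm[keep, , drop = FALSE]
  calls <- classify_sex_linked(mat, sex, w_female_min, w_male_max, z_ratio_min)
  w_test <- z_test <- NULL
  if (!is.null(locus_map)) {
    ## calls rows align with `keep`
    bg <- locus_map$chrom[match(keep, locus_map$locus)]
    mapped <- !is.na(bg)
    for (cl in c("W", "Z")) {
      sel <- which(calls$call == cl & mapped)
      res <- overrepresentation(bg[sel], bg[mapped])
      if (cl == "W") w_test <- res else z_test <- res
    }
  }
  list(size_factors = sf, retained = keep, calls = calls,
       w_test = w_test, z_test = z_test)
}
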