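#' @keywords internal
"_PACKAGE"

#' @importFrom stats fisher.test median rbinom rnbinom runif setNames aggregate
#' @importFrom utils read.table write.table
#' @importFrom methods new
NULL

## Pedigree-group vocabulary. "pop" covers single-species population samples
## (e.g. a 30F/30M wild-strain panel) that carry no pedigree information.
PEDIGREE_GROUPS <- c("parentM", "parentP", "F1",
                     "BC1_wt", "BC1_pigm", "BC100_wt", "BC100_pigm", "pop")

#' Genotype set: diploid calls with site and sample metadata
#'
#' The central container used throughout the package. Genotypes are stored as
#' an integer matrix of ALT-allele dosages (sites x samples): 0 = homozygous
#' REF, 1 = heterozygous, 2 = homozygous ALT, `NA` = missing. Sites are
#' biallelic SNPs with 1-based positions (VCF convention); all interval
#' arithmetic inside the package uses 0-based half-open coordinates and
#' converts at the boundary (see [bed_to_pos1()]).
#'
#' @param gt integer matrix, sites x samples, values in {0, 1, 2, NA}.
#' @param sites data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per row of `gt`; (chrom, pos) must be unique.
#' @param samples data.frame with columns `sample`, `sex` (one of "F", "M",
#'   "U") and `group` (pedigree vocabulary, see Details); one row per column
#'   of `gt`.
#'
#' @details Allowed groups are `parentM` (maternal parental strain),
#'   `parentP` (paternal parental strain), `F1`, `BC1_wt`, `BC1_pigm`,
#'   `BC100_wt`, `BC100_pigm`, and `pop` for population samples outside the
#'   pedigree.
#'
#' @return An object of class `geno_set`: a list with elements `gt`, `sites`,
#'   `samples`.
#' @export
geno_set <- function(gt, sites, samples) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  stopifnot(nrow(gt) == nrow(sites), ncol(gt) == nrow(samples))
  if (!all(gt %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) in site map")
  validate_sample_sheet(samples)
  rownames(gt) <- sites$id
  colnames(gt) <- samples$sample
  structure(list(gt = gt,
                 sites = as.data.frame(sites, stringsAsFactors = FALSE),
                 samples = as.data.frame(samples, stringsAsFactors = FALSE)),
            class = "geno_set")
}

validate_sample_sheet <- function(samples) {
  req <- c("sample", "sex", "group")
  if (!all(req %in% names(samples)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  bad_sex <- which(!samples$sex %in% c("F", "M", "U"))
  if (length(bad_sex))
    stop("invalid sex label for sample '", samples$sample[bad_sex[1]],
         "': '", samples$sex[bad_sex[1]], "' (expected F, M or U)")
  bad_grp <- which(!samples$group %in% PEDIGREE_GROUPS)
  if (length(bad_grp))
    stop("unknown pedigree group for sample '", samples$sample[bad_grp[1]],
         "': '", samples$group[bad_grp[1]], "'")
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in sample sheet")
  invisible(TRUE)
}

#' @export
#' @method print geno_set
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$gt), "sites x", ncol(x$gt), "samples\n")
  cat("  chromosomes:", length(unique(x$sites$chrom)), "\n")
  cat("  groups:", paste(sprintf("%s(%d)", names(table(x$samples$group)),
                                 table(x$samples$group)), collapse = " "), "\n")
  miss <- mean(is.na(x$gt))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype set by sample group
#'
#' @param geno a [geno_set()].
#' @param groups character vector of pedigree groups to keep.
#' @return a `geno_set` restricted to samples in `groups`.
#' @export
subset_group <- function(geno, groups) {
  keep <- geno$samples$group %in% groups
  if (!any(keep)) stop("no samples in group(s): ", paste(groups, collapse = ", "))
  geno_set(geno$gt[, keep, drop = FALSE], geno$sites,
           geno$samples[keep, , drop = FALSE])
}

## 1-based SNP position -> 0-based half-open interval membership
pos_in_interval <- function(pos, start, end) {
  (pos - 1L) >= start & (pos - 1L) < end
}

#' Convert between 1-based positions and 0-based half-open intervals
#'
#' `pos1_to_bed()` turns a 1-based inclusive interval \[first, last\] into the
#' BED-style 0-based half-open \[start, end); `bed_to_pos1()` is its inverse.
#' The two are involutive, which the test suite checks by property.
#'
#' @param first,last 1-based inclusive bounds.
#' @param start,end 0-based half-open bounds.
#' @return a two-column matrix of converted bounds.
#' @export
pos1_to_bed <- function(first, last) {
  cbind(start = first - 1, end = last)
}

#' @rdname pos1_to_bed
#' @export
bed_to_pos1 <- function(start, end) {
  cbind(first = start + 1, last = end)
}
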