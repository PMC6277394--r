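#' Read diploid genotypes from a VCF file with a sample sheet
#'
#' Loads GT calls from a VCF v4.2 file (only the GT FORMAT field is used),
#' joins them with a per-sample sheet giving sex and pedigree group, and
#' returns a [geno_set()]. Multi-allelic sites are dropped with a warning
#' reporting the count; non-diploid calls are a hard error.
#'
#' @param vcf_path path to a VCF (optionally gzip-compressed).
#' @param sheet either a path to a tab-separated sample sheet with columns
#'   `sample`, `sex`, `group`, or a data.frame with those columns.
#' @return a `geno_set`. Per-sample missingness is attached as attribute
#'   `"missingness"`.
#' @export
read_genotypes <- function(vcf_path, sheet) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  validate_sample_sheet(sheet)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) dropped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  vcf_samples <- colnames(gt_chr)
  missing_in_sheet <- setdiff(vcf_samples, sheet$sample)
  if (length(missing_in_sheet))
    stop("VCF sample(s) absent from sample sheet: ",
         paste(missing_in_sheet, collapse = ", "))
  sheet <- sheet[match(vcf_samples, sheet$sample), , drop = FALSE]

  gt_chr[gt_chr == "." | gt_chr == "./." | gt_chr == ".|."] <- NA
  alleles <- strsplit(gsub("|", "/", gt_chr, fixed = TRUE), "/", fixed = TRUE)
  ploidy <- lengths(alleles)
  bad <- !is.na(gt_chr) & ploidy != 2L
  if (any(bad)) {
    i <- which(bad)[1]
    stop("non-diploid genotype '", gt_chr[i], "' at site ",
         rownames(gt_chr)[(i - 1) %% nrow(gt_chr) + 1])
  }
  dose <- vapply(alleles, function(a) {
    if (length(a) != 2L || anyNA(suppressWarnings(as.integer(a)))) return(NA_integer_)
    sum(as.integer(a))
  }, integer(1))
  gt <- matrix(dose, nrow = nrow(gt_chr), ncol = ncol(gt_chr),
               dimnames = dimnames(gt_chr))

  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, "_", fix$POS)[is.na(ids) | ids == "."]
  sites <- data.frame(id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  out <- geno_set(gt, sites, sheet)
  attr(out, "missingness") <- colMeans(is.na(gt))
  out
}

#' Write a genotype set to VCF v4.2
#'
#' Only the GT field is emitted. The file is gzip-compressed by
#' [vcfR::write.vcf()]; [read_genotypes()] reads it back transparently.
#'
#' @param geno a [geno_set()].
#' @param path output path (conventionally ending in `.vcf.gz`).
#' @param seed optional integer recorded in the header as
#'   `##hybridsex_seed=` for provenance.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path, seed = NULL) {
  n_site <- nrow(geno$gt)
  meta <- c("##fileformat=VCFv4.2",
            paste0("##source=hybridsex_", as.character(utils::packageVersion("hybridsex"))),
            if (!is.null(seed)) paste0("##hybridsex_seed=", seed),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fix <- cbind(CHROM = as.character(geno$sites$chrom),
               POS = as.character(geno$sites$pos),
               ID = as.character(geno$sites$id),
               REF = as.character(geno$sites$ref),
               ALT = as.character(geno$sites$alt),
               QUAL = rep(".", n_site), FILTER = rep("PASS", n_site),
               INFO = rep(".", n_site))
  gt_chr <- matrix(c("0/0", "0/1", "1/1")[geno$gt + 1L],
                   nrow = n_site, dimnames = dimnames(geno$gt))
  gt_chr[is.na(gt_chr)] <- "./."
  gt_out <- cbind(FORMAT = rep("GT", n_site), gt_chr)
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt_out)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read and write tab-separated tables used by the pipeline
#'
#' Sample sheets (`sample`, `sex`, `group`), locus maps
#' (`locus`, `chrom`, `pos`) and locus x sample coverage matrices are all
#' plain TSV with a header row. Coverage matrices have locus ids in the
#' first column and integer read counts in the remaining columns.
#'
#' @param path file path.
#' @return `read_sample_sheet()` and `read_locus_map()` return data.frames;
#'   `read_coverage_matrix()` returns an integer matrix with locus rownames.
#' @export
read_sample_sheet <- function(path) {
  sh <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  validate_sample_sheet(sh)
  sh
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
read_coverage_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_sample_sheet
#' @param counts locus x sample integer matrix.
#' @export
write_coverage_matrix <- function(counts, path) {
  tab <- data.frame(locus = rownames(counts), counts, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_sample_sheet
#' @export
read_locus_map <- function(path) {
  lm <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("locus", "chrom") %in% names(lm)))
    stop("locus map needs columns 'locus' and 'chrom'")
  lm
}

#' @rdname read_sample_sheet
#' @param locus_map data.frame to write.
#' @export
write_locus_map <- function(locus_map, path) {
  write.table(locus_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Region masks in BED convention
#'
#' Masks are 0-based half-open intervals, the BED convention, both on disk
#' (three tab-separated columns, no header) and in memory.
#'
#' @param path BED file path.
#' @return `read_region_mask()` returns a data.frame with columns `chrom`,
#'   `start`, `end`.
#' @export
read_region_mask <- function(path) {
  bed <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed <- bed[, 1:3]
  if (any(bed$start >= bed$end)) stop("mask intervals must satisfy start < end")
  bed
}

#' @rdname read_region_mask
#' @param mask data.frame with columns `chrom`, `start`, `end`.
#' @export
write_region_mask <- function(mask, path) {
  stopifnot(all(mask$start < mask$end))
  write.table(mask[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove sites falling inside masked regions
#'
#' Sites whose (1-based) position lies inside any half-open masked interval
#' are removed; the number removed is reported via `message()`. A mask that
#' removes every site yields an empty site map with a warning.
#'
#' @param sites site map data.frame with columns `chrom`, `pos`.
#' @param mask data.frame of masked regions (`chrom`, `start`, `end`,
#'   0-based half-open), or `NULL` for no masking.
#' @return the retained rows of `sites`.
#' @export
apply_mask <- function(sites, mask) {
  if (is.null(mask) || nrow(mask) == 0) return(sites)
  drop <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(mask))) {
    drop <- drop | (sites$chrom == mask$chrom[i] &
                    pos_in_interval(sites$pos, mask$start[i], mask$end[i]))
  }
  message(sum(drop), " site(s) removed by mask")
  if (all(drop)) warning("mask removed all sites")
  sites[!drop, , drop = FALSE]
}
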