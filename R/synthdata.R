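#' Genome model for the synthetic study system
#'
#' Describes the karyotype used by the simulators: a set of linkage groups
#' (LGs), one of which carries the ZW pair with a terminal non-recombining
#' sex-determining (SD) region and a complementary pseudoautosomal region
#' (PAR). Defaults mirror a 24-LG poeciliid genome with the SD region
#' occupying roughly the distal 10 Mb of the sex linkage group.
#'
#' @param n_chromosomes number of linkage groups (default 24).
#' @param chrom_length length in bp of each LG; scalar or vector of length
#'   `n_chromosomes`.
#' @param sex_chrom index of the LG carrying the ZW pair (default 21).
#' @param sd_region numeric length-2, 0-based half-open interval \[start, end)
#'   in bp of the non-recombining SD region on `sex_chrom` (default 13-23 Mb).
#' @param diagnostic_density expected species-diagnostic sites per Mb fixed
#'   between the two parental strains (default 5).
#' @return an object of class `genome_model`.
#' @export
genome_model <- function(n_chromosomes = 24, chrom_length = 25e6,
                         sex_chrom = 21, sd_region = c(13e6, 23e6),
                         diagnostic_density = 5) {
  lens <- rep_len(chrom_length, n_chromosomes)
  if (any(lens <= 0)) stop("zero-length chromosome in genome model")
  if (sex_chrom < 1 || sex_chrom > n_chromosomes)
    stop("sex_chrom outside 1..n_chromosomes")
  if (sd_region[1] >= sd_region[2] || sd_region[2] > lens[sex_chrom])
    stop("sd_region must be a non-empty interval within the sex chromosome")
  if (diagnostic_density <= 0) stop("diagnostic_density must be > 0")
  ## PAR = everything on the sex LG outside the SD region
  par_region <- rbind(if (sd_region[1] > 0) c(0, sd_region[1]),
                      if (sd_region[2] < lens[sex_chrom]) c(sd_region[2], lens[sex_chrom]))
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_lengths = setNames(lens, paste0("LG", seq_len(n_chromosomes))),
                 sex_chrom = sex_chrom,
                 chrom_names = paste0("LG", seq_len(n_chromosomes)),
                 sd_region = sd_region,
                 par_region = par_region,
                 diagnostic_density = diagnostic_density),
            class = "genome_model")
}

## Draw sorted unique site positions (1-based) per chromosome at a given
## per-Mb density. Returns a data.frame(chrom, pos).
draw_site_positions <- function(genome, density) {
  out <- lapply(seq_len(genome$n_chromosomes), function(ci) {
    len <- genome$chrom_lengths[ci]
    n <- max(1L, round(density * len / 1e6))
    data.frame(chrom = genome$chrom_names[ci],
               pos = sort(sample.int(len, n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

site_linkage_label <- function(genome, chrom, pos) {
  sexc <- genome$chrom_names[genome$sex_chrom]
  ifelse(chrom == sexc & pos_in_interval(pos, genome$sd_region[1], genome$sd_region[2]),
         "SD", "A")
}

#' Simulate the two parental strains
#'
#' Places species-diagnostic sites along the genome and genotypes the two
#' parental strains: at every diagnostic site the maternal strain is
#' homozygous for one allele and the paternal strain homozygous for the
#' other. Whether the maternal allele is REF or ALT is randomized per site
#' and recorded in the truth table.
#'
#' @param genome a [genome_model()].
#' @param n_per_strain samples per parental strain (default 4: two of each
#'   sex).
#' @param seed RNG seed.
#' @return list with elements `geno` (a [geno_set()] of the parental
#'   samples), `truth` (data.frame: `id`, `chrom`, `pos`, `maternal`,
#'   `paternal`, `maternal_is_alt`, `sex_linkage` in {A, SD}) and `genome`.
#' @export
make_parents <- function(genome, n_per_strain = 4, seed = 1) {
  set.seed(seed)
  sp <- draw_site_positions(genome, genome$diagnostic_density)
  n <- nrow(sp)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  maternal_is_alt <- sample(c(TRUE, FALSE), n, replace = TRUE)
  sites <- data.frame(id = paste0("d", seq_len(n)), chrom = sp$chrom,
                      pos = sp$pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = c(paste0("matP", seq_len(n_per_strain)),
               paste0("patP", seq_len(n_per_strain))),
    sex = rep(rep_len(c("F", "M"), n_per_strain), 2),
    group = rep(c("parentM", "parentP"), each = n_per_strain),
    stringsAsFactors = FALSE)
  ## maternal strain: 2 copies of the maternal allele; paternal: 0
  mat_dose <- ifelse(maternal_is_alt, 2L, 0L)
  pat_dose <- 2L - mat_dose
  gt <- cbind(matrix(mat_dose, n, n_per_strain),
              matrix(pat_dose, n, n_per_strain))
  truth <- data.frame(id = sites$id, chrom = sites$chrom, pos = sites$pos,
                      maternal = ifelse(maternal_is_alt, alt, ref),
                      paternal = ifelse(maternal_is_alt, ref, alt),
                      maternal_is_alt = maternal_is_alt,
                      sex_linkage = site_linkage_label(genome, sites$chrom, sites$pos),
                      stringsAsFactors = FALSE)
  list(geno = geno_set(gt, sites, samples), truth = truth, genome = genome)
}

#' Translocation event description
#'
#' Moves the maternal copy of a sex-chromosome interval (which must contain
#' the selected marker) onto an autosome during the backcross, optionally
#' suppressing recombination across the destination interval. The
#' destination interval has the same width as the source.
#'
#' @param src 0-based half-open source interval on the sex chromosome;
#'   `NULL` (default) means the whole SD region.
#' @param dest_chrom destination chromosome index.
#' @param dest_start 0-based start of the destination interval.
#' @param generation backcross generation at whose meiosis the rearranged
#'   linkage first applies (default 1: the first backcross, when the donor
#'   maternal haplotype is still intact).
#' @param suppressed logical; forbid crossovers inside the destination
#'   interval (default TRUE).
#' @return an object of class `translocation_event`.
#' @export
translocation_event <- function(src = NULL, dest_chrom = 2, dest_start = 8e6,
                                generation = 1, suppressed = TRUE) {
  structure(list(src = src, dest_chrom = dest_chrom, dest_start = dest_start,
                 generation = generation, suppressed = suppressed),
            class = "translocation_event")
}

#' Backcross design
#'
#' Parameters of the serial backcross: a hybrid female is mated to a
#' paternal-strain male each generation; offspring carrying the maternal
#' sex-determining/marker allele develop as females ("pigm" phenotype when a
#' pigmentation marker rides with the SD block), and one carrier female is
#' chosen to mother the next generation.
#'
#' @param generations number of backcross generations (default 100).
#' @param brood_size offspring simulated per generation (default 20).
#' @param selection logical; require the line mother to carry the marker
#'   block (default TRUE). Because hybrid females are by construction SD
#'   carriers, turning this off matters only when the marker differs from
#'   the SD locus.
#' @param marker_locus 1-based position of the selected marker on the sex
#'   chromosome; `NULL` (default) uses the diagnostic site nearest the SD
#'   region midpoint. Must lie inside the SD region.
#' @param n_crossovers crossovers per chromosome per meiosis (default 1),
#'   placed uniformly.
#' @param translocation optional [translocation_event()].
#' @param n_f1,n_bc1,n_bc100 samples recorded for the F1 group, the
#'   first-backcross brood and the final-generation brood (defaults 4, 16,
#'   18, matching a small pedigree sequencing panel). Recorded broods are
#'   split evenly between carriers (`*_pigm`) and non-carriers (`*_wt`).
#' @param misassignment_rate probability a recorded individual's sex label
#'   contradicts its SD genotype (default 0).
#' @param missing_rate flat genotype missingness applied to the output
#'   (default 0).
#' @param retries resampling attempts when a brood lacks a required carrier.
#' @param seed RNG seed.
#' @return an object of class `cross_design`.
#' @export
cross_design <- function(generations = 100, brood_size = 20, selection = TRUE,
                         marker_locus = NULL, n_crossovers = 1,
                         translocation = NULL, n_f1 = 4, n_bc1 = 16,
                         n_bc100 = 18, misassignment_rate = 0,
                         missing_rate = 0, retries = 50, seed = 1) {
  stopifnot(generations >= 0, brood_size >= 1, n_crossovers >= 0,
            misassignment_rate >= 0, misassignment_rate <= 1,
            missing_rate >= 0, missing_rate < 1)
  structure(list(generations = generations, brood_size = brood_size,
                 selection = selection, marker_locus = marker_locus,
                 n_crossovers = n_crossovers, translocation = translocation,
                 n_f1 = n_f1, n_bc1 = n_bc1, n_bc100 = n_bc100,
                 misassignment_rate = misassignment_rate,
                 missing_rate = missing_rate, retries = retries, seed = seed),
            class = "cross_design")
}

## Linkage coordinates of each site at backcross generation g: after the
## translocation generation, sites inside the source interval segregate with
## the destination chromosome.
linkage_map <- function(truth, genome, trans, g) {
  lchrom <- truth$chrom
  lpos <- truth$pos
  if (!is.null(trans) && g >= trans$generation) {
    src <- trans$src
    sexc <- genome$chrom_names[genome$sex_chrom]
    moved <- truth$chrom == sexc & pos_in_interval(truth$pos, src[1], src[2])
    lchrom[moved] <- genome$chrom_names[trans$dest_chrom]
    lpos[moved] <- trans$dest_start + (truth$pos[moved] - 1 - src[1]) + 1
  }
  list(chrom = lchrom, pos = lpos)
}

## One round of meioses from a mother with maternal-origin haplotype h1 and
## an all-paternal homolog. Returns the gamete maternal-origin bit matrix
## (sites x n) and the breakpoint log. Breakpoints avoid `suppress[[chrom]]`
## intervals (0-based half-open) by drawing from the complement.
meiosis_gametes <- function(h1, map, chrom_lengths, n, n_crossovers,
                            suppress = list()) {
  S <- length(h1)
  gam <- matrix(0L, S, n)
  bp_log <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    P <- map$pos[idx]
    L <- max(chrom_lengths[ch], max(P), na.rm = TRUE)
    sup <- suppress[[ch]]
    crosses <- matrix(0L, length(idx), n)
    if (n_crossovers > 0) {
      k <- n_crossovers
      if (is.null(sup)) {
        bp <- matrix(runif(k * n, 0, L), k, n)
      } else {
        w <- sup[2] - sup[1]
        bp <- matrix(runif(k * n, 0, L - w), k, n)
        bp[bp >= sup[1]] <- bp[bp >= sup[1]] + w
      }
      for (j in seq_len(k)) {
        crosses <- crosses + outer(P - 1, bp[j, ], ">")  # breakpoint left of site
      }
      bp_log[[ch]] <- data.frame(chrom = ch, pos = as.vector(bp),
                                 meiosis = rep(seq_len(n), each = k),
                                 stringsAsFactors = FALSE)
    }
    phase <- matrix(rep(sample(0:1, n, replace = TRUE), each = length(idx)),
                    length(idx), n)
    hap <- (phase + crosses) %% 2           # 0 = maternal-origin homolog
    gam[idx, ] <- h1[idx] * (hap == 0L)     # paternal homolog carries 0 bits
  }
  list(gam = gam, breakpoints = do.call(rbind, bp_log))
}

#' Simulate a serial backcross pedigree
#'
#' Starting from an F1 female (heterozygous maternal/paternal at every
#' diagnostic site), repeatedly backcrosses to the paternal strain. Each
#' offspring receives one recombined gamete from the hybrid mother and one
#' all-paternal gamete. Offspring sex is female iff the maternal SD/marker
#' allele is present (after a translocation, presence of the translocated
#' block). Broods are recorded at generation 1 (`BC1_*`) and at the final
#' generation (`BC100_*` labels, following the study group vocabulary
#' regardless of the exact generation count).
#'
#' @param parents output of [make_parents()].
#' @param design a [cross_design()].
#' @return list with elements `geno` (a [geno_set()] containing parents, F1
#'   and recorded backcross samples), `truth` (site truth plus the
#'   maternal-allele dosage matrix `dosage` for all samples), `breakpoints`
#'   (crossover log with generation), `design`, `genome`.
#' @export
simulate_cross <- function(parents, design) {
  genome <- parents$genome
  truth <- parents$truth
  set.seed(design$seed)
  S <- nrow(truth)
  sexc <- genome$chrom_names[genome$sex_chrom]

  ## marker site: nearest diagnostic site to marker_locus inside the SD region
  sd_idx <- which(truth$sex_linkage == "SD")
  if (!length(sd_idx)) stop("no diagnostic sites inside the SD region")
  target <- if (is.null(design$marker_locus)) mean(genome$sd_region) else design$marker_locus
  if (!is.null(design$marker_locus) &&
      !pos_in_interval(design$marker_locus, genome$sd_region[1], genome$sd_region[2]))
    stop("marker_locus must lie inside the SD region")
  marker_idx <- sd_idx[which.min(abs(truth$pos[sd_idx] - target))]

  trans <- design$translocation
  if (!is.null(trans)) {
    if (is.null(trans$src)) trans$src <- genome$sd_region
    mpos0 <- truth$pos[marker_idx] - 1
    if (design$selection && !(mpos0 >= trans$src[1] && mpos0 < trans$src[2]))
      stop("translocation source must contain the selected marker locus")
  }

  ## chromosome lengths keyed by name; widen destination LG if needed
  lens <- genome$chrom_lengths
  names(lens) <- genome$chrom_names

  suppress_for <- function(g) {
    if (is.null(trans) || !trans$suppressed || g < trans$generation) return(list())
    out <- list()
    out[[genome$chrom_names[trans$dest_chrom]]] <-
      c(trans$dest_start, trans$dest_start + (trans$src[2] - trans$src[1]))
    out
  }

  record <- list()   # per recorded group: dosage matrix + labels
  bp_all <- list()
  mother <- rep(1L, S)   # F1 maternal-origin haplotype: all maternal

  record_quota <- function(g) {
    if (design$generations == 0) return(NULL)
    if (g == 1 && design$n_bc1 > 0) {
      list(prefix = if (design$generations == 1) "BC1" else "BC1", n = design$n_bc1,
           labels = c("BC1_pigm", "BC1_wt"))
    } else if (g == design$generations && g > 1 && design$n_bc100 > 0) {
      list(prefix = "BC100", n = design$n_bc100, labels = c("BC100_pigm", "BC100_wt"))
    } else NULL
  }

  for (g in seq_len(design$generations)) {
    map <- linkage_map(truth, genome, trans, g)
    sup <- suppress_for(g)
    quota <- record_quota(g)
    need_car <- if (is.null(quota)) 0L else ceiling(quota$n / 2)
    need_non <- if (is.null(quota)) 0L else quota$n - need_car
    keep_car <- NULL; keep_non <- NULL
    mother_next <- NULL
    for (try in seq_len(design$retries)) {
      rem <- (need_car - if (is.null(keep_car)) 0L else ncol(keep_car)) +
             (need_non - if (is.null(keep_non)) 0L else ncol(keep_non))
      n_draw <- max(design$brood_size, min(4096L, 2L * max(rem, 0L)))
      mm <- meiosis_gametes(mother, map, lens, n_draw, design$n_crossovers, sup)
      mm$breakpoints$generation <- g
      bp_all[[length(bp_all) + 1L]] <- mm$breakpoints
      carrier <- mm$gam[marker_idx, ] == 1L
      if (!is.null(quota)) {
        if (is.null(keep_car)) keep_car <- mm$gam[, carrier, drop = FALSE][, 0]
        if (is.null(keep_non)) keep_non <- keep_car
        keep_car <- cbind(keep_car, mm$gam[, carrier, drop = FALSE])
        keep_non <- cbind(keep_non, mm$gam[, !carrier, drop = FALSE])
      }
      if (g < design$generations && is.null(mother_next)) {
        ## next line mother: a carrier female (selection requires the marker;
        ## female development requires the SD allele, the same block here)
        cand <- which(carrier)
        if (length(cand)) mother_next <- mm$gam[, sample(cand, 1)]
        else warning("no carrier in brood at generation ", g, "; resampling")
      }
      done_rec <- is.null(quota) ||
        (ncol(keep_car) >= need_car && ncol(keep_non) >= need_non)
      done_mom <- g == design$generations || !is.null(mother_next)
      if (done_rec && done_mom) break
      if (try == design$retries)
        stop("failed to obtain required carriers after ", design$retries,
             " broods at generation ", g)
    }
    if (!is.null(quota)) {
      record[[quota$labels[1]]] <- keep_car[, seq_len(need_car), drop = FALSE]
      record[[quota$labels[2]]] <- keep_non[, seq_len(need_non), drop = FALSE]
    }
    if (g < design$generations) mother <- mother_next
  }

  ## assemble dosage matrix: parents, F1, recorded broods
  n_par <- ncol(parents$geno$gt)
  par_dose <- cbind(matrix(2L, S, sum(parents$geno$samples$group == "parentM")),
                    matrix(0L, S, sum(parents$geno$samples$group == "parentP")))
  f1_dose <- matrix(1L, S, design$n_f1)
  dose <- cbind(par_dose, f1_dose)
  samples <- rbind(parents$geno$samples,
                   data.frame(sample = paste0("f1_", seq_len(design$n_f1)),
                              sex = "F", group = "F1", stringsAsFactors = FALSE))
  for (grp in names(record)) {
    m <- record[[grp]]
    if (!ncol(m)) next
    is_pigm <- grepl("_pigm$", grp)
    sex <- rep(if (is_pigm) "F" else "M", ncol(m))
    if (design$misassignment_rate > 0) {
      flip <- runif(ncol(m)) < design$misassignment_rate
      sex[flip] <- ifelse(sex[flip] == "F", "M", "F")
    }
    samples <- rbind(samples,
                     data.frame(sample = paste0(tolower(grp), "_", seq_len(ncol(m))),
                                sex = sex, group = grp, stringsAsFactors = FALSE))
    dose <- cbind(dose, m)
  }
  colnames(dose) <- samples$sample

  ## maternal dosage -> ALT dosage
  gt <- ifelse(matrix(truth$maternal_is_alt, S, ncol(dose)), dose, 2L - dose)
  if (design$missing_rate > 0) {
    gt[matrix(runif(length(gt)) < design$missing_rate, nrow(gt))] <- NA_integer_
  }
  geno <- geno_set(gt, parents$geno$sites, samples)

  truth$is_marker <- seq_len(S) == marker_idx
  if (!is.null(trans)) {
    moved <- truth$chrom == sexc & pos_in_interval(truth$pos, trans$src[1], trans$src[2])
    truth$translocated <- moved
  }
  bp <- if (length(bp_all)) do.call(rbind, bp_all) else
    data.frame(chrom = character(), pos = numeric(), meiosis = integer(),
               generation = integer())
  list(geno = geno, truth = list(sites = truth, dosage = dose),
       breakpoints = bp, design = design, genome = genome,
       translocation = trans)
}

#' Simulate a single-species ZW population sample
#'
#' Generates the genotype panel used by the sex-association scan: females
#' are heterozygous (W/Z) at every SNP inside the SD region while males are
#' homozygous, and all other SNPs segregate at Hardy-Weinberg frequencies
#' independent of sex.
#'
#' @param genome a [genome_model()].
#' @param n_f,n_m numbers of females and males (defaults 30/30).
#' @param snp_density polymorphic sites per Mb (default 2).
#' @param freq_range range of the ALT allele frequency at unlinked sites.
#' @param seed RNG seed.
#' @return list with `geno` (a [geno_set()], groups all `pop`) and `truth`
#'   (site map with `sex_linkage` in {A, SD}).
#' @export
simulate_zw_population <- function(genome, n_f = 30, n_m = 30,
                                   snp_density = 2, freq_range = c(0.1, 0.9),
                                   seed = 1) {
  stopifnot(n_f >= 1, n_m >= 1)
  set.seed(seed)
  sp <- draw_site_positions(genome, snp_density)
  n <- nrow(sp)
  lab <- site_linkage_label(genome, sp$chrom, sp$pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gt <- matrix(NA_integer_, n, n_f + n_m)
  auto <- lab == "A"
  p_alt <- runif(sum(auto), freq_range[1], freq_range[2])
  gt[auto, ] <- rbinom(sum(auto) * (n_f + n_m), 2, rep(p_alt, n_f + n_m))
  ## SD region: ALT plays the W allele, carried by every female, no male
  gt[!auto, seq_len(n_f)] <- 1L
  gt[!auto, n_f + seq_len(n_m)] <- 0L
  samples <- data.frame(sample = c(paste0("popF", seq_len(n_f)),
                                   paste0("popM", seq_len(n_m))),
                        sex = rep(c("F", "M"), c(n_f, n_m)),
                        group = "pop", stringsAsFactors = FALSE)
  sites <- data.frame(id = paste0("s", seq_len(n)), chrom = sp$chrom,
                      pos = sp$pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  truth <- cbind(sites, sex_linkage = lab, stringsAsFactors = FALSE)
  list(geno = geno_set(gt, sites, samples), truth = truth)
}

#' RAD-locus catalogue with sex-linkage labels
#'
#' Draws a catalogue of RAD loci across the genome for the coverage
#' simulator. Loci on the sex chromosome are labelled W-linked (placed in
#' the SD region, present only on the W) with probability `w_fraction`,
#' Z-linked with probability `z_fraction`, and autosomal-like otherwise;
#' loci elsewhere are autosomal.
#'
#' @param genome a [genome_model()].
#' @param n_loci catalogue size (default 3000).
#' @param w_fraction,z_fraction fractions of sex-chromosome loci that are
#'   W-linked / Z-linked (defaults 0.05 / 0.15, the order of magnitude seen
#'   in RAD catalogues of ZW species: W-specific loci are rare and Z
#'   dosage-candidates a modest multiple of them).
#' @param seed RNG seed.
#' @return data.frame with columns `locus`, `chrom`, `pos`, `sex_linkage`
#'   (one of "A", "W", "Z").
#' @export
sample_rad_loci <- function(genome, n_loci = 3000, w_fraction = 0.05,
                            z_fraction = 0.15, seed = 1) {
  stopifnot(w_fraction >= 0, z_fraction >= 0, w_fraction + z_fraction <= 1)
  set.seed(seed)
  probs <- genome$chrom_lengths / sum(genome$chrom_lengths)
  ci <- sample.int(genome$n_chromosomes, n_loci, replace = TRUE, prob = probs)
  pos <- floor(runif(n_loci, 1, genome$chrom_lengths[ci]))
  lab <- rep("A", n_loci)
  on_sex <- ci == genome$sex_chrom
  u <- runif(n_loci)
  lab[on_sex & u < w_fraction] <- "W"
  lab[on_sex & u >= w_fraction & u < w_fraction + z_fraction] <- "Z"
  ## W loci live on the W haplotype of the SD region
  wsel <- lab == "W"
  pos[wsel] <- floor(runif(sum(wsel), genome$sd_region[1] + 1, genome$sd_region[2]))
  data.frame(locus = paste0("L", seq_len(n_loci)),
             chrom = genome$chrom_names[ci], pos = as.integer(pos),
             sex_linkage = lab, stringsAsFactors = FALSE)
}

#' Coverage noise model
#'
#' Read counts per locus and sample are negative-binomial with mean
#' `dosage * mean_depth / 2` (dosage 2 at autosomal loci in both sexes; 1 in
#' females and 0 in males at W-linked loci; 1 in females and 2 in males at
#' Z-linked loci) and the given overdispersion (`dispersion` is the NB size
#' parameter; Poisson in the limit `dispersion -> Inf`). A small mismapping
#' rate gives W-linked loci a residual male mean of
#' `error_rate * mean_depth`.
#'
#' @param mean_depth expected reads per autosomal locus per sample
#'   (default 20).
#' @param dispersion negative-binomial size (default 5).
#' @param error_rate W-linked male mismapping rate (default 0.01).
#' @return an object of class `coverage_model`.
#' @export
coverage_model <- function(mean_depth = 20, dispersion = 5, error_rate = 0.01) {
  stopifnot(mean_depth > 0, dispersion > 0, error_rate >= 0)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 error_rate = error_rate), class = "coverage_model")
}

#' Simulate a RAD coverage matrix from sex-linkage labels
#'
#' @param labels character vector of per-locus labels in {A, W, Z} (for
#'   example the `sex_linkage` column of [sample_rad_loci()]).
#' @param n_f,n_m numbers of females and males.
#' @param model a [coverage_model()].
#' @param seed RNG seed.
#' @param locus_ids optional locus names (defaults to L1..Ln).
#' @return list with `counts` (integer locus x sample matrix) and `samples`
#'   (sheet with sex labels, group `pop`).
#' @export
simulate_coverage <- function(labels, n_f, n_m, model = coverage_model(),
                              seed = 1, locus_ids = NULL) {
  stopifnot(n_f >= 1, n_m >= 1, all(labels %in% c("A", "W", "Z")))
  set.seed(seed)
  n <- length(labels)
  dose_f <- c(A = 2, W = 1, Z = 1)[labels]
  dose_m <- c(A = 2, W = 0, Z = 2)[labels]
  mu_f <- dose_f * model$mean_depth / 2
  mu_m <- dose_m * model$mean_depth / 2
  mu_m[labels == "W"] <- model$error_rate * model$mean_depth
  mu <- cbind(matrix(mu_f, n, n_f), matrix(mu_m, n, n_m))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = model$dispersion),
                   n, n_f + n_m)
  storage.mode(counts) <- "integer"
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(n))
  dimnames(counts) <- list(locus_ids,
                           c(paste0("covF", seq_len(n_f)), paste0("covM", seq_len(n_m))))
  samples <- data.frame(sample = colnames(counts),
                        sex = rep(c("F", "M"), c(n_f, n_m)),
                        group = "pop", stringsAsFactors = FALSE)
  list(counts = counts, samples = samples)
}
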