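---
title: "Methods: sex-linkage detection and backcross ancestry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linkage detection and backcross ancestry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`hybridsex` implements the computational chain of a classic experimental
design in fish genetics: two species with different sex-chromosome systems
are hybridised, the hybrid line is backcrossed to one parental species for
many generations under artificial selection on a marker linked to the
donor's sex-determining (SD) region, and genomic data are used to ask

1. which linkage group carries the ZW pair in the recurrent (paternal)
   species, and where its non-recombining region ends;
2. which alleles are diagnostic of each parental species, and how they
   segregate through the pedigree;
3. where maternal (donor) ancestry is retained in late-generation
   backcrosses — in particular whether a translocated SD block has created
   a new sex chromosome on a former autosome; and
4. whether the amount of retained maternal ancestry exceeds what neutral
   drift in a small backcross line can explain.

Every stage runs on synthetic data with known ground truth, so the package
is self-contained and each method can be validated against the generator's
truth labels.

# Genotype-based sex-linkage scan (`sex_scan`, `wc_fst`)

Each biallelic SNP is tested for allelic association with sex using the
2×2 table of allele copies × sex and a two-sided Fisher exact test — the
allelic encoding used by standard GWAS tools in exact mode. Two-sided
p-values sum hypergeometric probabilities not exceeding the observed
table's probability, with the customary `1e-7` relative tie tolerance;
tables with a zero margin are uninformative and return p = 1 by
convention.

Multiplicity is handled with a Bonferroni family-wise threshold computed
at run time as `alpha / m` (default `alpha = 0.05`, `m` = number of sites
scanned), plus a configurable suggestive threshold (default `1e-4`). A
site is reported as a genome-wide hit only when it also shows excess
female heterozygosity (`het_F > het_M`), the ZW signature: under female
heterogamety, W/Z females are heterozygous at fully sex-linked sites while
ZZ males are homozygous.

Differentiation between the sexes is quantified with the Weir–Cockerham
variance-components estimator of F_ST, treating females and males as the
two populations. Per site we report the three components `a` (among
groups), `b` (among individuals within groups), `c` (within individuals)
and `theta = a/(a+b+c)`; monomorphic sites (zero total variance) are
flagged unusable. Windowed summaries use non-overlapping tiling windows
(1, 10 and 100 kb by default) with the ratio-of-sums (weighted) estimator
`sum(a)/sum(a+b+c)`; the mean of per-site `theta` is reported alongside
for transparency but thresholds use the weighted value, which is the less
noisy of the two. The outlier threshold is the upper 1% of per-window
values under the nearest-rank convention (the `ceiling(0.99 n)`-th order
statistic); windows without usable sites are excluded from the percentile.

The estimator is implemented from the variance-components algebra directly
because no installed package provides it; the test suite checks it against
an independent nested-ANOVA computation on raw allele copies and against
closed-form cases (fixed difference gives `theta = 1`).

# Coverage-based W/Z classification (`covsex_analysis`)

Read-depth dosage offers an orthogonal signal: a W-linked locus exists
only on the W haplotype and so is sequenced only in females, while a
Z-linked locus has two copies in ZZ males and one in ZW females, giving an
expected male/female depth ratio of 2.

Raw locus × sample counts are normalized by median-ratio size factors:
the per-locus reference is the geometric mean across samples over loci
with no zero count, and each sample's factor is the median of its
count/reference ratios. This is the estimator popularized by differential
expression analysis; the tests cross-check it against
`DESeq2::estimateSizeFactorsForMatrix` (which takes the median in log
space — identical up to how an even number of reference loci averages its
two middle ratios). A locus mean-coverage filter then retains loci with
overall normalized mean in `[3, 400]`; the bounds are kept (only strictly
below/above is removed) since the quoted rules are strict inequalities.

Classification applies, in order:

* **W-linked**: female mean > 7 *and* male mean < 2 (normalized counts);
* **Z-linked**: not W, female mean > 0, and male/female ratio > 1.9.

W and Z are therefore mutually exclusive with W priority. All thresholds
are configurable; they are depth-dependent by nature (7 and 2 are absolute
read counts), so the defaults assume depths of the order of 20× and the
ratio rule — which is scale-free — carries more weight at other depths.
A `use_raw` flag classifies on raw counts instead, since the original
rule text does not say which scale it used; normalized is the default
because normalization immediately precedes classification in the
workflow.

Candidate lists are tested for per-chromosome over-representation with a
two-sided Fisher exact test on the (called vs not) × (on chromosome vs
elsewhere) table against the mapped background catalogue, Bonferroni
corrected across chromosomes.

One practical caveat the package's own simulations exposed: if sex-linked
loci are more than a few percent of the catalogue, the dosage difference
itself biases the size factors (male factors inflate, pushing normalized
M/F ratios below 2). In real RAD catalogues the sex-linked fraction is
well under 1%, and the synthetic catalogue defaults (`w_fraction = 0.05`,
`z_fraction = 0.15` *of sex-chromosome loci*, i.e. ~0.8% of the catalogue)
mirror that. With the default coverage model the Z ratio rule at 1.9
recovers roughly 60–65% of true Z loci — the threshold sits deliberately
close to the expected ratio of 2, trading recall for precision.

# Sorting of parental alleles (`select_diagnostic_sites` and friends)

Diagnostic sites are selected by three criteria applied jointly:

1. all non-missing genotypes are homozygous within each parental strain
   and the strains carry different alleles;
2. every non-missing F1 genotype is heterozygous;
3. every non-missing backcross individual (over all BC groups present)
   carries at least one paternal allele.

Missing genotypes never veto a site (the denominators shrink), but a
configurable per-site completeness filter (default 80% non-missing) is
applied first. Criterion 3 is evaluated per individual over all backcross
samples jointly.

Per-group tallies count maternal-allele copies over all diagnostic sites;
proportions are printed to three decimals (half-even rounding). Expected
counts under Mendelian backcross segregation use the maternal proportion
`0.5^(g+1)` at backcross generation `g` (g = 0 is the F1), applied to the
observed allele total and truncated toward zero — truncation, rather than
rounding, is what reproduces published segregation tables in which a
`.5` expectation is printed as its integer part.

Maternal-ancestry profiles give the per-site frequency of maternal alleles
in a group and per-chromosome counts of sites carrying at least one
maternal allele. Retained blocks are maximal runs of sites at frequency
`>= min_freq` (default 0.5 — in a selected line every carrier is
heterozygous across the protected block, so the block frequency is 0.5),
bridging at most `max_gap_sites` (default 2) consecutive below-threshold
sites, and requiring `min_block_sites` (default 10) above-threshold sites.
These block parameters are operational choices: with the default
diagnostic density (5 sites/Mb) they make a 10 Mb protected block one
detected block while leaving isolated retained sites unclustered. Regions
can be masked (BED convention, 0-based half-open) before profiling, which
is how the translocated block is excluded when counting residual retained
ancestry.

# Neutral backcross-drift null (`simulate_drift`, `excess_test`)

The null model for retained ancestry is a binomial drift recursion: with
`N` diploid hybrids per generation, the maternal ancestry frequency
follows

    y_t ~ Binomial(2N, p_{t-1} * 0.5),    p_t = y_t / 2N,

starting from `p_0 = 0.5` (an F1 line). The halving reflects backcrossing
to the recurrent species each generation; zero is absorbing. Defaults are
`N = 10` (with 15 as the common alternative), 100 generations and 10,000
replicates. With these settings every replicate loses all maternal
ancestry well before generation 100 (over 99% are absorbed by generation
20), so the neutral expectation for retained ancestry is nil.

The excess test maps each replicate's terminal frequency to a
retained-locus count proportionally
(`round(terminal_p * sites_per_genome)`) — the recursion itself is
locus-free, so some mapping is required, and the proportional one is
stated in the output — and reports the add-one empirical p-value
`(#{null >= observed} + 1)/(reps + 1)`, which is never exactly zero. All
replicates are advanced with one seeded vectorized RNG stream; given R's
generator this is exactly reproducible for a fixed (seed, N, generations,
reps) without per-replicate sub-streams.

# The synthetic-data generator

The generator emulates the *statistical* structure of the study design,
not its molecular detail:

* **Parents.** Two strains fixed for alternative alleles at diagnostic
  sites placed uniformly at `diagnostic_density` per Mb (default 5) over a
  24-LG genome (25 Mb per LG; the ZW pair on LG21 with a non-recombining
  SD region at 13–23 Mb and the remainder pseudoautosomal). Whether the
  maternal allele is REF or ALT is randomized per site and recorded.
* **Meiosis.** One crossover per chromosome per meiosis (configurable),
  uniformly placed; no interference, no Morgan-scale map. Backcross
  offspring receive one recombined maternal gamete and one all-paternal
  gamete, so they are never homozygous for a maternal allele —
  criterion 3 holds by construction.
* **Sex and selection.** Offspring are female iff they carry the maternal
  SD/marker allele (the observed rule in such crosses is ~99.7%
  concordant; a misassignment rate is available, default 0). The line
  mother each generation is a carrier female; the recorded broods are
  split into carrier (`*_pigm`) and non-carrier (`*_wt`) groups. Default
  recorded sizes (4 F1, 16 BC1, 18 BC100) match a small pedigree
  sequencing panel.
* **Translocation.** Optionally, the maternal copy of the SD interval
  moves to an autosome (default LG2 at 8 Mb) with recombination suppressed
  across the destination interval. The default timing is the *first*
  backcross meiosis: the paper-scale observation of a dense ~10 Mb
  maternal block around the relocated SD region requires the donor
  haplotype to be intact when suppression begins, which is only guaranteed
  early in the line's establishment; later timings are configurable but
  leave a sparser block. After the event, sites in the source interval
  segregate with the destination chromosome while keeping their original
  (reference-alignment) coordinates in all outputs — exactly how such a
  block appears when hybrid reads are mapped to the donor reference.
* **ZW population panel.** For the single-species scan, females are
  heterozygous at every SD-region SNP and males homozygous; all other SNPs
  are Hardy–Weinberg with frequency drawn uniformly (0.1–0.9),
  independent of sex.
* **Coverage.** Negative-binomial counts with mean `dosage x mean_depth/2`
  (dosage 2/2, 1/0 and 1/2 for A, W and Z loci in F/M) and NB size
  `dispersion` (default 5, i.e. a per-locus CV of ~0.55 at 20× — typical
  RAD-scale overdispersion; Poisson in the limit). W-linked loci get a
  residual male mean of `0.01 x mean_depth` to model mismapping.

What the generator does **not** model: read-level artefacts (FASTQ,
alignment, PCR duplicates), genotype-calling error beyond a flat
missingness rate, linkage disequilibrium within the population panel,
multi-allelic sites, and recombination-map heterogeneity. Passing tests
therefore demonstrate correctness of the statistical chain under clean
Mendelian and dosage structure, not robustness to upstream calling
artefacts — those are deliberately upstream of this package's scope.

# Numerical conventions and degenerate inputs

* Coordinates: 1-based positions in VCF and site tables; 0-based
  half-open intervals for masks and internal interval logic (BED
  convention on disk). The converters are involutive and property-tested.
* Fisher ties: probabilities within a `1e-7` relative factor of the
  observed table's count as "as extreme".
* Zero-margin tables: p = 1. Sites with a sex entirely missing are
  skipped and logged.
* Percentiles: nearest rank, `sort(x)[ceiling(q n)]`.
* Expected segregation counts: truncated toward zero.
* Proportions: three decimals, half-even.
* Empirical p-values: add-one estimator, never zero.
* Monomorphic sites: p = 1 in the scan; undefined `theta`, excluded from
  windowed F_ST and its percentile.
* Coverage: samples with all-zero counts, or matrices with no all-nonzero
  locus, are hard errors (the latter suggesting a pseudo-reference
  fallback) rather than silent degradation.

# Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
genomes of 3–24 chromosomes at 5 diagnostic sites/Mb (up to ~3,000 sites),
population panels of 30 females and 30 males, coverage catalogues up to
30,000 loci, backcross simulations up to 100 generations with recorded
broods of ~20 (4,000 for the Mendelian-proportion checks), and 10,000
drift replicates. These sizes keep every stochastic check within tight
Monte-Carlo error while the full suite runs in well under a minute of CPU.

# Known limitations

* The drift null is locus-free; linked-site drift (a chromosome-structured
  null) is out of scope, so the excess test treats retained loci as
  exchangeable.
* Absolute W thresholds (7/2 reads) assume ~20× depth; at other depths
  they must be rescaled by the user (the ratio rule needs no rescaling).
* The block detector is a run-length heuristic, not an HMM; it is tuned
  for dense protected blocks against a near-zero background, the regime
  late-generation selected backcrosses produce.
* `select_diagnostic_sites` requires all three pedigree tiers; with very
  small parental panels (2–4 individuals) criterion 1 cannot distinguish
  fixation from sampling, which matches the design it emulates.
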