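---
title: "Methods: classifying and comparing gonadal small RNAomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and comparing gonadal small RNAomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the models, conventions and design choices behind the
package, in the spirit of a methods supplement. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The biological setting

*C. elegans* gonads contain the germline proper surrounded by the somatic
gonad, and both tissues are sexually dimorphic. Small RNA sequencing of
dissected gonads captures several RNA classes at once, distinguishable by
template, length and 5' nucleotide: miRNAs processed from hairpins, piRNAs
(21 nt, 5' U, germline-specific, quantified as sense reads over their
annotated loci), primary Dicer-made 26G siRNAs and secondary RdRP-made 22G
siRNAs, which lie antisense to the coding exons of their target mRNAs.
Because sequencers report DNA space, a 5' U appears throughout this package
as a 5' T.

Three genotypes anchor the tissue logic. Hermaphrodite gonads are female in
both tissues; control male gonads are male in both; *fog-3* mutant males
carry a *female* germline inside a *male* somatic gonad. A difference
between control and *fog-3* males can only come from the germline (the
somas are identical), and a difference between hermaphrodites and *fog-3*
males can only come from the soma (the germlines are both female). This is
the truth table `attribute_tissue()` implements; when a feature qualifies
for both the germline and the somatic pattern the germline interpretation
takes precedence, since the mutant-vs-control male comparison is the
cleaner contrast. piRNAs are attributed from the sex comparison alone
(`germline_only = TRUE`) because they do not exist outside the germline.

## The alignment cascade

Reads are trimmed (3' adapter at its leftmost occurrence; the adapter or
its read-terminal prefix must match with an error rate of at most 0.1 and
at least 3 bases of overlap) and length-filtered to 21–34 nt. Retained
reads then pass through six reference compartments in a fixed order —
contaminant (k = 2 mismatches), structural tRNA/rRNA (k = 2), GFP sensor
(k = 0), recoded trigger (k = 0), miRNA hairpins (k = 0), genome (k = 0) —
and the first stage with a qualifying hit claims the read. The aligner
itself is an exact scan over every offset of both strands: a contract that
a desk-scale reference set permits and that an FM-index engine would only
approximate with flag-dependent behavior. Ties break deterministically:
fewest mismatches, then reference declaration order, then smallest offset,
then sense before antisense. A read base of `N` mismatches everything.
Multimapping reads therefore count once, at their best deterministic
position; the alternative (counting multimappers fractionally or multiply)
is not implemented.

Two consequences of the stage order are asserted as behavior rather than
corrected, because they are properties of the published assay design:

* a trigger-derived read spanning a SNP can never be claimed by the sensor
  stage at k = 0 (it mismatches the sensor at exactly that base), and
* a 21 nt trigger read that happens to sit between SNPs is
  indistinguishable from a sensor read and is claimed by the earlier sensor
  stage. With SNPs at every 21st position starting at 21, every window of
  length ≥ 21 spans a SNP, so this window only exists when the SNP phase is
  shifted; the simulator exposes `ambiguous_primary` plus a configurable
  phase to generate exactly these reads. For reads of ≥ 22 nt the sensor
  and recoded stages are provably order-independent, which the acceptance
  suite checks by swapping them.

## The synthetic data

The generator is the package's study population, not a tuning knob. The
reference bundle holds a two-chromosome 30 kb toy genome with
non-overlapping annotated features (40 coding exons, 30 piRNA loci — each
21 nt with its sense strand patched to start with T — 8 pseudogenes, 8
transposons), a 2 kb contaminant fragment, two structural pools, 40
hairpins of 90 nt, and a 720 nt sensor whose recoded counterpart is derived
with the fixed transversion map A→C, C→A, G→T, T→G at every 21st position.
The true recoded sequence used in the original assay was synthesized
commercially and never printed, so the substitution map and the placement
phase are explicit parameters rather than guesses; the default phase 0
places SNPs at exact multiples of the spacing.

The default read mixture mirrors the composition of gonadal libraries: 27%
22G siRNAs (the published libraries report 27.4%/27.9%), 15% miRNAs, 15%
sense degradation fragments, 13% other antisense siRNAs, 5% each of piRNAs
(the 5'-phosphate-independent cloning chemistry recovers piRNAs
inefficiently) and 26G siRNAs, 5% contaminant, 10% structural carry-over,
and a small GFP component in which secondary reads dominate primary ones.
Class counts are multinomial; each read is drawn from its compartment with
the class-defining constraints (22 nt/5' G antisense for 22G, 26 nt/5' G for
26G, 21 nt/5' T sense for piRNA, SNP-spanning for primary trigger reads)
and rejection-sampled so that it cannot match any earlier cascade stage
within that stage's mismatch allowance and maps uniquely in the genome.
Ground truth is therefore well defined, and the round-trip tests demand
100% recovery rather than "high" recovery.

What the simulator does **not** model: sequencing error and quality scores,
ligation bias, 5'-phosphorylation chemistry, multimapping read families,
overlapping gene models, and expression-level heterogeneity between genes
within a class. Passing round-trip tests consequently show correctness of
the pipeline's logic, not robustness to every artifact of real libraries.

## Normalization and sex-bias calling

Size factors use the median-of-ratios estimator: factor_j = median over
features (with a positive geometric mean across libraries) of
count_ij / geometric-mean_i. Sense and antisense matrices are normalized
independently, because sense reads are dominated by mRNA degradation while
antisense reads reflect siRNA production. Features enter testing when their
mean normalized count reaches 5 in at least one group; the threshold is
interpreted on normalized counts (the alternative — raw counts — would make
the filter depend on library depth).

A feature is called sex-biased when it passes **both** a four-fold change
(on group means with a pseudocount of 0.5, so features detected exclusively
in one sex remain callable) and an adjusted p below 0.01. Two test routes
exist:

* `method = "wilcoxon"`: per-feature two-sided Wilcoxon rank-sum (exact for
  small tie-free samples, otherwise the continuity-corrected normal
  approximation) with Benjamini–Hochberg adjustment. This is the test the
  published figure legends describe.
* `method = "deseq2"`: the negative-binomial Wald test of DESeq2 on raw
  counts, as the published methods section describes.

The two routes are not interchangeable at small replication, and this is a
mathematical fact rather than an implementation choice: with three
replicates per group the most extreme exact two-sided rank-sum p is
2/C(6,3) = 0.1, and adjusted p can only be larger, so the rank route can
never reach a 1% FDR — with any data. Genome-wide calling at the study's
replication (2, 3 and 6 replicates) is therefore only possible through the
NB route, which is what the planted-effect recovery checks exercise; the
rank route remains the default for the descriptive per-feature statistics
and is verified against an exhaustive enumeration oracle. A unit test
documents the granularity bound explicitly.

The planted-effect study conditions are fixed: 2000 features, 50 with a
ten-fold effect (half up in each sex), negative-binomial counts with
dispersion 0.1 around log-normal baselines centred near 200 reads (typical
per-gene gonadal siRNA depth), 3 vs 3 replicates, 20 simulation seeds.

## The SNP sensor assay

Primary siRNAs are processed from the fed trigger and carry its recoded
bases; secondary siRNAs are RdRP products templated on the sensor mRNA and
match the sensor exactly. The cascade realizes the quantification directly:
secondary count = sensor compartment, primary count = recoded compartment.
Rates are per million reads retained after trimming and length filtering
(the published normalization says only "total reads"; the retained-read
denominator is the configurable choice here). Group ratios average
per-library secondary/primary ratios rather than taking the ratio of mean
rates — the published group ratios (9 and 56) are inconsistent with
ratio-of-means arithmetic on the published rates, implying per-replicate
computation. A library with no primary reads has an undefined ratio and is
excluded from the group mean.

Phenotype scoring is binomial: percent silenced with SEM
100·sqrt(p(1−p)/n), group differences by Yates-corrected chi-square
(correction adopted as the conservative convention; the original analysis
does not state it), and intensity comparisons by two-sided Welch t-tests
(the original does not state Student vs Welch or sidedness; Welch two-sided
is the robust default). Note one arithmetic subtlety: pooled scoring counts
of 305/307 give 99.3% at one decimal, while the published figure reports
99.4% — a mean over experimental replicates whose per-replicate breakdown
is not printed. The package reports the pooled computation.

## The binned 22G/mRNA association

Genes with at least 10 reads of each RNA type define the targeted fraction;
genes are then ranked by 22G level and split into 20 equal-count bins (ties
broken by stable input order; sizes differ by at most one). Within each bin
an OLS of log10(mRNA + 1) on log10(22G + 1) tests whether mRNA still rises
with 22G inside that expression stratum — the log10(x+1) scale is the
package's choice, as the original "linear model" scale is unstated. Bins
with fewer than 3 genes or a constant predictor are `na`; a constant
response yields slope 0 and p 1 by convention, and a numerically perfect
fit reports p ≈ 0 rather than noise-driven t statistics.

Within-bin Argonaute-target comparisons use two-sided Wilcoxon tests with
Bonferroni correction whose denominator counts only eligible bins, matching
the published legends' exclusion of single-category bins (`na`). Target
flags derived from hermaphrodite data are applied unchanged to the male
table ("interpolated"). The synthetic association population fixes the
study conditions: 2000 genes, log10 22G uniform on [0, 4], baseline slope 1
with Gaussian noise (sd 0.2), the top 5% of 22G carrying a silencing slope
of −6 (which averages to the ~four-fold mRNA suppression over the top bin),
30% WAGO-like targets at 0.25× mRNA and 20% CSR-1-like targets at 4× mRNA,
planted disjointly.

The matched-abundance comparison pools both sexes' genes, bins on mRNA so
genes of similar expression are compared, and tests 22G levels between the
sexes per bin. The feedback loop between 22G RNAs and their mRNA templates
means none of these associations identify causal direction; the binning
machinery only localizes where in the expression range the association
flips sign.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open internally and converted to 1-based
inclusive at the GFF3 boundary. All generators take explicit integer seeds
and are byte-deterministic. Equal group means with zero variance give
t-test p = 1; an all-tied bin gives Wilcoxon p = 1; chi-square on a table
with a zero marginal is an error rather than a silent NaN. The test and
acceptance workloads use 10,000-read libraries for round-trip checks,
50,000 reads for sensor ratio recovery, 1000 random queries against a 2 kb
reference for aligner validation, and 20 simulation seeds for the
planted-effect operating characteristics — sizes at which every expected
effect is resolvable and the full suite still runs in a few minutes.

## Known limitations

* The cascade is mismatch-only (bowtie `-v`-style); indels are out of scope.
* One best hit per read; no multimapping allocation.
* Real structural-RNA and contaminant references are replaced by synthetic
  stand-ins; compartment *labels*, not compartment *content*, carry the
  meaning.
* The piRNA class is annotation-driven (sense overlap with a piRNA locus),
  with length/first-base as metadata only, matching how piRNAs are counted
  rather than how they are discovered; upstream motif (type I vs type II)
  analysis is out of scope.
* `attribute_tissue` reduces each comparison to a significance bit and a
  direction; borderline features near the fold or FDR cutoffs flip
  categories discontinuously.
* Whether the 20-bin view and the 5%-percentile statistics of the original
  analysis used identical boundary rules is unknown; one equal-count scheme
  with configurable `n_bins` serves both here.
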