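---
title: "Models and methods behind srnapop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnapop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

srnapop analyses population-scale small RNA sequencing: multiplexed
libraries of ~22 nt RNAs (miRNA arms, snoRNA-derived fragments and other
short products) sequenced as 37-base reads, quantified per individual,
and related to genotypes and metabolic phenotypes. This vignette explains
the models and the judgement calls; the README shows the workflow.

## The synthetic cohort and what it does (not) emulate

Every stage is exercised against a generator (`sim_config`,
`make_reference_catalogue`, `simulate_cohort`, `write_fastq`,
`simulate_mrna_matrix`) that reproduces the study design: 12-plex pools
with six-base index tags, an Illumina v1.5-style 3' adaptor, 37-base
reads, miRNA hairpins with mature and star arms placed on a single
synthetic chromosome (clusters within 10 kb blocks), Hardy–Weinberg
genotype dosages with MAF and imputation-info annotations, additive
cis-eQTL effects in log2 units, per-read A-to-I editing rates,
genotype-carried transcript variants, batch and tag effects, and
phenotypes linearly coupled to chosen RNAs.

Choices the data do not dictate, made once:

* **Abundances are log2-normal** (`abundance_meanlog2 = 6`,
  `abundance_sdlog2 = 2`): small RNA libraries are heavy-tailed, with a
  handful of species accounting for most reads; a log-normal reproduces
  that "median ~17 species for 75% of reads" shape.
* **Read depth defaults to 5,000 reads per sample.** Real libraries run
  to millions of reads; depth here is a free scale parameter, and all
  distributional properties under test (tag assignment, trimming,
  mapping ambiguity, fractional mass, allele fractions) are
  depth-invariant. Analyses state their own problem sizes below.
* **Residual expression noise** is Gaussian on the log2 scale
  (`expr_sd = 0.5`), batch effects N(0, 0.5), tag effects N(0, 0.25) —
  mid-sized confounders that the PC screen should flag when planted
  larger than the noise.
* **Qualities are constant high Phred**; the pipeline never reads them.
* **Expression baselines are drawn before genotype streams**, so two
  configurations differing only in planted sites share baselines — used
  by the analysis drivers to plant events on arms known to be abundant.
* Per-tag read-count imbalance is exposed as a parameter
  (`batch_assignments`) rather than matched to any particular run.

The generator does **not** model ligation bias, PCR duplicates or
size-selection physics, and sequencing errors are uniform substitutions.
Passing tests therefore demonstrate correctness of the statistical
machinery and the filtering rules, not robustness to protocol-specific
artefacts in real libraries.

A read is the sample's tag, the product sequence with sample-specific
alleles/edits, then adaptor and linker fill, truncated to 37 nt; an
adaptor-dimer contaminant fraction (default 5%) is mixed in. With 12
tags, one FASTQ per 12-plex pool is written (a single pooled file when
`n_samples <= 12`); a sidecar table records every read's provenance.

## Demultiplexing and trimming

Tag distance is positional over the six prefix bases (match 0, N 0.25,
mismatch 1); Levenshtein alignment is pointless at fixed length six and
would blur the fractional N cost. Reads at distance >= 2.75 to all tags,
or tied between tags, stay unassigned. Adaptor trimming searches the
adaptor's first 12 bases internally (leftmost hit, mismatches <=
floor(0.2 x 12)), then anchors prefixes of length 12 down to 1 at the 3'
end (mismatches <= floor(0.2 x L); `floor` because "up to 20%" states no
rounding rule). The two stages repeat to a fixpoint, making the operation
idempotent — a single pass can leave a 3' end that re-qualifies at a
shorter overlap. Cleanup applies, in order: truncation at the first N of
any five-base window with three Ns; repeated trimming of Ns within two
bases of the 3' end; discard if one base is >= 90% of the remainder (N
counts only as itself); discard below 16 nt. The order matters and is
fixed.

## Ambiguity-aware alignment and counting

References come in five strata: (0) kit contaminants — every adaptor,
linker, adaptor–linker and adaptor–tag combination with all single-base
substitutions, insertions and deletions; (1) mature and star arm
sequences extended up to 3 nt 5' and 5 nt 3' into the hairpin; (2) all
ncRNA plus full hairpins; (3) pseudogenes; (4) the genome. Known variant
positions carry the minimal IUPAC code covering their alleles in every
stratum.

The alignment contract is <= 2 substitutions and <= 1 single-base gap; a
read base matches an IUPAC symbol iff it is in its allele set, and an N
in a read matches nothing. Two matchers implement the contract
independently in C++: an exhaustive scan of every offset with a banded,
early-exit check, and a pigeonhole-seeded matcher (one of four read
chunks must be error-free; candidate offsets from a q-gram hash with
IUPAC windows expanded) with its own verification. A read is kept only if
both agree on all its locations — mirroring a two-aligner consensus
without reproducing any particular aligner's heuristics. Equal-distance
gap placements collapse to one record per (target, offset, strand).

Resolution: any contaminant hit discards the read; otherwise the
highest-priority stratum with hits wins even if a lower stratum matches
more closely, and within it only minimum-edit-distance locations are
kept. A read with k winning locations contributes 1/k to each, so column
sums equal resolved read counts exactly (tested to 1e-9). Unannotated
loci are maximal gap-free runs of pooled coverage; the short subset
(<100 bp, >=1000 reads at full scale) is tested for annotation-track
overlap with an exact binomial tail. Matrix filters (>=1000 total or
>=100 in one sample; >=500,000 mapped reads per sample) take arguments so
scaled-down cohorts can use proportional values.

## Normalisation and the PC screen

Size factors are the median across all-positive genes of the ratio of a
library's count to the gene's geometric mean, rescaled to unit geometric
mean. The rescaling is deliberate: it leaves the two-sample worked
examples unchanged, makes the estimator an exact fixed point on corrected
counts, and keeps only the ratios (which is all normalisation uses)
identified. Zeros are excluded from the median and handled in the log
transform by a 0.5 pseudocount: `log2((n + 0.5)/s)`.

The batch screen correlates sample-space principal components of the
centred log expression (covariance PCA; correlation PCA would upweight
noisy low-expression RNAs) with covariates, using
`t = r sqrt((n-2)/(1-r^2))` on n−2 df, Bonferroni-corrected over one test
per sample. At n = 131 the implied significance boundary is |r| = 0.31.
Categorical covariates enter one-hot with the largest-magnitude level
correlation reported.

## Variant and editing calls

Pileups count alleles per sample at transcript positions from gap-free
alignments. "Observed alleles" is read as read-level depth — a
ten-distinct-allele reading would be meaningless. Sites need information
from >= 20 samples, one sample with >= 10 alleles, and one sample with
>= 20% non-reference reads; calls at the final mature base are flagged as
modified degradation products rather than variants. DNA validation:
>= 5 DNA alternative reads in any sample makes a polymorphism; an A-to-I
edit requires reference A, <= 2 DNA G reads everywhere, and both A and G
in >= 90% of RNA-informative samples (the denominator the text leaves
open; samples with zero coverage cannot count against a site). With no
DNA at all a site stays unresolved — never an edit. The one-off manual
exclusion of a single high-count site in the original analysis is exposed
as an optional outlier filter, not hard-coded. Expected discovery counts
integrate Hardy–Weinberg carrier probabilities against binomial
read-count detection at >= 10 alternative reads.

## Association models

All tests are Gaussian likelihood-ratio tests: nested least-squares fits
with `-2 log LR = n ln(RSS0/RSS1)` on chi-squared(1). The Gaussian choice
follows the linear model on log-normalised counts; the LRT agrees with
the F test to within 10% relative p at n >= 50 (tested). Covariates (age
numeric; batch and tag one-hot) are part of both fits. Cis windows are
100 kb either side of the transcript; SNPs need MAF > 5% and imputation
info > 0.8; q-values pool all cis tests, while phenotype scans control
FDR per trait. Insulin-like assay floors (values under 13 set to 12) are
applied before testing. The lean/obese contrast excludes 25 <= BMI <= 30
and tests the binary label. Arm analysis reports Spearman rho (average
ranks, t approximation) per mature/star pair, flagging |rho| > 0.4, and
scans the (mature − star) log2 difference through the same eQTL
machinery.

q-values are Storey's: pi0 from a df-3 smoothing spline of pi0(lambda)
over lambda in {0.05, ..., 0.95} evaluated at 0.95 (bootstrap variant by
flag), then the step-up minimum of pi0 m p / rank. With pi0 = 1 it
reproduces Benjamini–Hochberg to 1e-10 (tested against `p.adjust`).
Small families (m < 100) fall back to pi0 = 1 — the smoother is not
identified there.

## Seed enrichment

For each miRNA, probes are ranked by Pearson correlation with the miRNA
(most negative first, ties by probe id). For an adenosine-ending 8-mer
and its middle 6-mer and two 7-mers, the occurrence count of each word in
the top-n UTRs (overlapping sliding windows) is tested against the full
set with a one-sided upper hypergeometric tail; the seed score is the
maximum over a 20-point grid of n of the summed −log10 p of the four
words, each capped at 320 to avoid underflow infinities. A third-order
Markov correction (default on for focal scoring, off in the
oracle-tested batch path) rescales each UTR's effective window count by
the ratio of its own Markov word probability to the pooled occurrence
rate, damping composition-driven enrichment.

The null for a focal miRNA is a generalized extreme-value distribution
fitted by maximum likelihood (Nelder–Mead from Gumbel moment starts) to
the scores of all — or a large sample of — A-ending 8-mers on the same
ranking; the focal p is the fitted upper tail, with an empirical-tail
fallback if the fit fails. Parameter recovery is tested on GEV-simulated
samples (shape within 0.1 at n = 4096). Calibration holds when the focal
word is exchangeable with the background: on unplanted UTR panels large
enough that 8-mer counts are non-degenerate (1,200 UTRs of 800 nt in the
tests), focal p-values under random rankings are uniform. Each word is
tested independently even though 6-mer windows overlap 7/8-mer windows —
the combined score is a ranking statistic whose null is estimated
empirically, so the dependence is absorbed by the GEV fit.

## Expression-variation statistics

Cross-tissue specificity uses Welch-style Z scores
`(mu_a − mu_t)/sqrt(var_a/n_a + var_t/n_t)` with two-tailed normal p and
per-tissue q-values; an RNA is tissue-specific when Z > 0 and q < 0.1
against every other tissue (the averaged-q alternative is a flag).
Conservation tests are Pearson chi-squared (1 df, no continuity
correction) on the 2x2 split of high vs not by unconserved vs not, run
for the mean-based and variance-based splits. Cluster co-expression
compares per-cluster median pairwise Pearson correlations (on
covariate-residualised expression) with size-matched random sets via a
two-sided Mann–Whitney U; random draws are seeded and without
replacement. Target summaries report the mean pair correlation, a
one-sample t test against zero, and a Mann–Whitney comparison with random
pairs.

## Problem sizes and degenerate inputs

The test-suite and acceptance-script sizes are the package's own:
matcher equivalence on 10,000 reads against 100 kb (tests) / 4,000 reads
(script); eQTL recovery over 100 / 60 cohorts of n = 100 with beta = 1 at
MAF 0.3; null calibration over ~5,000 pooled tests; variant/edit recovery
over 40 / 30 generator runs at 25 samples; seed calibration over 150 /
100 random rankings. The demo cohort in `analysis/` uses 24 samples at
~4,000 reads each, with the 1000/100/500,000 matrix thresholds scaled by
relative depth, and adjusts linear models for age and batch only — the
12-level tag factor would nearly saturate 24 samples.

Degenerate inputs are errors, not silent results: no all-positive gene
for size factors, empty locus sets, constant traits, rank-deficient
covariate designs, empty BMI groups, alt equal to ref at a variant site,
edit sites on a non-A base. Constant covariates and collinear predictors
are skipped with warnings. Ties are deterministic throughout (stable
probe order, leftmost trim position, one record per alignment location).

## Known limitations

The matchers are exhaustive-by-design for references up to a few hundred
kilobases; they are oracles and reference implementations, not FM-index
replacements for a full human genome. Variant calling has no genotype
likelihood model — it reproduces threshold-based filters. The Markov
correction rescales expected counts rather than re-deriving Sylamer's
internal windowing, whose exact form is tool-internal. Editing calls
require DNA pileups; cohorts without DNA cannot distinguish edits from
polymorphisms by design.
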