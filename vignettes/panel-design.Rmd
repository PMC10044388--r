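---
title: "Designing tiered carrier screening panels from cohort genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tiered carrier screening panels from cohort genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscreen)
```

## The problem

Carrier screening identifies couples at risk of having a child affected by
a severe recessive or X-linked condition. Modern recommendations stratify
screened variants into tiers by carrier frequency: tier 1 is a core gene
list, tier 2 covers carrier frequencies of at least 1/100, tier 3 at least
1/200 plus all X-linked conditions, and tier 4 everything rarer. Pathogenic
*founder* variants — alleles at elevated frequency in a specific ancestry
because of a shared ancestor — are exactly the variants that generic,
pan-population panels miss, and they can only be found by estimating
carrier frequencies *within* ancestry groups of a local cohort.

`founderscreen` implements that workflow end to end: cohort quality
control, ancestry inference, per-ancestry carrier frequency estimation
with a family-structure correction, tier assignment, candidate filtering,
evidence-based curation, and comparison against existing panels. Because
clinical exome cohorts cannot be redistributed, the package also ships a
synthetic cohort generator that reproduces the statistical structure the
pipeline relies on, so every stage is testable against planted ground
truth.

## Relatedness quality control

Clinical cohorts are full of trios and repeat samples; counting both
parents of the same family — or the same person twice — biases carrier
frequencies upward. `kinship_coefficient()` implements the KING-robust
between-family estimator

$$\phi = \frac{N_{het,het} - 2\,N_{opp.hom}}{N_{het,i} + N_{het,j}},$$

chosen because it needs no allele-frequency estimates and stays unbiased
under population structure — essential in a multi-ethnic cohort where any
pooled frequency would be wrong for everyone. Expected values are ~0.5 for
duplicates, ~0.25 for parent–offspring, ~0.125 for second degree.
`prune_cohort()` removes affected probands first (their healthy parents
carry the same transmitted alleles and represent the general population
better), then greedily deletes the highest-degree node of the relatedness
graph until no pair remains at or above the second-degree threshold.
Thresholds default to the standard powers-of-two midpoints 0.354 / 0.177 /
0.0884; ties in the greedy step break lexicographically on sample id so
pruning is deterministic. A pair with no heterozygous site in either
sample has an undefined estimator and is treated as unrelated rather than
silently zero.

## Ancestry inference

Self-reported ethnicity is informative but error-prone, so the pipeline
infers ancestry from the genotypes: PCA on common (default MAF ≥ 0.05,
call rate ≥ 0.95) autosomal variants, followed by a multinomial logistic
classifier on the first ten principal components, trained on the samples
with self-reported labels. Ten components is deliberately more than the
number of well-separated groups typically present; the classifier learns
which directions matter. Predictions below a confidence threshold
(default 0.8) are labelled `unassigned` and excluded from every
per-ancestry denominator — a sample of uncertain ancestry should dilute
no group.

Numerical conventions that make fits reproducible: missing dosages are
mean-imputed per variant (neutral after centering); each loading column's
sign is fixed so its largest-magnitude entry is positive; the classifier
(fitted with `nnet::multinom`, small L2 decay) draws its initial weights
after an internal fixed seed. New samples are always *projected* with the
stored centering/scaling/loadings, never refitted.

### The self-report outlier rule

Before training, samples that do not cluster with their reported label are
removed. The rule is a squared Mahalanobis distance to the reported
label's centroid, cut at the chi-square 99% quantile with 10 degrees of
freedom. Two estimation details matter at realistic training sizes
(a few dozen samples per label):

* **Pooled within-label covariance.** With ~31 samples in 10 dimensions a
  per-label covariance is so noisy that genuine outliers inflate it along
  exactly the directions separating populations, and the hard algebraic
  ceiling on sample Mahalanobis distances ($\approx (n-1)^2/n$) sits just
  above the cutoff — outliers mask themselves. Pooling the within-label
  covariance across labels (each label centered on its own centroid)
  removes both failure modes. The per-label metric remains available via
  `covariance = "label"` for cohorts with large labelled groups.
* **Iterative trimming.** After outliers are dropped, centroids and the
  covariance are re-estimated and all samples re-scored until the inlier
  set is stable. In simulations with 5% planted label errors the iterated
  pooled rule removes essentially all of them while discarding about 1% of
  correctly labelled samples — the calibration the 99% quantile promises.

Labels with fewer than 11 samples pass through unfiltered with a warning:
no meaningful centroid can be estimated, and silently dropping a small
minority group would defeat the point of a pan-ethnic panel.

## Carrier frequencies, the parent correction, and tiers

For each (ancestry, variant) pair, `carrier_frequencies()` counts carriers
(dosage ≥ 1; homozygotes are carriers too), homozygotes, and the group
size as the number of samples of that ancestry with a *non-missing* call
at that site. The frequency is kept as the exact ratio; the familiar
"1/N" rendering uses N = group/carriers rounded half away from zero and is
attached for reporting only. Tier comparisons never touch the rounded
form — comparing `n_carriers * 200 >= group_size` in integers avoids every
floating-point boundary artifact at 1/100 and 1/200.

Ascertainment correction: a cohort recruited through affected children
contains obligate-carrier parents. For each variant,
`remove_homozygous_proband_parents()` removes every parent of a proband
homozygous for it (or compound heterozygous for it with another variant of
the same gene) from that variant's numerator and denominator only. The
adjusted counts are recomputed from scratch on the reduced sample set, so
the operation is exactly a recount, not an increment.

`assign_tier()` applies the tier rules with an inclusive boundary
(frequency exactly 1/200 is tier 3), since the tier definitions are worded
as "≥". One published description of the validation step uses a strict
">" instead; both the tiering and the validation threshold are
independently configurable (`strict_tier3`, `strict`), with strict
comparison the default only in `sensitivity_validation()` where that
convention originated.

## Candidate selection and filtering

`select_reported_plp()` admits a variant if *any* classification source
calls it P or LP — a deliberately sensitive gate; specificity comes later.
`subtract_panel()` removes variants already covered by an existing panel
(exact canonical-key match for variant-based panels, gene symbol for
gene-based ones). `frequency_gate()` keeps variants reaching the minimum
carrier frequency (default 1/200) in at least one target ancestry.
`exclusion_filters()` then drops candidates that are implausible founder
alleles: reference-population allele frequency strictly above 0.5%, three
or more reference homozygotes, or a mild condition. Each exclusion records
all rules it triggered, which is what makes the three rules provably
order-independent. Candidates with missing annotation are retained and
flagged `not_evaluable` — this pipeline's posture is manual-review-forward,
and silent drops are the one failure mode a screening designer cannot
audit.

Variant identity everywhere is the canonical key produced by
`normalize_variant_key()`: uppercase alleles, shared suffix then prefix
trimmed, and indels left-aligned against a reference sequence when one is
provided. Keys are idempotent under renormalization, which the test suite
fuzzes.

## Evidence curation

`curate_variant()` formalizes manual curation as a precedence rule engine
over structured evidence records (community cases with zygosity and
phenotype status, literature reports, archive submissions):

1. a homozygous or compound-heterozygous case in a healthy individual — or
   one with no associated phenotype — excludes the variant;
2. mild conditions are excluded;
3. a biallelic case with a concordant affected phenotype, or a causal
   literature report, confirms the variant;
4. anything else remains uncertain.

Exclusion outranks confirmation, so contradictory evidence resolves
conservatively and is flagged for review. The decision is a pure function
of the evidence multiset — permutation-invariant, which the tests check by
shuffling. Phenotype concordance is an input label, not something the
package computes: reading clinical narratives is out of scope.

## Panel comparison and validation

`compare_to_panels()` reports coverage at both the exact-variant and the
gene level, since an expanded gene-based panel can cover a founder variant
whose precise allele it never lists. `sensitivity_validation()` converts
reference-population allele frequencies to carrier frequencies under
Hardy–Weinberg equilibrium, $CF = 2p(1-p)$ (the linear $2p$ approximation
is available behind a flag; at founder-variant scale they differ by well
under 1%), selects the reference tier-2/3 set, and measures the fraction
the pipeline's candidate set recovered.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. It
emulates the features of a clinical multi-ethnic exome cohort that the
pipeline's statistics depend on:

* **Population structure** under the Balding–Nichols model: per-population
  allele frequencies drawn from Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$ around a
  uniform ancestral frequency, genotypes binomial under Hardy–Weinberg
  within population. The divergence parameter is the Fst, giving direct
  control of how hard the ancestry problem is; Hudson-estimator checks in
  the test suite confirm the realized divergence.
* **Founder variants** planted as heterozygotes in exactly
  `round(cf × N)` samples of the target population and nowhere else.
  Deterministic planting makes frequency-recovery tests exact; a binomial
  mode exists for statistical experiments.
* **Family structure**: trio families whose affected proband is generated
  by Mendelian transmission, plus `plant_affected_family()` to construct
  homozygous or compound-heterozygous affected trios for a chosen variant
  — the exact scenario the parent-removal correction acts on.
* **Data artifacts**: verbatim duplicate samples (copied before
  missingness), self-report label errors at a configured rate, and
  uniform random missingness.

Identical configurations (including the seed) produce bit-identical
cohorts.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: linkage disequilibrium (variants are
independent), sex-aware X hemizygosity (all samples are treated as
diploid, including for "X"-labelled variants), admixed individuals
(each sample has exactly one true population), sequencing artifacts,
batch effects, and non-uniform missingness. The family-size distribution
of real clinical cohorts is also richer than the configurable
trios-plus-singletons structure simulated here.

## Problem sizes and numerical choices

The test suite validates the statistical claims at deliberately desk-sized
configurations chosen to leave the conclusions unambiguous: kinship
calibration on 5,000 sites; ancestry accuracy on 13 populations of 75
samples at Fst 0.05 with 31 training samples per label (mirroring a
567-sample labelled training subset); frequency recovery on two
populations of 1,000; end-to-end runs on two populations of 400. Kinship
needs only a few thousand informative sites for degree-level resolution,
so `prune_cohort()` accepts a site cap (`max_sites`) that subsamples
evenly across the genome on larger cohorts.

Other numerical decisions, collected in one place: ridge regularization of
the outlier-rule covariance is relative (`1e-3` of the mean diagonal);
PCA is variance-scaled, with zero-variance guards; `one_in_n` rounds half
away from zero (so 1011/15 = 67.4 renders "1/67"); greedy pruning breaks
ties toward removing the lexicographically later sample id; all pipeline
randomness flows from the single config seed, and the classifier's
internal initialization seed is fixed, so `run_pipeline()` is
byte-reproducible.

## Known limitations

Tier assignment is only as good as the group sizes: in groups of a few
hundred samples the difference between tier 3 and tier 4 is one or two
carriers, which is why the pipeline reports exact counts alongside every
frequency and why small ancestry groups should be read as candidate
sources, not as frequency estimates. Carrier frequencies from an
affected-family cohort remain somewhat inflated even after the
proband-parent correction (the correction only addresses families
ascertained through the candidate variant itself). Mixed-ancestry samples
are forced into their most probable single group or left unassigned;
both choices perturb group frequencies slightly. And the curation engine
deliberately does not arbitrate between contradictory classification
sources beyond its fixed precedence — it flags the conflict for a human.
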