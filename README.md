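# founderscreen

Data-driven design of pan-ethnic carrier screening panels from cohort
genotypes.

## What problem this solves

Carrier screening panels built from public databases systematically miss
**pathogenic founder variants (PFVs)** — disease alleles at elevated
frequency in a specific ancestry because of a shared ancestor. Finding
them requires estimating carrier frequencies *within* the ancestry groups
of a local clinical cohort, which in turn requires cleaning the cohort of
relatives and duplicates, inferring each sample's ancestry from its
genotypes, and correcting the frequencies for the families the cohort was
ascertained through. `founderscreen` is for statistical geneticists and
clinical-genomics teams who want to run that workflow on a multi-sample
genotype cohort and emerge with a curated, tiered candidate panel.

The pipeline stages, each an exported function group:

1. **QC / relatedness** — pairwise kinship with the KING-robust
   between-family estimator
   φ = (N<sub>het,het</sub> − 2 N<sub>opp.hom</sub>) /
   (N<sub>het,i</sub> + N<sub>het,j</sub>);
   greedy graph pruning removes duplicates (φ ≥ 0.354) and first/second
   degree relatives (φ ≥ 0.0884), after dropping affected probands in
   favor of their healthy parents.
2. **Ancestry** — PCA on common autosomal variants, multinomial logistic
   classifier on the first ten principal components, Mahalanobis outlier
   removal of mis-self-reported training samples, and an "unassigned"
   label below a confidence threshold.
3. **Frequencies & tiers** — exact per-ancestry carrier frequencies
   (carriers = dosage ≥ 1, denominators exclude missing calls), the
   proband-parent correction, and tier assignment: tier 1 by gene list,
   tier 2 at carrier frequency ≥ 1/100, tier 3 at ≥ 1/200 or X-linked,
   tier 4 below. Comparisons use exact integer fractions, never the
   rounded "1/N" rendering.
4. **Candidates** — any-source P/LP selection, subtraction of existing
   panels, the frequency gate, and exclusion filters (reference AF >
   0.5%, ≥ 3 reference homozygotes, mild conditions).
5. **Curation** — a precedence rule engine over structured evidence
   records (healthy biallelic case ⇒ excluded; mild ⇒ excluded; affected
   biallelic case or causal literature ⇒ confirmed; else uncertain).
6. **Panel comparison** — variant- and gene-level coverage against
   existing panels, and sensitivity validation via Hardy–Weinberg carrier
   frequencies CF = 2p(1−p) from reference allele frequencies.
7. **Simulation** — a Balding–Nichols cohort generator (structured
   populations at controlled Fst, planted founder variants, Mendelian
   trios, duplicates, label errors, missingness) providing ground truth
   for every stage.

`run_pipeline()` chains all stages from a VCF + metadata + annotation
table on disk, writing one TSV artifact per stage and a JSON-lines log;
identical config and seed give byte-identical outputs.

## Worked example: the parent-removal correction changes a tier

A cohort recruited through affected children contains obligate-carrier
parents, inflating carrier frequencies. Reconstruct a 613-sample ancestry
group with 8 heterozygous carriers of a recessive variant, 4 of whom are
parents of homozygous affected probands:

```r
library(founderscreen)

cfg <- simulation_config(
  population_sizes = 613, fst = 0, n_background_variants = 40,
  founder_variants = data.frame(population = "muslim_arab",
                                carrier_frequency = 4/613,
                                inheritance = "AR", gene = "MADDL"),
  population_names = "muslim_arab", seed = 11)
sim <- simulate_cohort(cfg)
variant <- sim$annotation$variant_key[sim$annotation$is_founder]

g <- sim$genotypes; m <- sim$meta
set.seed(11)
for (i in 1:2) {                       # two affected trios for this variant
  fam <- plant_affected_family(g, m, variant, "muslim_arab", "homozygous")
  g <- fam$genotypes; m <- fam$meta
}
labels <- setNames(ifelse(m$role == "proband", "unassigned", "muslim_arab"),
                   m$sample_id)

before <- carrier_frequencies(g, labels, variant)
before[, c("ancestry", "n_carriers", "group_size", "one_in_n")]
#>      ancestry n_carriers group_size one_in_n
#> 1 muslim_arab          8        613     1/77
assign_tier(before[1, ], "AR")$tier
#> [1] 2

after <- remove_homozygous_proband_parents(before, g, m, labels,
                                           sim$annotation)
after[, c("ancestry", "n_carriers", "group_size", "one_in_n")]
#>      ancestry n_carriers group_size one_in_n
#> 1 muslim_arab          4        609    1/152
assign_tier(after[1, ], "AR")$tier
#> [1] 3
```

Eight carriers in 613 samples is a ~1/77 carrier frequency — tier 2. Four
of those carriers are only in the cohort because their affected child
brought the family in; removing them from this variant's calculation
leaves 4/609 ≈ 1/152, which is tier 3. The correction is per-variant:
records of other variants are untouched.

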