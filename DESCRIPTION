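Package: founderscreen
Title: Data-Driven Design of Pan-Ethnic Carrier Screening Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds tiered carrier screening panels from multi-sample cohort
    genotypes. Provides quality control by kinship-based relatedness pruning
    (KING-robust estimator), ancestry inference by principal component
    analysis with a multinomial classifier on the leading components,
    per-ancestry carrier frequency estimation with a correction that removes
    parents of homozygous or compound-heterozygous probands, carrier
    frequency tier assignment (tier 1 gene lists, tier 2 at 1/100, tier 3 at
    1/200 or X-linked, tier 4 below), candidate pathogenic founder variant
    selection and exclusion filtering, an evidence-based curation rule
    engine, comparison against variant- and gene-based screening panels, and
    a synthetic cohort generator (Balding-Nichols population structure,
    trios, duplicates, planted founder variants) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
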