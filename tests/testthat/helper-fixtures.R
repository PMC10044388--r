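# shared fixture builders and independent oracles

# dosage matrix from a list of per-sample vectors
dose_matrix <- function(..., keys = NULL) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  }
  colnames(m) <- keys %||% sprintf("1:%d:A:G", 100L + seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal annotation for a set of keys (parses chrom/pos/ref/alt out of the
# canonical key)
annotation_for <- function(keys, gene = NULL, inheritance = "AR",
                           severity = "severe", af = 0.001, hom = 0L,
                           classes = NULL) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  ann <- data.frame(
    variant_key = keys,
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    ref = vapply(parts, `[`, "", 3L),
    alt = vapply(parts, `[`, "", 4L),
    gene = gene %||% sprintf("G%03d", seq_along(keys)),
    inheritance = rep_len(inheritance, length(keys)),
    severity = rep_len(severity, length(keys)),
    reference_overall_af = rep_len(af, length(keys)),
    reference_homozygote_count = rep_len(as.integer(hom), length(keys)),
    stringsAsFactors = FALSE)
  # classes: optional list of character vectors of classification calls
  # per key (default: one "P" call each)
  ann$classifications <- lapply(seq_along(keys), function(i) {
    cls <- if (is.null(classes)) "P" else classes[[i]]
    data.frame(source = rep("clinvar", length(cls)), class = cls,
               stringsAsFactors = FALSE)
  })
  ann
}

# Hudson's two-population Fst estimator (ratio of averages over variants);
# independent of the simulator's internals
hudson_fst <- function(genotypes, pop_labels) {
  pops <- unique(pop_labels)
  stopifnot(length(pops) == 2L)
  g1 <- genotypes[pop_labels == pops[1], , drop = FALSE]
  g2 <- genotypes[pop_labels == pops[2], , drop = FALSE]
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  n1 <- colSums(!is.na(g1))
  n2 <- colSums(!is.na(g2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# per-pair brute-force KING-robust phi (independent re-implementation used
# as the oracle for the vectorized kinship matrix)
phi_brute <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  den <- sum(a == 1) + sum(b == 1)
  if (den == 0) return(NA_real_)
  (sum(a == 1 & b == 1) - 2 * sum(abs(a - b) == 2)) / den
}

# evidence-record constructors
evidence_row <- function(key, kind, zygosity = NA, status = NA,
                         source = "src1", causal = NA) {
  data.frame(variant_key = key, kind = kind, zygosity = zygosity,
             phenotype_status = status, source_id = source,
             causal = causal, stringsAsFactors = FALSE)
}
# full on-disk cohort + config for end-to-end pipeline runs: two ancestry
# groups, six planted founder variants exercising every pipeline gate
# (confirmable tier-2/3, benign-evidence exclusion, mild-condition
# exclusion, already-on-panel subtraction), trios and a duplicate
build_pipeline_fixture <- function(dir, seed = 71) {
  fv <- data.frame(
    population = c("ashkenazi", "ashkenazi", "muslim_arab", "muslim_arab",
                   "ashkenazi", "ashkenazi"),
    carrier_frequency = c(0.05, 0.0075, 0.04, 0.04, 0.04, 0.05),
    inheritance = "AR",
    gene = c("WFS1L", "TKTL", "ACSF3L", "BENIGN1", "MILD1", "KNOWN1"),
    stringsAsFactors = FALSE)
  cfg <- simulation_config(population_sizes = c(400, 400), fst = 0.05,
                           n_background_variants = 800,
                           founder_variants = fv,
                           n_trios_per_population = 2, n_duplicates = 1,
                           label_error_rate = 0.02, missing_rate = 0.01,
                           population_names = c("ashkenazi", "muslim_arab"),
                           seed = seed)
  sim <- simulate_cohort(cfg)
  ann <- sim$annotation
  fk <- ann$variant_key[ann$is_founder]
  names(fk) <- ann$gene[ann$is_founder]
  ann$severity[ann$gene == "MILD1"] <- "mild"

  paths <- list(vcf = file.path(dir, "cohort.vcf"),
                meta = file.path(dir, "meta.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                panel = file.path(dir, "israeli_panel.tsv"),
                evidence = file.path(dir, "evidence.tsv"),
                out = file.path(dir, "out"))
  write_cohort_vcf(sim$genotypes, ann, paths$vcf)
  write_sample_meta(sim$meta, paths$meta)
  write_annotation(ann, paths$annotation)
  known <- ann[ann$gene == "KNOWN1", ]
  utils::write.table(
    data.frame(gene = known$gene, transcript = "tx", hgvs_c = "c.?",
               chrom = known$chrom, pos = known$pos, ref = known$ref,
               alt = known$alt),
    paths$panel, sep = "\t", quote = FALSE, row.names = FALSE)
  ev <- rbind(
    evidence_row(fk[["WFS1L"]], "community_case", "homozygous",
                 "affected_concordant", source = "franklin1"),
    evidence_row(fk[["TKTL"]], "literature_report", causal = TRUE,
                 source = "pmid1"),
    evidence_row(fk[["ACSF3L"]], "community_case", "compound_het",
                 "affected_concordant", source = "franklin2"),
    evidence_row(fk[["BENIGN1"]], "community_case", "homozygous",
                 "healthy", source = "franklin3"))
  utils::write.table(ev, paths$evidence, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(paths = paths, sim = sim, founder_keys = fk, annotation = ann)
}

empty_evidence <- function() {
  data.frame(variant_key = character(0), kind = character(0),
             zygosity = character(0), phenotype_status = character(0),
             source_id = character(0), causal = logical(0),
             stringsAsFactors = FALSE)
}
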