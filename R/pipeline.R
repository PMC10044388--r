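pipeline_defaults <- list(
  vcf = NULL, meta = NULL, annotation = NULL,
  subtract_panels = list(), compare_panels = list(),
  evidence = NULL, tier1_genes = NULL, reference_af = NULL,
  target_ancestries = "auto", n_target_groups = 2L,
  dup_threshold = 0.354, second_degree_threshold = 0.0884,
  kinship_max_sites = 5000L,
  maf_min = 0.05, call_rate_min = 0.95, n_components = 10L,
  distance_quantile = 0.99, confidence_threshold = 0.8,
  min_frequency = 1 / 200, strict_tier3 = FALSE,
  af_max = 0.005, hom_max = 3L,
  validation_min_frequency = 1 / 200,
  genome_build = "GRCh37",
  seed = 1L, out_dir = "founderscreen_out"
)

#' Build a validated pipeline configuration
#'
#' All tunable thresholds of every stage live here: kinship pruning
#' thresholds, common-variant selection (MAF and call rate), the number of
#' principal components, the classifier confidence threshold, the tier
#' boundaries (1/100 and 1/200, as exact fractions), the exclusion-cascade
#' cutoffs (reference AF 0.005, homozygote count 3), the candidate
#' frequency gate, the seed and the output directory. Unknown keys are
#' rejected so typos never silently fall back to defaults.
#'
#' @param ... Named settings overriding the defaults (see
#'   `founderscreen:::pipeline_defaults`). Panel entries in
#'   `subtract_panels` / `compare_panels` are lists with `path`, `kind`
#'   and optional `name`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(pipeline_defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- pipeline_defaults
  cfg[names(over)] <- over   # plain replacement; no recursive list merging
  stopifnot(cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$call_rate_min >= 0, cfg$call_rate_min <= 1,
            cfg$n_components >= 1,
            cfg$confidence_threshold >= 0, cfg$confidence_threshold <= 1,
            cfg$min_frequency > 0, cfg$min_frequency <= 1,
            cfg$af_max >= 0, cfg$af_max <= 1, cfg$hom_max >= 0,
            cfg$second_degree_threshold > 0,
            cfg$dup_threshold >= cfg$second_degree_threshold)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return Validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

log_line <- function(con, stage, n_in, n_out, extra = NULL) {
  kv <- c(sprintf("\"stage\":\"%s\"", stage),
          sprintf("\"n_in\":%d", as.integer(n_in)),
          sprintf("\"n_out\":%d", as.integer(n_out)),
          extra)
  writeLines(paste0("{", paste(kv, collapse = ","), "}"), con)
}

#' Run the complete panel-design pipeline
#'
#' Chains every stage over a cohort on disk: cohort parsing, kinship-based
#' QC, ancestry model fitting and prediction, per-ancestry carrier
#' frequencies for the reported-P/LP candidates, the homozygous-proband
#' parent-removal correction, tier assignment, subtraction of existing
#' panels, the candidate frequency gate, the exclusion cascade, evidence
#' curation, and comparison/validation against external panels. Each stage
#' writes a TSV artifact into `out_dir` plus a JSON-lines log with
#' input/output record counts; a given configuration and seed always
#' produce byte-identical outputs.
#'
#' Stages whose inputs are not configured (no evidence file, no panels, no
#' reference allele frequencies) are skipped.
#'
#' @param config A [pipeline_config()] with at least `vcf`, `meta`,
#'   `annotation` and `out_dir` set.
#' @return Invisibly, a list with the in-memory results of every executed
#'   stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$vcf) || is.null(config$meta) ||
      is.null(config$annotation)) {
    stop("config must provide vcf, meta and annotation paths")
  }
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.jsonl")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  res <- list(config = config)

  # --- load ----------------------------------------------------------------
  cohort <- read_cohort(config$vcf, config$meta)
  annotation <- read_annotation(config$annotation)
  geno <- cohort$genotypes
  meta <- cohort$meta
  log_line(con, "read_cohort", nrow(geno), nrow(geno),
           sprintf("\"n_variants\":%d,\"genome_build\":\"%s\"",
                   ncol(geno), config$genome_build))

  # --- QC: relatedness pruning --------------------------------------------
  qc <- prune_cohort(geno, meta,
                     dup_threshold = config$dup_threshold,
                     second_degree_threshold = config$second_degree_threshold,
                     max_sites = config$kinship_max_sites)
  stopifnot(length(qc$retained) + nrow(qc$removed) == nrow(geno))
  writeLines(sort(qc$retained), file.path(config$out_dir,
                                          "retained_samples.txt"))
  write_tsv(qc$removed[order(qc$removed$sample_id), , drop = FALSE],
            file.path(config$out_dir, "removed_samples.tsv"))
  write_kinship_tsv(qc$kinship, file.path(config$out_dir,
                                          "kinship_pairs.tsv"))
  log_line(con, "qc_relatedness", nrow(geno), length(qc$retained))
  res$qc <- qc
  keep_geno <- geno[sort(qc$retained), , drop = FALSE]
  keep_meta <- meta[match(rownames(keep_geno), meta$sample_id), ]

  # --- ancestry ------------------------------------------------------------
  training <- keep_meta[!is.na(keep_meta$reported_ancestry), ]
  model <- fit_ancestry_model(keep_geno, annotation,
                              training$sample_id,
                              training$reported_ancestry,
                              maf_min = config$maf_min,
                              call_rate_min = config$call_rate_min,
                              n_components = config$n_components,
                              distance_quantile = config$distance_quantile,
                              confidence_threshold =
                                config$confidence_threshold)
  pred <- predict_ancestry(model, keep_geno)
  write_tsv(pred[order(pred$sample_id),
                 c("sample_id", "ancestry", "best_label", "confidence")],
            file.path(config$out_dir, "ancestry_assignments.tsv"))
  log_line(con, "ancestry", nrow(keep_geno),
           sum(pred$ancestry != "unassigned"))
  res$ancestry_model <- model
  res$ancestry <- pred
  labels <- stats::setNames(pred$ancestry, pred$sample_id)

  targets <- config$target_ancestries
  if (identical(targets, "auto")) {
    tab <- sort(table(labels[labels != "unassigned"]), decreasing = TRUE)
    targets <- names(tab)[seq_len(min(config$n_target_groups, length(tab)))]
  }
  res$target_ancestries <- targets

  # --- candidate P/LP variants and their frequencies ----------------------
  plp <- select_reported_plp(annotation)
  plp <- intersect(plp, colnames(geno))
  log_line(con, "select_reported_plp", nrow(annotation), length(plp))
  records <- carrier_frequencies(keep_geno, labels, plp)
  records <- remove_homozygous_proband_parents(records, geno, meta,
                                               labels, annotation)
  records <- tier_table(records, annotation,
                        tier1_genes = load_gene_list(config$tier1_genes),
                        strict_tier3 = config$strict_tier3)
  write_tsv(records[order(records$ancestry, records$variant_key), ],
            file.path(config$out_dir, "frequencies.tsv"))
  res$records <- records

  # --- panel subtraction, frequency gate, exclusion cascade ---------------
  candidates <- plp
  for (p in config$subtract_panels) {
    panel <- read_panel(p$path, name = p$name %||% NULL,
                        kind = p$kind %||% "variant_based")
    n_in <- length(candidates)
    candidates <- subtract_panel(candidates, panel, annotation)
    log_line(con, paste0("subtract_panel:", panel$name), n_in,
             length(candidates))
  }
  n_in <- length(candidates)
  candidates <- frequency_gate(records, candidates, targets,
                               min_frequency = config$min_frequency)
  log_line(con, "frequency_gate", n_in, length(candidates))
  excl <- exclusion_filters(candidates, annotation,
                            af_max = config$af_max, hom_max = config$hom_max)
  stopifnot(sum(excl$retained) + sum(!excl$retained) == length(candidates))
  write_tsv(excl[order(excl$variant_key), ],
            file.path(config$out_dir, "exclusion_report.tsv"))
  candidates <- excl$variant_key[excl$retained]
  log_line(con, "exclusion_filters", nrow(excl), length(candidates))
  writeLines(sort(candidates), file.path(config$out_dir, "candidates.txt"))
  res$candidates <- candidates

  # --- curation ------------------------------------------------------------
  if (!is.null(config$evidence)) {
    evidence <- read_evidence(config$evidence)
    severity <- annotation$severity[match(candidates,
                                          annotation$variant_key)]
    decisions <- lapply(seq_along(candidates), function(i) {
      ev <- evidence[evidence$variant_key == candidates[i], , drop = FALSE]
      curate_variant(candidates[i], ev, severity = severity[i])
    })
    summary <- summarize_curation(decisions, tiers = records)
    cur <- data.frame(
      variant_key = candidates,
      outcome = vapply(decisions, function(d) d$outcome, ""),
      supporting = vapply(decisions, function(d) {
        paste(d$supporting_items, collapse = ",")
      }, ""),
      conflicting = vapply(decisions, function(d) d$conflicting_evidence,
                           logical(1)),
      stringsAsFactors = FALSE)
    write_tsv(cur[order(cur$variant_key), ],
              file.path(config$out_dir, "curation.tsv"))
    write_tsv(summary$panel, file.path(config$out_dir, "final_panel.tsv"))
    log_line(con, "curation", length(candidates), nrow(summary$panel))
    res$curation <- summary
    final_keys <- summary$panel$variant_key
  } else {
    final_keys <- candidates
  }

  # --- comparison with external panels ------------------------------------
  if (length(config$compare_panels)) {
    panels <- lapply(config$compare_panels, function(p) {
      read_panel(p$path, name = p$name %||% NULL,
                 kind = p$kind %||% "gene_based")
    })
    vdf <- data.frame(
      variant_key = final_keys,
      gene = annotation$gene[match(final_keys, annotation$variant_key)],
      stringsAsFactors = FALSE)
    comparison <- compare_to_panels(vdf, panels)
    write_tsv(comparison, file.path(config$out_dir, "panel_comparison.tsv"))
    log_line(con, "panel_comparison", length(final_keys), nrow(comparison))
    res$comparison <- comparison
  }

  # --- sensitivity validation ---------------------------------------------
  if (!is.null(config$reference_af)) {
    ref <- utils::read.delim(config$reference_af, stringsAsFactors = FALSE)
    val <- sensitivity_validation(ref, plp,
                                  min_frequency =
                                    config$validation_min_frequency)
    write_tsv(data.frame(variant_key = val$reference_set,
                         found = val$reference_set %in% plp,
                         stringsAsFactors = FALSE),
              file.path(config$out_dir, "validation.tsv"))
    log_line(con, "validation", val$n_reference, val$n_found,
             sprintf("\"recall\":%s",
                     ifelse(is.na(val$recall), "null",
                            format(val$recall, digits = 10))))
    res$validation <- val
  }

  invisible(res)
}

load_gene_list <- function(path) {
  if (is.null(path)) return(character(0))
  readLines(path)
}
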