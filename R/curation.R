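#' Decide a candidate's fate from structured evidence
#'
#' Rule engine formalizing the manual curation step of panel design.
#' Evidence items are structured records of real-world observations:
#' community cases with a zygosity and phenotype status, literature
#' reports (optionally flagged causal), or archive submissions. Rules are
#' applied in a fixed precedence order:
#'
#' 1. any homozygous or compound-heterozygous community case in a healthy
#'    individual — or one with no associated phenotype — disproves
#'    pathogenicity: `excluded_benign_evidence`;
#' 2. a mild condition is excluded from screening: `excluded_mild`;
#' 3. a homozygous/compound-het community case with a concordant affected
#'    phenotype, or a causal literature report, confirms: `confirmed_pfv`;
#' 4. otherwise the variant stays `uncertain`.
#'
#' Exclusion outranking confirmation means contradictory evidence (healthy
#' and affected homozygotes both observed) resolves to exclusion; such
#' conflicts are additionally flagged for review.
#'
#' @param variant_key Candidate variant key.
#' @param evidence data.frame of evidence items with columns
#'   `variant_key`, `kind` (community_case / literature_report /
#'   clinvar_submission), `zygosity` (homozygous / compound_het /
#'   heterozygous / NA), `phenotype_status` (affected_concordant / healthy
#'   / unknown), `source_id`, and optional logical `causal` for literature
#'   reports. All rows must reference `variant_key`.
#' @param severity Condition severity ("severe", "moderate" or "mild").
#' @return List of class `"curation_decision"`: `variant_key`, `outcome`,
#'   `supporting_items` (source ids behind the outcome) and
#'   `conflicting_evidence` flag.
#' @export
curate_variant <- function(variant_key, evidence, severity = "severe") {
  if (nrow(evidence) > 0) {
    if (!all(evidence$variant_key == variant_key)) {
      stop("evidence items reference a different variant than ", variant_key)
    }
    comm <- evidence$kind == "community_case"
    if (any(comm & (is.na(evidence$zygosity) | evidence$zygosity == ""))) {
      stop("community_case evidence must carry a zygosity")
    }
  }
  biallelic <- nrow(evidence) > 0 & evidence$kind == "community_case" &
    evidence$zygosity %in% c("homozygous", "compound_het")
  benign_idx <- which(biallelic &
                        evidence$phenotype_status %in% c("healthy", "unknown"))
  affected_idx <- which(biallelic &
                          evidence$phenotype_status == "affected_concordant")
  causal <- if (!is.null(evidence$causal)) {
    !is.na(evidence$causal) & evidence$causal
  } else rep(FALSE, nrow(evidence))
  lit_idx <- which(nrow(evidence) > 0 &
                     evidence$kind == "literature_report" & causal)
  conflict <- length(benign_idx) > 0 && length(affected_idx) > 0

  decision <- function(outcome, idx) {
    structure(list(variant_key = variant_key, outcome = outcome,
                   supporting_items = evidence$source_id[idx],
                   conflicting_evidence = conflict),
              class = "curation_decision")
  }
  if (length(benign_idx)) {
    return(decision("excluded_benign_evidence", benign_idx))
  }
  if (identical(severity, "mild")) return(decision("excluded_mild", integer(0)))
  if (length(affected_idx) || length(lit_idx)) {
    return(decision("confirmed_pfv", c(affected_idx, lit_idx)))
  }
  decision("uncertain", integer(0))
}

#' Summarize curation decisions into the final panel
#'
#' Tallies outcomes and assembles the confirmed pathogenic founder
#' variants, with their tiers, into the final panel list, deterministically
#' ordered by tier, then gene, then variant key.
#'
#' @param decisions List of `"curation_decision"` objects, one per
#'   candidate (duplicate variant keys are an error).
#' @param tiers Optional tiered record table ([tier_table()] output) used
#'   to attach `tier`, `gene` and `ancestry` to panel rows; when a variant
#'   has records in several ancestries its best (lowest) tier is kept.
#' @return List: `counts` (named outcome tally over all four outcomes) and
#'   `panel` (data.frame of confirmed variants).
#' @export
summarize_curation <- function(decisions, tiers = NULL) {
  keys <- vapply(decisions, function(d) d$variant_key, "")
  if (anyDuplicated(keys)) {
    stop("duplicate curation decisions for: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  outcomes <- vapply(decisions, function(d) d$outcome, "")
  levels <- c("confirmed_pfv", "excluded_benign_evidence",
              "excluded_mild", "uncertain")
  counts <- table(factor(outcomes, levels = levels))
  confirmed <- keys[outcomes == "confirmed_pfv"]
  panel <- data.frame(variant_key = confirmed,
                      gene = rep(NA_character_, length(confirmed)),
                      ancestry = rep(NA_character_, length(confirmed)),
                      tier = rep(NA_integer_, length(confirmed)),
                      stringsAsFactors = FALSE)
  if (!is.null(tiers) && nrow(panel) > 0) {
    for (r in seq_len(nrow(panel))) {
      rec <- tiers[tiers$variant_key == panel$variant_key[r] &
                     !is.na(tiers$tier), , drop = FALSE]
      if (nrow(rec)) {
        best <- rec[order(rec$tier, rec$ancestry), ][1, ]
        panel$gene[r] <- best$gene
        panel$ancestry[r] <- best$ancestry
        panel$tier[r] <- best$tier
      }
    }
  }
  panel <- panel[order(panel$tier, panel$gene, panel$variant_key), ,
                 drop = FALSE]
  rownames(panel) <- NULL
  list(counts = c(counts), panel = panel)
}
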