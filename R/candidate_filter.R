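#' Select variants reported pathogenic or likely pathogenic
#'
#' A variant enters the candidate pool if at least one classification call
#' from any source is P or LP — an any-source rule: a single pathogenic
#' submission is enough even when other sources disagree.
#'
#' @param annotation Variant annotation with a `classifications`
#'   list-column of data.frames (columns `source`, `class` with classes in
#'   P/LP/VUS/LB/B).
#' @return Character vector of candidate variant keys.
#' @export
select_reported_plp <- function(annotation) {
  has_plp <- vapply(annotation$classifications, function(calls) {
    !is.null(calls) && nrow(calls) > 0 && any(calls$class %in% c("P", "LP"))
  }, logical(1))
  annotation$variant_key[has_plp]
}

#' Remove candidates already covered by an existing panel
#'
#' Variant-based panels are subtracted by exact canonical-key match;
#' gene-based panels by gene symbol. The result never intersects the
#' panel and the operation is idempotent.
#'
#' @param candidates Character vector of candidate variant keys.
#' @param panel A [panel_definition()].
#' @param annotation Needed (variant_key, gene) only for gene-based panels.
#' @return Candidate keys not covered by the panel.
#' @export
subtract_panel <- function(candidates, panel, annotation = NULL) {
  stopifnot(inherits(panel, "panel_definition"))
  if (panel$kind == "variant_based") {
    setdiff(candidates, panel$entries)
  } else {
    if (is.null(annotation)) {
      stop("gene-based panel subtraction needs the variant annotation")
    }
    genes <- annotation$gene[match(candidates, annotation$variant_key)]
    candidates[!(genes %in% panel$entries)]
  }
}

#' Gate candidates by carrier frequency in target ancestries
#'
#' A variant is retained when its carrier frequency reaches
#' `min_frequency` in at least one of the target ancestry groups, using
#' the exact-fraction comparison (so a frequency of exactly 1/200 passes a
#' 1/200 gate).
#'
#' @param records Frequency records ([carrier_frequencies()] output).
#' @param candidates Candidate variant keys to gate.
#' @param target_ancestries Ancestry labels whose frequencies count.
#' @param min_frequency Threshold as a fraction (default 1/200).
#' @return Retained candidate keys.
#' @export
frequency_gate <- function(records, candidates, target_ancestries,
                           min_frequency = 1 / 200) {
  denom <- 1 / min_frequency
  rec <- records[records$ancestry %in% target_ancestries &
                   records$variant_key %in% candidates, , drop = FALSE]
  pass <- rec$n_carriers * denom >= rec$group_size & rec$group_size > 0
  keep <- unique(rec$variant_key[pass])
  candidates[candidates %in% keep]
}

#' Automated exclusion cascade for candidate founder variants
#'
#' Removes candidates unlikely to be true pathogenic founder variants:
#' those common in a worldwide reference population (overall reference
#' allele frequency strictly above `af_max`), those with several reference
#' homozygotes (at or above `hom_max` — a recessive-lethal founder allele
#' should have next to none), and those causing only mild conditions. Each
#' exclusion records every rule it triggered, so the three rules commute.
#' Candidates with missing annotation fields are retained and flagged
#' "not_evaluable" rather than silently dropped, keeping them visible for
#' manual review.
#'
#' @param candidates Candidate variant keys.
#' @param annotation Annotation with `reference_overall_af`,
#'   `reference_homozygote_count`, `severity`.
#' @param af_max Reference allele-frequency cutoff, exclusive (default
#'   0.005, i.e. 0.5 percent; a variant at exactly 0.005 is retained).
#' @param hom_max Reference homozygote cutoff, inclusive (default 3).
#' @return data.frame: `variant_key`, `retained`, `reasons`
#'   (comma-separated machine-readable rule ids, "" when retained),
#'   `not_evaluable`.
#' @export
exclusion_filters <- function(candidates, annotation,
                              af_max = 0.005, hom_max = 3L) {
  i <- match(candidates, annotation$variant_key)
  af <- annotation$reference_overall_af[i]
  hom <- annotation$reference_homozygote_count[i]
  sev <- annotation$severity[i]
  n <- length(candidates)
  reasons <- vector("list", n)
  not_eval <- logical(n)
  for (j in seq_len(n)) {
    r <- character(0)
    if (is.na(af[j]) || is.na(hom[j]) || is.na(sev[j])) not_eval[j] <- TRUE
    if (!is.na(af[j]) && af[j] > af_max) r <- c(r, "af_gt_0.5pct")
    if (!is.na(hom[j]) && hom[j] >= hom_max) r <- c(r, "hom_ge_3")
    if (!is.na(sev[j]) && sev[j] == "mild") r <- c(r, "mild_condition")
    reasons[[j]] <- r
  }
  if (any(not_eval)) {
    warning(sum(not_eval), " candidate(s) not fully evaluable ",
            "(missing annotation fields); retained for manual review")
  }
  data.frame(
    variant_key = candidates,
    retained = lengths(reasons) == 0L,
    reasons = vapply(reasons, paste, "", collapse = ","),
    not_evaluable = not_eval,
    stringsAsFactors = FALSE
  )
}
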