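#' Define a screening panel
#'
#' @param name Panel name.
#' @param kind "variant_based" (entries are canonical variant keys) or
#'   "gene_based" (entries are gene symbols).
#' @param entries Character entries; deduplicated after normalization
#'   (gene symbols uppercased).
#' @return Object of class `"panel_definition"`.
#' @export
panel_definition <- function(name, kind = c("variant_based", "gene_based"),
                             entries) {
  kind <- match.arg(kind)
  entries <- as.character(entries)
  if (kind == "gene_based") entries <- toupper(entries)
  structure(list(name = name, kind = kind, entries = unique(entries)),
            class = "panel_definition")
}

#' Read a panel definition from TSV
#'
#' Variant-based panels carry columns (gene, transcript, hgvs_c, chrom,
#' pos, ref, alt); entries are normalized to canonical variant keys.
#' Gene-based panels carry a single `gene` column.
#'
#' @param path TSV path.
#' @param name Panel name (default: file base name).
#' @param kind Panel kind.
#' @param reference Optional reference sequences for key normalization.
#' @return A [panel_definition()].
#' @export
read_panel <- function(path, name = NULL,
                       kind = c("variant_based", "gene_based"),
                       reference = NULL) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (kind == "gene_based") {
    if (!"gene" %in% names(df)) stop("gene-based panel needs a 'gene' column")
    return(panel_definition(name, kind, df$gene))
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("variant-based panel needs columns: ", paste(need, collapse = ", "))
  }
  keys <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    keys[i] <- tryCatch(
      normalize_variant_key(df$chrom[i], df$pos[i], df$ref[i], df$alt[i],
                            reference = reference)$key,
      error = function(e) stop("malformed panel entry at line ", i + 1L,
                               " of ", path, ": ", conditionMessage(e)))
  }
  panel_definition(name, kind, keys)
}

#' Membership of variants across panels
#'
#' For variant-based panels membership is exact canonical-key match; for
#' gene-based panels it is gene-symbol membership. Both levels are
#' reported so a variant can be "covered at the gene level" by an
#' expanded panel even when the exact allele is not listed.
#'
#' @param variants data.frame with `variant_key` and `gene`.
#' @param panels List of [panel_definition()] objects.
#' @return Long-format data.frame: `variant_key`, `panel`, `kind`,
#'   `covered`, `match_level` ("variant", "gene" or `NA`).
#' @export
compare_to_panels <- function(variants, panels) {
  if (!length(panels)) {
    return(data.frame(variant_key = character(0), panel = character(0),
                      kind = character(0), covered = logical(0),
                      match_level = character(0), stringsAsFactors = FALSE))
  }
  out <- lapply(panels, function(p) {
    covered <- if (p$kind == "variant_based") {
      variants$variant_key %in% p$entries
    } else {
      toupper(variants$gene) %in% p$entries
    }
    data.frame(variant_key = variants$variant_key, panel = p$name,
               kind = p$kind, covered = covered,
               match_level = ifelse(covered,
                                    ifelse(p$kind == "variant_based",
                                           "variant", "gene"),
                                    NA_character_),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Carrier frequency from an allele frequency under Hardy-Weinberg
#'
#' Under Hardy-Weinberg equilibrium the heterozygote (carrier) frequency
#' for allele frequency p is 2p(1-p). The linear approximation 2p,
#' adequate for rare alleles, is available behind a flag.
#'
#' @param p Allele frequency in `[0, 1]` (vectorized).
#' @param approximate Use 2p instead of 2p(1-p).
#' @return Carrier frequency.
#' @examples
#' hwe_carrier_frequency(0.0025)  # 0.0049875, about 1/201
#' @export
hwe_carrier_frequency <- function(p, approximate = FALSE) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("allele frequency must lie in [0, 1]")
  }
  if (approximate) 2 * p else 2 * p * (1 - p)
}

#' Validate pipeline sensitivity against a reference panel
#'
#' Converts reference-population allele frequencies of an established
#' panel's variants to carrier frequencies under Hardy-Weinberg, selects
#' the reference tier-2/3 set (carrier frequency strictly above
#' `min_frequency` by default, per the validation convention), and
#' measures recall: the fraction of that set present in the pipeline's
#' candidate set. Optionally cross-tabulates reference tiers against the
#' cohort's tiers.
#'
#' @param reference data.frame with `variant_key` and `allele_frequency`
#'   (reference population AF).
#' @param candidates Pipeline candidate variant keys.
#' @param min_frequency Carrier-frequency threshold (default 1/200).
#' @param strict Strict ">" comparison (default TRUE here, matching the
#'   validation convention; tiering elsewhere defaults to inclusive).
#' @param cohort_tiers Optional named integer vector (variant key -> cohort
#'   tier) for the concordance table.
#' @return List: `reference_set` (selected keys), `n_reference`, `n_found`,
#'   `recall` (`NA` when the reference set is empty), `concordance`
#'   (table or `NULL`).
#' @export
sensitivity_validation <- function(reference, candidates,
                                   min_frequency = 1 / 200,
                                   strict = TRUE, cohort_tiers = NULL) {
  cf <- hwe_carrier_frequency(reference$allele_frequency)
  sel <- if (strict) cf > min_frequency else cf >= min_frequency
  ref_set <- reference$variant_key[sel]
  n_ref <- length(ref_set)
  found <- ref_set %in% candidates
  recall <- if (n_ref > 0) mean(found) else NA_real_
  concordance <- NULL
  if (!is.null(cohort_tiers) && n_ref > 0) {
    ref_tier <- ifelse(cf[sel] >= 1 / 100, 2L, 3L)
    coh_tier <- cohort_tiers[ref_set]
    concordance <- table(reference_tier = ref_tier,
                         cohort_tier = ifelse(is.na(coh_tier), "absent",
                                              as.character(coh_tier)))
  }
  list(reference_set = ref_set, n_reference = n_ref,
       n_found = sum(found), recall = recall, concordance = concordance)
}
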