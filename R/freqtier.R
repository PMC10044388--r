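#' Per-ancestry carrier frequencies
#'
#' For each (ancestry, variant) pair, counts carriers (dosage >= 1),
#' homozygotes (dosage 2) and the group size (samples of that ancestry with
#' a non-missing call at that site). The carrier frequency is the exact
#' ratio n_carriers / group_size; the conventional clinical "1/N" rendering
#' is attached for reporting but is never used in tier comparisons.
#' Samples labelled "unassigned" (or `NA`) are excluded from every group.
#'
#' @param genotypes Dosage matrix.
#' @param ancestry_labels Named character vector (names = sample ids) of
#'   assigned ancestries, e.g. the `ancestry` column of
#'   [predict_ancestry()] output.
#' @param variants Variant keys to evaluate (default: all columns).
#' @return data.frame of frequency records: `ancestry`, `variant_key`,
#'   `n_carriers`, `n_homozygous`, `group_size`, `frequency`, `one_in_n`.
#' @examples
#' g <- matrix(c(rep(1, 4), rep(0, 297)), ncol = 1,
#'             dimnames = list(sprintf("s%03d", 1:301), "1:100:A:G"))
#' carrier_frequencies(g, stats::setNames(rep("druze", 301), rownames(g)))$one_in_n
#' # "1/75"
#' @export
carrier_frequencies <- function(genotypes, ancestry_labels,
                                variants = colnames(genotypes)) {
  if (is.null(names(ancestry_labels))) {
    stop("ancestry_labels must be named by sample id")
  }
  labs <- ancestry_labels[!is.na(ancestry_labels) &
                            ancestry_labels != "unassigned"]
  labs <- labs[names(labs) %in% rownames(genotypes)]
  groups <- split(names(labs), labs)
  out <- list()
  for (anc in names(groups)) {
    sub <- genotypes[groups[[anc]], variants, drop = FALSE]
    ok <- !is.na(sub)
    n_car <- colSums(sub >= 1L & ok)
    n_hom <- colSums(sub == 2L & ok)
    gsz <- colSums(ok)
    out[[anc]] <- data.frame(
      ancestry = anc, variant_key = variants,
      n_carriers = as.integer(n_car), n_homozygous = as.integer(n_hom),
      group_size = as.integer(gsz),
      frequency = ifelse(gsz > 0, n_car / gsz, NA_real_),
      one_in_n = one_in_n(n_car, gsz),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove parents of homozygous / compound-heterozygous probands
#'
#' A clinical cohort is enriched for families ascertained through an
#' affected child; when a proband is homozygous (or compound heterozygous)
#' for a candidate variant, both parents are obligate carriers and inflate
#' that variant's carrier frequency. This correction removes, for each
#' variant separately, every sample that is a parent of a proband
#' homozygous for it — or compound heterozygous for it together with
#' another variant of the same gene — from both the numerator and the
#' denominator of that variant's frequency record. Records of other
#' variants are untouched.
#'
#' @param records Frequency records from [carrier_frequencies()].
#' @param genotypes Dosage matrix including proband genotypes (probands may
#'   be absent from `ancestry_labels` — e.g. removed by QC — but their
#'   genotypes drive the rule).
#' @param meta Sample metadata with `sample_id`, `family_id`, `role`,
#'   `affected`.
#' @param ancestry_labels Same labelling used to build `records`.
#' @param annotation Variant annotation (`variant_key`, `gene`) used to
#'   find gene partners for the compound-heterozygote rule; compound
#'   heterozygosity is only assessed over variants present in `records`.
#' @return `records` with adjusted counts, plus an `n_parents_removed`
#'   column.
#' @export
remove_homozygous_proband_parents <- function(records, genotypes, meta,
                                              ancestry_labels, annotation) {
  probands <- meta[meta$role == "proband" & meta$affected, , drop = FALSE]
  variants <- unique(records$variant_key)
  gene_of <- annotation$gene[match(variants, annotation$variant_key)]
  names(gene_of) <- variants

  excluded <- setNames(vector("list", length(variants)), variants)
  for (p in seq_len(nrow(probands))) {
    pid <- probands$sample_id[p]
    fam <- probands$family_id[p]
    if (!pid %in% rownames(genotypes)) next
    dos <- stats::setNames(genotypes[pid, variants], variants)
    het_keys <- variants[!is.na(dos) & dos == 1L]
    for (v in variants) {
      d <- dos[v]
      if (is.na(d)) next
      hom <- d == 2L
      cph <- d == 1L && !is.na(gene_of[v]) &&
        any(het_keys != v & gene_of[het_keys] %in% gene_of[v])
      if (!hom && !cph) next
      if (is.na(fam)) {
        warning("proband ", pid, " qualifies for parent removal at ", v,
                " but has no family link; no removal")
        next
      }
      parents <- meta$sample_id[!is.na(meta$family_id) &
                                  meta$family_id == fam &
                                  meta$role == "parent"]
      if (!length(parents)) {
        warning("family ", fam, " of proband ", pid,
                " has no parent samples; no removal")
        next
      }
      excluded[[v]] <- union(excluded[[v]], parents)
    }
  }

  labs <- ancestry_labels[!is.na(ancestry_labels) &
                            ancestry_labels != "unassigned"]
  labs <- labs[names(labs) %in% rownames(genotypes)]
  records$n_parents_removed <- 0L
  for (v in variants) {
    ex <- excluded[[v]]
    if (is.null(ex) || !length(ex)) next
    rows <- which(records$variant_key == v)
    for (r in rows) {
      anc <- records$ancestry[r]
      ids <- setdiff(names(labs)[labs == anc], ex)
      dos <- genotypes[ids, v]
      ok <- !is.na(dos)
      records$n_carriers[r] <- sum(dos >= 1L & ok)
      records$n_homozygous[r] <- sum(dos == 2L & ok)
      new_g <- sum(ok)
      records$n_parents_removed[r] <- records$group_size[r] - new_g
      records$group_size[r] <- new_g
      records$frequency[r] <- if (new_g > 0) {
        records$n_carriers[r] / new_g
      } else NA_real_
      records$one_in_n[r] <- one_in_n(records$n_carriers[r], new_g)
    }
  }
  records
}

# exact-fraction comparison: n/g >= 1/den  <=>  n * den >= g
freq_at_least <- function(n_carriers, group_size, denom, strict = FALSE) {
  if (strict) n_carriers * denom > group_size
  else n_carriers * denom >= group_size
}

#' Assign a carrier-screening tier
#'
#' Tiering follows the four-tier carrier-screening stratification: tier 1
#' is membership of an explicit core gene list; otherwise a carrier
#' frequency of at least 1/100 gives tier 2; at least 1/200 — or an
#' X-linked condition regardless of frequency — gives tier 3; everything
#' else is tier 4. Comparisons use the exact fraction
#' n_carriers/group_size, never the rounded "1/N" rendering, so boundary
#' cases (exactly 1/100 or 1/200) resolve per the inclusive ">=" rule;
#' `strict_tier3 = TRUE` switches the 1/200 boundary to a strict ">".
#'
#' @param record A frequency record (list or one-row data.frame with
#'   `n_carriers` and `group_size`).
#' @param inheritance "AR" or "XL".
#' @param tier1_genes Character vector of core-list genes.
#' @param gene Gene symbol of the variant (for the tier 1 lookup).
#' @param strict_tier3 Use a strict inequality at the 1/200 boundary.
#' @return List of class `"tier_result"`: `tier` (integer 1-4) and `basis`
#'   ("tier1_list", "frequency" or "x_linked").
#' @export
assign_tier <- function(record, inheritance = "AR",
                        tier1_genes = character(0), gene = NULL,
                        strict_tier3 = FALSE) {
  n <- record$n_carriers
  g <- record$group_size
  if (is.null(g) || is.na(g) || g <= 0L) {
    stop("tier assignment needs group_size > 0")
  }
  if (!is.null(gene) && !is.na(gene) && gene %in% tier1_genes) {
    return(structure(list(tier = 1L, basis = "tier1_list"),
                     class = "tier_result"))
  }
  if (freq_at_least(n, g, 100L)) {
    return(structure(list(tier = 2L, basis = "frequency"),
                     class = "tier_result"))
  }
  if (freq_at_least(n, g, 200L, strict = strict_tier3)) {
    return(structure(list(tier = 3L, basis = "frequency"),
                     class = "tier_result"))
  }
  if (identical(inheritance, "XL")) {
    return(structure(list(tier = 3L, basis = "x_linked"),
                     class = "tier_result"))
  }
  structure(list(tier = 4L, basis = "frequency"), class = "tier_result")
}

#' Tier every frequency record of a table
#'
#' Vectorized [assign_tier()] over a frequency-record table joined with the
#' variant annotation for gene and inheritance.
#'
#' @inheritParams assign_tier
#' @param records Frequency records ([carrier_frequencies()] output).
#' @param annotation Variant annotation (`variant_key`, `gene`,
#'   `inheritance`).
#' @return `records` with `gene`, `inheritance`, `tier` and `tier_basis`
#'   columns appended; records with `group_size` 0 get `NA` tiers.
#' @export
tier_table <- function(records, annotation, tier1_genes = character(0),
                       strict_tier3 = FALSE) {
  i <- match(records$variant_key, annotation$variant_key)
  records$gene <- annotation$gene[i]
  records$inheritance <- annotation$inheritance[i]
  n <- nrow(records)
  records$tier <- NA_integer_
  records$tier_basis <- NA_character_
  for (r in seq_len(n)) {
    if (is.na(records$group_size[r]) || records$group_size[r] <= 0L) next
    tr <- assign_tier(records[r, ], inheritance = records$inheritance[r],
                      tier1_genes = tier1_genes, gene = records$gene[r],
                      strict_tier3 = strict_tier3)
    records$tier[r] <- tr$tier
    records$tier_basis[r] <- tr$basis
  }
  records
}

#' Wilson score interval for a carrier frequency
#'
#' Optional reporting utility; tier assignment never uses it.
#'
#' @param n_carriers,group_size Counts.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
carrier_frequency_ci <- function(n_carriers, group_size, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- n_carriers / group_size
  den <- 1 + z^2 / group_size
  ctr <- (p + z^2 / (2 * group_size)) / den
  hw <- z * sqrt(p * (1 - p) / group_size +
                   z^2 / (4 * group_size^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}
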