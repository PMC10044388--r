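chrom_order <- function(chrom) {
  match(as.character(chrom), c(as.character(1:22), "X", "Y", "MT"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a cohort as a multi-sample VCF
#'
#' Minimal VCF v4.2 with a GT-only FORMAT, 1-based positions, records
#' sorted by chromosome then position. Dosages map to unphased diploid
#' genotypes: 0 -> "0/0", 1 -> "0/1", 2 -> "1/1", missing -> "./.".
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param annotation Variant annotation with chrom/pos/ref/alt per key.
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_cohort_vcf <- function(genotypes, annotation, path) {
  ann <- annotation[match(colnames(genotypes), annotation$variant_key), ]
  ord <- order(chrom_order(ann$chrom), ann$pos)
  ann <- ann[ord, ]
  geno <- genotypes[, ord, drop = FALSE]
  gt <- matrix("./.", nrow = ncol(geno), ncol = nrow(geno))
  codes <- c("0/0", "0/1", "1/1")
  idx <- !is.na(t(geno))
  gt[idx] <- codes[t(geno)[idx] + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=founderscreen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- paste(ann$chrom, ann$pos, ann$variant_key, ann$ref, ann$alt,
                ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write / read the sample metadata sidecar
#'
#' @param meta Sample metadata data.frame.
#' @param path TSV path.
#' @return Invisibly `path` (write) / the data.frame (read).
#' @export
write_sample_meta <- function(meta, path) write_tsv(meta, path)

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  meta$affected <- as.logical(meta$affected)
  meta
}

#' Write / read the variant annotation table
#'
#' The `classifications` list-column is serialized as
#' "source:class|source:class" (empty string when no calls exist).
#'
#' @param annotation Annotation data.frame.
#' @param path TSV path.
#' @return Invisibly `path` (write) / the data.frame (read).
#' @export
write_annotation <- function(annotation, path) {
  df <- annotation
  if (!is.null(df$classifications)) {
    df$classifications <- vapply(df$classifications, function(calls) {
      if (is.null(calls) || nrow(calls) == 0) return("")
      paste(paste0(calls$source, ":", calls$class), collapse = "|")
    }, "")
  }
  write_tsv(df, path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(df$chrom)) df$chrom <- as.character(df$chrom)
  if (!is.null(df$classifications)) {
    raw <- df$classifications
    df$classifications <- lapply(raw, function(s) {
      if (is.na(s) || s == "") {
        return(data.frame(source = character(0), class = character(0),
                          stringsAsFactors = FALSE))
      }
      parts <- strsplit(strsplit(s, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
      data.frame(source = vapply(parts, `[`, "", 1L),
                 class = vapply(parts, `[`, "", 2L),
                 stringsAsFactors = FALSE)
    })
  }
  df
}

# GT string -> per-allele dosage for alt allele `allele_idx`; half calls and
# "./." are missing
gt_to_dosage <- function(gt, allele_idx) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".") || any(is.na(a))) {
      return(NA_integer_)
    }
    sum(a == as.character(allele_idx))
  }, integer(1))
}

#' Read a cohort from a VCF and metadata sidecar
#'
#' Parses diploid GT calls to alternate-allele dosages. Multi-allelic
#' records are split into one biallelic row per alternate allele (the
#' dosage counts that allele only); every resulting variant is re-keyed
#' through [normalize_variant_key()]. Half calls and "./." become missing.
#'
#' @param vcf_path Multi-sample VCF (v4.x, GT field).
#' @param meta_path Optional metadata TSV whose `sample_id` column must
#'   match the VCF sample ids exactly.
#' @param reference Optional reference sequences for key normalization.
#' @return List with `genotypes` (dosage matrix), `meta` (or `NULL`) and
#'   `variants` (data.frame chrom/pos/ref/alt/variant_key).
#' @export
read_cohort <- function(vcf_path, meta_path = NULL, reference = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) fix <- t(as.matrix(fix))   # single-record VCF
  if (nrow(fix) == 0L) stop("VCF contains no records: ", vcf_path)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.matrix(gt_raw)) {
    gt_raw <- matrix(gt_raw, nrow = 1L,
                     dimnames = list(NULL, names(gt_raw)))
  }
  samples <- colnames(gt_raw)

  rows <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    for (a in seq_along(alts)) {
      key <- tryCatch(
        normalize_variant_key(fix[r, "CHROM"], as.integer(fix[r, "POS"]),
                              fix[r, "REF"], alts[a], reference = reference),
        error = function(e) {
          stop("malformed record at ", fix[r, "CHROM"], ":", fix[r, "POS"],
               ": ", conditionMessage(e))
        })
      rows[[length(rows) + 1L]] <- list(key = key, row = r, allele = a)
    }
  }
  geno <- matrix(NA_integer_, nrow = length(samples), ncol = length(rows),
                 dimnames = list(samples,
                                 vapply(rows, function(x) x$key$key, "")))
  for (j in seq_along(rows)) {
    geno[, j] <- gt_to_dosage(gt_raw[rows[[j]]$row, ], rows[[j]]$allele)
  }
  variants <- data.frame(
    variant_key = colnames(geno),
    chrom = vapply(rows, function(x) x$key$chrom, ""),
    pos = vapply(rows, function(x) x$key$pos, 1L),
    ref = vapply(rows, function(x) x$key$ref, ""),
    alt = vapply(rows, function(x) x$key$alt, ""),
    stringsAsFactors = FALSE)

  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- read_sample_meta(meta_path)
    if (!setequal(meta$sample_id, samples)) {
      only_meta <- setdiff(meta$sample_id, samples)
      only_vcf <- setdiff(samples, meta$sample_id)
      stop("sample ids differ between VCF and metadata; only in metadata: ",
           paste(utils::head(only_meta, 5), collapse = ", "),
           "; only in VCF: ", paste(utils::head(only_vcf, 5), collapse = ", "))
    }
    meta <- meta[match(samples, meta$sample_id), ]
    rownames(meta) <- NULL
  }
  list(genotypes = geno, meta = meta, variants = variants)
}

#' Read evidence records for curation
#'
#' @param path TSV with columns variant_key, kind, zygosity,
#'   phenotype_status, source_id and optional logical causal.
#' @return data.frame of evidence items.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if (!is.null(ev$causal)) ev$causal <- as.logical(ev$causal)
  ev
}
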