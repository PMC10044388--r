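#' Normalize a variant to its canonical key
#'
#' Reduces a (chrom, pos, ref, alt) tuple to a minimal, canonical
#' representation so that the same allele written in different ways (extra
#' padding bases, right-shifted indels) always yields the same key. The
#' procedure is: uppercase alleles; trim the shared suffix; trim the shared
#' prefix, advancing `pos` by one base per trimmed prefix character; and,
#' when a reference sequence is supplied, left-align indels by extending the
#' alleles leftward along the reference while they share a terminal base.
#'
#' @param chrom Chromosome name (coerced to character; a leading "chr" is
#'   stripped so "chr1" and "1" match).
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Reference and alternate alleles (A/C/G/T only).
#' @param reference Optional named list/vector of chromosome sequences
#'   (plain character strings) used for left-alignment of indels.
#' @return A list with elements `chrom`, `pos`, `ref`, `alt` and the
#'   canonical string `key` ("chrom:pos:ref:alt").
#' @examples
#' normalize_variant_key("1", 100, "AT", "AC")$key  # "1:101:T:C"
#' @export
normalize_variant_key <- function(chrom, pos, ref, alt, reference = NULL) {
  chrom <- sub("^chr", "", as.character(chrom))
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop("alleles must contain only A, C, G, T; got ref='", ref,
         "' alt='", alt, "'")
  }
  if (identical(ref, alt)) {
    stop("ref and alt are identical ('", ref, "'): not a variant")
  }
  chromseq <- if (!is.null(reference)) reference[[chrom]] else NULL

  repeat {
    # trim shared suffix (keep at least one base on each allele)
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    # left-extend along the reference while the alleles still share a
    # terminal base (only possible for indels, and only with a reference)
    if (!is.null(chromseq) && nchar(ref) != nchar(alt) && pos > 1L &&
        substr(ref, nchar(ref), nchar(ref)) ==
        substr(alt, nchar(alt), nchar(alt))) {
      prev <- toupper(substr(chromseq, pos - 1L, pos - 1L))
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
      next
    }
    break
  }
  # trim shared prefix, advancing pos
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt,
       key = paste(chrom, pos, ref, alt, sep = ":"))
}

#' Build canonical variant keys for vectors of variant fields
#'
#' Vectorized convenience wrapper around [normalize_variant_key()].
#'
#' @inheritParams normalize_variant_key
#' @return Character vector of canonical keys.
#' @export
variant_keys <- function(chrom, pos, ref, alt, reference = NULL) {
  mapply(function(c, p, r, a) {
    normalize_variant_key(c, p, r, a, reference = reference)$key
  }, chrom, pos, ref, alt, USE.NAMES = FALSE)
}

# round half away from zero; base round() is half-to-even which would render
# 4 carriers in 301 as "1/75" either way but disagrees at exact .5 boundaries
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Render a carrier frequency as "1/N"
#'
#' N is `group_size / n_carriers` rounded half away from zero. This is the
#' conventional clinical rendering; tier comparisons always use the exact
#' fraction, never this rounded form.
#'
#' @param n_carriers Carrier count (dosage >= 1).
#' @param group_size Number of samples with a non-missing call.
#' @return "1/N" as character, or `NA_character_` when there are no carriers.
#' @examples
#' one_in_n(4, 301)   # "1/75"
#' one_in_n(15, 1011) # "1/67"
#' @export
one_in_n <- function(n_carriers, group_size) {
  ifelse(n_carriers > 0,
         paste0("1/", round_half_away(group_size / n_carriers)),
         NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
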