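#' Pairwise kinship coefficient (KING-robust)
#'
#' Estimates the kinship coefficient between two samples from diploid
#' dosage vectors using the allele-frequency-free between-family estimator
#'
#' \deqn{\phi = \frac{N_{het,het} - 2\,N_{opp.hom}}{N_{het,i} + N_{het,j}}}
#'
#' where counts are taken over sites called in both samples: sites where
#' both are heterozygous, sites with opposite homozygotes (0 vs 2), and the
#' per-sample heterozygous site counts. Because no population allele
#' frequencies enter the estimate it remains unbiased under population
#' structure, which matters in a multi-ethnic cohort. Expected values are
#' about 0.5 for duplicates/MZ twins, 0.25 for first-degree and 0.125 for
#' second-degree relatives, and 0 for unrelated pairs.
#'
#' @param genotypes_i,genotypes_j Dosage vectors (0/1/2, `NA` missing) of
#'   equal length.
#' @return A list of class `"kinship_estimate"`: `phi` (`NA` when no
#'   heterozygous sites exist in either sample, in which case the pair is
#'   flagged `undefined` and treated as unrelated), `n_informative_sites`
#'   (sites called in both samples) and `undefined`.
#' @examples
#' kinship_coefficient(c(0, 1, 1, 2), c(0, 1, 1, 2))$phi  # 0.5
#' @export
kinship_coefficient <- function(genotypes_i, genotypes_j) {
  if (length(genotypes_i) != length(genotypes_j)) {
    stop("dosage vectors must have equal length")
  }
  ok <- !is.na(genotypes_i) & !is.na(genotypes_j)
  gi <- genotypes_i[ok]; gj <- genotypes_j[ok]
  n_hh <- sum(gi == 1L & gj == 1L)
  n_opp <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  het_i <- sum(gi == 1L)
  het_j <- sum(gj == 1L)
  denom <- het_i + het_j
  structure(list(
    phi = if (denom > 0L) (n_hh - 2 * n_opp) / denom else NA_real_,
    n_informative_sites = sum(ok),
    undefined = denom == 0L
  ), class = "kinship_estimate")
}

#' Full pairwise kinship matrix
#'
#' Vectorized KING-robust kinship over all sample pairs via indicator
#' matrix products; missing calls are excluded pairwise.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param max_sites Optional cap on the number of sites used (evenly spaced
#'   subsample) to bound cost on large cohorts; kinship needs only a few
#'   thousand informative sites for degree-level resolution.
#' @return Symmetric numeric matrix of phi values (`NA` where undefined),
#'   with sample ids as dimnames.
#' @export
kinship_matrix <- function(genotypes, max_sites = NULL) {
  if (!is.null(max_sites) && ncol(genotypes) > max_sites) {
    keep <- round(seq(1L, ncol(genotypes), length.out = max_sites))
    genotypes <- genotypes[, keep, drop = FALSE]
  }
  m <- !is.na(genotypes)
  g <- genotypes; g[!m] <- 0L
  H <- (g == 1L) & m; storage.mode(H) <- "double"
  A0 <- (g == 0L) & m; storage.mode(A0) <- "double"
  A2 <- (g == 2L) & m; storage.mode(A2) <- "double"
  M <- m; storage.mode(M) <- "double"

  n_hh <- tcrossprod(H)
  n_opp <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  het_shared_i <- tcrossprod(H, M)   # sites het in i and called in j
  denom <- het_shared_i + t(het_shared_i)
  phi <- (n_hh - 2 * n_opp) / denom
  phi[denom == 0] <- NA_real_
  diag(phi) <- 0.5
  dimnames(phi) <- list(rownames(genotypes), rownames(genotypes))
  phi
}

#' Prune a cohort of duplicates, close relatives and affected probands
#'
#' Reproduces the cohort quality-control step of the panel pipeline:
#' affected probands are removed first (their healthy parents carry the
#' transmitted alleles and are retained), then samples are greedily removed
#' from the kinship graph until no retained pair has phi at or above the
#' second-degree threshold. Greedy removal takes the node with the highest
#' number of remaining related partners first (ties broken by lexicographic
#' sample id, later id removed), which maximizes the number of retained
#' samples in the common case.
#'
#' @param genotypes Dosage matrix.
#' @param meta Sample metadata with `sample_id`, `role`, `affected`.
#' @param dup_threshold Kinship at or above which a pair is considered
#'   duplicated/monozygotic (default 0.354, the geometric midpoint between
#'   the duplicate and first-degree expectations).
#' @param second_degree_threshold Kinship at or above which a pair is
#'   related to second degree or closer (default 0.0884); all such pairs
#'   are broken.
#' @param max_sites Passed to [kinship_matrix()].
#' @return A list: `retained` (character ids), `removed` (data.frame of
#'   id + reason "affected_proband" or "related"), and the `kinship`
#'   matrix computed over the post-proband cohort.
#' @export
prune_cohort <- function(genotypes, meta,
                         dup_threshold = 0.354,
                         second_degree_threshold = 0.0884,
                         max_sites = NULL) {
  ids <- rownames(genotypes)
  if (length(ids) == 0L) {
    return(list(retained = character(0),
                removed = data.frame(sample_id = character(0),
                                     reason = character(0)),
                kinship = matrix(numeric(0), 0, 0)))
  }
  stopifnot(setequal(ids, meta$sample_id))
  meta <- meta[match(ids, meta$sample_id), ]

  probands <- ids[meta$affected & meta$role == "proband"]
  keep <- setdiff(ids, probands)
  removed <- data.frame(sample_id = probands,
                        reason = rep("affected_proband", length(probands)),
                        stringsAsFactors = FALSE)

  phi <- kinship_matrix(genotypes[keep, , drop = FALSE],
                        max_sites = max_sites)
  adj <- !is.na(phi) & phi >= second_degree_threshold
  diag(adj) <- FALSE

  alive <- rep(TRUE, length(keep))
  names(alive) <- keep
  repeat {
    deg <- rowSums(adj[alive, alive, drop = FALSE])
    if (!length(deg) || max(deg) == 0L) break
    worst <- names(deg)[deg == max(deg)]
    drop_id <- sort(worst, decreasing = TRUE)[1]   # ties: later id removed
    alive[drop_id] <- FALSE
    partners <- phi[drop_id, names(alive)[alive]]
    reason <- if (any(!is.na(partners) & partners >= dup_threshold)) {
      "duplicate"
    } else {
      "related"
    }
    removed <- rbind(removed,
                     data.frame(sample_id = drop_id, reason = reason,
                                stringsAsFactors = FALSE))
  }
  list(retained = names(alive)[alive], removed = removed, kinship = phi)
}

#' Write a pairwise kinship table
#'
#' Upper-triangle pairs of a kinship matrix as TSV (sample_i, sample_j,
#' phi), for inspection or downstream filtering.
#'
#' @param phi Kinship matrix from [kinship_matrix()].
#' @param path Output TSV path.
#' @param min_phi Only pairs with phi at or above this value are written
#'   (default keeps the file small by reporting related pairs only).
#' @return Invisibly, the written data.frame.
#' @export
write_kinship_tsv <- function(phi, path, min_phi = 0.0442) {
  idx <- which(upper.tri(phi) & !is.na(phi) & phi >= min_phi,
               arr.ind = TRUE)
  out <- data.frame(sample_i = rownames(phi)[idx[, 1]],
                    sample_j = colnames(phi)[idx[, 2]],
                    phi = phi[idx], stringsAsFactors = FALSE)
  out <- out[order(-out$phi, out$sample_i), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
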