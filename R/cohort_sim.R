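#' Configuration for a synthetic cohort
#'
#' Defines the structured population model used by [simulate_cohort()].
#' Population allele frequencies diverge from a shared ancestral frequency
#' under the Balding-Nichols model: for ancestral frequency p and divergence
#' F (the fixation index Fst), the per-population frequency is drawn from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so E[p_k] = p and Var[p_k] = F p(1-p).
#' Genotypes are then binomial under Hardy-Weinberg equilibrium within each
#' population.
#'
#' @param population_sizes Integer vector (>= 1 each) of founder sample
#'   counts per population; its length sets the number of populations and
#'   its sum the cohort size before trios and duplicates are added.
#' @param fst Per-population divergence in `[0, 1)`; recycled to the number
#'   of populations. `0` means the population sits exactly at the ancestral
#'   frequency.
#' @param n_background_variants Number of neutral biallelic variants.
#' @param ancestral_maf_range Interval in `(0, 0.5]` from which ancestral
#'   allele frequencies are drawn uniformly.
#' @param founder_variants Optional data.frame with columns `population`,
#'   `carrier_frequency` (fraction in `(0, 0.5]`), `inheritance` ("AR" or
#'   "XL") and optionally `gene`; one planted pathogenic founder variant per
#'   row, present as heterozygotes in exactly
#'   `round(carrier_frequency * population_size)` samples of the target
#'   population and absent elsewhere.
#' @param n_trios_per_population Trio families added per population: two
#'   existing samples become parents and an affected proband offspring is
#'   generated by Mendelian transmission.
#' @param n_duplicates Number of samples duplicated verbatim (before
#'   missingness), emulating repeat submissions of the same individual.
#' @param label_error_rate Probability that a sample's self-reported
#'   ancestry label differs from its true population.
#' @param missing_rate Probability that any single genotype call is missing.
#' @param population_names Optional character names; defaults to
#'   "pop01", "pop02", ...
#' @param binomial_founders If `TRUE`, planted carrier counts are drawn
#'   Binomial(size, carrier_frequency) instead of being exact; the exact
#'   default makes frequency-recovery checks deterministic.
#' @param seed Integer seed; identical configurations (including the seed)
#'   produce bit-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(population_sizes,
                              fst = 0.05,
                              n_background_variants = 2000L,
                              ancestral_maf_range = c(0.01, 0.5),
                              founder_variants = NULL,
                              n_trios_per_population = 0L,
                              n_duplicates = 0L,
                              label_error_rate = 0,
                              missing_rate = 0,
                              population_names = NULL,
                              binomial_founders = FALSE,
                              seed = 1L) {
  population_sizes <- as.integer(population_sizes)
  k <- length(population_sizes)
  if (k < 1L || any(population_sizes < 1L)) {
    stop("population_sizes must contain at least one population of size >= 1")
  }
  fst <- rep_len(as.numeric(fst), k)
  if (any(fst < 0 | fst >= 1)) stop("fst values must lie in [0, 1)")
  if (length(ancestral_maf_range) != 2L ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  if (label_error_rate < 0 || label_error_rate >= 1) {
    stop("label_error_rate must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (is.null(population_names)) {
    population_names <- sprintf("pop%02d", seq_len(k))
  }
  stopifnot(length(population_names) == k, !anyDuplicated(population_names))

  if (!is.null(founder_variants)) {
    founder_variants <- as.data.frame(founder_variants,
                                      stringsAsFactors = FALSE)
    req <- c("population", "carrier_frequency", "inheritance")
    if (!all(req %in% names(founder_variants))) {
      stop("founder_variants needs columns: ", paste(req, collapse = ", "))
    }
    if (!all(founder_variants$population %in% population_names)) {
      stop("founder_variants reference unknown populations: ",
           paste(setdiff(founder_variants$population, population_names),
                 collapse = ", "))
    }
    cf <- founder_variants$carrier_frequency
    if (any(cf <= 0 | cf > 0.5)) {
      stop("founder carrier frequencies must lie in (0, 0.5]")
    }
    if (!all(founder_variants$inheritance %in% c("AR", "XL"))) {
      stop("founder inheritance must be 'AR' or 'XL'")
    }
    sizes <- population_sizes[match(founder_variants$population,
                                    population_names)]
    planted <- round_half_away(cf * sizes)
    bad <- which(planted > sizes)
    if (length(bad)) {
      stop("infeasible founder variant spec (row ", bad[1],
           "): ", planted[bad[1]], " carriers exceed population size ",
           sizes[bad[1]])
    }
    if (is.null(founder_variants$gene)) {
      founder_variants$gene <- sprintf("FND%d", seq_len(nrow(founder_variants)))
    }
  }

  structure(list(
    population_sizes = population_sizes,
    population_names = population_names,
    fst = fst,
    n_background_variants = as.integer(n_background_variants),
    ancestral_maf_range = as.numeric(ancestral_maf_range),
    founder_variants = founder_variants,
    n_trios_per_population = as.integer(n_trios_per_population),
    n_duplicates = as.integer(n_duplicates),
    label_error_rate = label_error_rate,
    missing_rate = missing_rate,
    binomial_founders = isTRUE(binomial_founders),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a structured cohort with trios, duplicates and founder variants
#'
#' Generates a diploid dosage matrix (samples x variants; 0/1/2, `NA` for
#' missing), per-sample metadata and a variant annotation table. Background
#' variants follow the Balding-Nichols / Hardy-Weinberg model described in
#' [simulation_config()]; planted founder variants appear as heterozygotes
#' in exactly the configured number of carriers of their target population
#' and nowhere else; trio offspring obey Mendelian transmission; duplicate
#' samples are exact copies of their template taken before missingness is
#' applied.
#'
#' @param config A [simulation_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{integer matrix, rownames sample ids, colnames
#'       canonical variant keys.}
#'     \item{meta}{data.frame: `sample_id`, `population` (true),
#'       `reported_ancestry`, `family_id`, `role` ("unrelated", "parent",
#'       "proband", "duplicate"), `affected`, `duplicate_of`.}
#'     \item{annotation}{data.frame: `variant_key`, `chrom`, `pos`, `ref`,
#'       `alt`, `gene`, `inheritance`, `severity`, `reference_overall_af`,
#'       `reference_homozygote_count`, `is_founder`, `founder_population`,
#'       `target_carrier_frequency`, plus a `classifications` list-column of
#'       (source, class) calls (founder variants carry a "P" call).}
#'   }
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  k <- length(config$population_sizes)
  pops <- config$population_names
  sizes <- config$population_sizes
  n_founder_samples <- sum(sizes)
  n_bg <- config$n_background_variants
  fv <- config$founder_variants
  n_fv <- if (is.null(fv)) 0L else nrow(fv)
  n_var <- n_bg + n_fv

  # --- variant coordinates -------------------------------------------------
  bases <- c("A", "C", "G", "T")
  chrom <- character(n_var)
  if (n_bg > 0L) chrom[seq_len(n_bg)] <- as.character(sample(1:22, n_bg, TRUE))
  if (n_fv > 0L) {
    chrom[n_bg + seq_len(n_fv)] <-
      ifelse(fv$inheritance == "XL", "X", as.character(sample(1:22, n_fv, TRUE)))
  }
  pos <- sample.int(5e7, n_var, replace = FALSE)
  ref <- sample(bases, n_var, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  keys <- paste(chrom, pos, ref, alt, sep = ":")

  # --- background allele frequencies and genotypes -------------------------
  p_anc <- stats::runif(n_bg, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
  geno <- matrix(0L, nrow = n_founder_samples, ncol = n_var)
  pop_of <- rep(pops, sizes)
  row_start <- cumsum(c(0L, sizes[-k]))
  for (i in seq_len(k)) {
    f <- config$fst[i]
    p_pop <- if (f == 0 || n_bg == 0L) p_anc else {
      stats::rbeta(n_bg, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
    rows <- row_start[i] + seq_len(sizes[i])
    if (n_bg > 0L) {
      geno[rows, seq_len(n_bg)] <-
        stats::rbinom(sizes[i] * n_bg, 2L, rep(p_pop, each = sizes[i]))
    }
  }

  # --- planted founder variants -------------------------------------------
  if (n_fv > 0L) {
    for (j in seq_len(n_fv)) {
      i <- match(fv$population[j], pops)
      rows <- row_start[i] + seq_len(sizes[i])
      n_car <- if (config$binomial_founders) {
        stats::rbinom(1L, sizes[i], fv$carrier_frequency[j])
      } else {
        round_half_away(fv$carrier_frequency[j] * sizes[i])
      }
      carriers <- sample(rows, min(n_car, sizes[i]))
      geno[carriers, n_bg + j] <- 1L
    }
  }

  sample_ids <- sprintf("S%05d", seq_len(n_founder_samples))
  rownames(geno) <- sample_ids
  colnames(geno) <- keys

  meta <- data.frame(
    sample_id = sample_ids,
    population = pop_of,
    reported_ancestry = pop_of,
    family_id = NA_character_,
    role = "unrelated",
    affected = FALSE,
    duplicate_of = NA_character_,
    stringsAsFactors = FALSE
  )

  # --- trios ---------------------------------------------------------------
  fam_counter <- 0L
  if (config$n_trios_per_population > 0L) {
    for (i in seq_len(k)) {
      avail <- which(meta$population == pops[i] & meta$role == "unrelated")
      need <- 2L * config$n_trios_per_population
      if (length(avail) < need) {
        stop("population ", pops[i], " too small for ",
             config$n_trios_per_population, " trios")
      }
      parents <- sample(avail, need)
      for (t in seq_len(config$n_trios_per_population)) {
        fam_counter <- fam_counter + 1L
        fam <- sprintf("FAM%04d", fam_counter)
        p1 <- parents[2L * t - 1L]; p2 <- parents[2L * t]
        meta$role[c(p1, p2)] <- "parent"
        meta$family_id[c(p1, p2)] <- fam
        child <- mendelian_offspring(geno[p1, ], geno[p2, ])
        child_id <- paste0(fam, "_c1")
        geno <- rbind(geno, matrix(child, nrow = 1L,
                                   dimnames = list(child_id, keys)))
        meta <- rbind(meta, data.frame(
          sample_id = child_id, population = pops[i],
          reported_ancestry = pops[i], family_id = fam, role = "proband",
          affected = TRUE, duplicate_of = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }

  # --- duplicates (exact copies, pre-missingness) --------------------------
  if (config$n_duplicates > 0L) {
    templates <- sample(which(meta$role == "unrelated"),
                        config$n_duplicates)
    for (d in seq_along(templates)) {
      tmpl <- templates[d]
      dup_id <- sprintf("DUP%03d", d)
      geno <- rbind(geno, matrix(geno[tmpl, ], nrow = 1L,
                                 dimnames = list(dup_id, keys)))
      meta <- rbind(meta, data.frame(
        sample_id = dup_id, population = meta$population[tmpl],
        reported_ancestry = meta$reported_ancestry[tmpl],
        family_id = NA_character_, role = "duplicate", affected = FALSE,
        duplicate_of = meta$sample_id[tmpl], stringsAsFactors = FALSE))
    }
  }

  # --- self-report label errors -------------------------------------------
  if (config$label_error_rate > 0 && k > 1L) {
    flip <- stats::runif(nrow(meta)) < config$label_error_rate
    for (s in which(flip)) {
      meta$reported_ancestry[s] <-
        sample(setdiff(pops, meta$population[s]), 1L)
    }
  }

  # --- uniform missingness -------------------------------------------------
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }

  storage.mode(geno) <- "integer"
  rownames(meta) <- NULL

  annotation <- data.frame(
    variant_key = keys, chrom = chrom, pos = pos, ref = ref, alt = alt,
    gene = c(sprintf("BG%04d", seq_len(n_bg)),
             if (n_fv > 0L) fv$gene else character(0)),
    inheritance = c(rep("AR", n_bg),
                    if (n_fv > 0L) fv$inheritance else character(0)),
    severity = "severe",
    reference_overall_af = c(round(p_anc, 6), rep(0.0005, n_fv)),
    reference_homozygote_count = 0L,
    is_founder = c(rep(FALSE, n_bg), rep(TRUE, n_fv)),
    founder_population = c(rep(NA_character_, n_bg),
                           if (n_fv > 0L) fv$population else character(0)),
    target_carrier_frequency = c(rep(NA_real_, n_bg),
                                 if (n_fv > 0L) fv$carrier_frequency
                                 else numeric(0)),
    stringsAsFactors = FALSE
  )
  annotation$classifications <- lapply(annotation$is_founder, function(f) {
    if (f) data.frame(source = "clinvar", class = "P",
                      stringsAsFactors = FALSE)
    else data.frame(source = character(0), class = character(0),
                    stringsAsFactors = FALSE)
  })

  list(genotypes = geno, meta = meta, annotation = annotation)
}

# Mendelian offspring dosage from two parental dosage vectors: each parent
# transmits one allele, Binomial(1, dosage/2); NA wherever a parent is NA.
mendelian_offspring <- function(g1, g2) {
  n <- length(g1)
  a1 <- stats::rbinom(n, 1L, g1 / 2)
  a2 <- stats::rbinom(n, 1L, g2 / 2)
  out <- a1 + a2
  out[is.na(g1) | is.na(g2)] <- NA_integer_
  as.integer(out)
}

#' Plant an affected trio for a variant
#'
#' Converts two unused samples of a population into heterozygous carrier
#' parents and adds an affected proband offspring that is either homozygous
#' for `variant` or compound heterozygous over `variant` and
#' `partner_variant` (a second variant of the same gene, one inherited from
#' each parent). This creates exactly the family structure that the
#' homozygous-proband parent-removal correction of
#' [remove_homozygous_proband_parents()] acts on.
#'
#' Parents are drawn from samples with `role == "unrelated"`, no family
#' link, and dosage 0 at the involved variant(s), so each planted family
#' adds exactly two new carriers of `variant` among the existing samples.
#'
#' @param genotypes Dosage matrix as produced by [simulate_cohort()].
#' @param meta Matching sample metadata.
#' @param variant Canonical key of the variant (must be a column).
#' @param population Target population.
#' @param kind `"homozygous"` or `"compound_het"`.
#' @param partner_variant Second variant key, required for
#'   `"compound_het"`.
#' @return List with updated `genotypes` and `meta`.
#' @export
plant_affected_family <- function(genotypes, meta, variant, population,
                                  kind = c("homozygous", "compound_het"),
                                  partner_variant = NULL) {
  kind <- match.arg(kind)
  if (!variant %in% colnames(genotypes)) {
    stop("variant ", variant, " not present in the genotype matrix")
  }
  involved <- variant
  if (kind == "compound_het") {
    if (is.null(partner_variant)) {
      stop("compound_het planting requires partner_variant")
    }
    if (!partner_variant %in% colnames(genotypes)) {
      stop("partner variant ", partner_variant, " not present")
    }
    involved <- c(variant, partner_variant)
  }
  free <- which(meta$population == population & meta$role == "unrelated" &
                  is.na(meta$family_id) & !meta$affected)
  zero_dose <- vapply(free, function(s) {
    d <- genotypes[meta$sample_id[s], involved]
    all(!is.na(d)) && all(d == 0L)
  }, logical(1))
  free <- free[zero_dose]
  if (length(free) < 2L) {
    stop("population ", population,
         " has no capacity: fewer than 2 unused non-carrier samples")
  }
  free <- free[order(meta$sample_id[free])][1:2]

  existing <- meta$family_id[!is.na(meta$family_id)]
  fam_counter <- sum(grepl("^PFAM", existing))
  fam <- sprintf("PFAM%04d", fam_counter + 1L)
  meta$role[free] <- "parent"
  meta$family_id[free] <- fam
  ids <- meta$sample_id[free]

  child <- mendelian_offspring(genotypes[ids[1], ], genotypes[ids[2], ])
  names(child) <- colnames(genotypes)
  if (kind == "homozygous") {
    genotypes[ids, variant] <- 1L
    child[variant] <- 2L
  } else {
    genotypes[ids[1], variant] <- 1L
    genotypes[ids[2], partner_variant] <- 1L
    child[variant] <- 1L
    child[partner_variant] <- 1L
  }
  child_id <- paste0(fam, "_c1")
  genotypes <- rbind(genotypes,
                     matrix(child, nrow = 1L,
                            dimnames = list(child_id, colnames(genotypes))))
  meta <- rbind(meta, data.frame(
    sample_id = child_id, population = population,
    reported_ancestry = population, family_id = fam, role = "proband",
    affected = TRUE, duplicate_of = NA_character_, stringsAsFactors = FALSE))
  rownames(meta) <- NULL
  list(genotypes = genotypes, meta = meta)
}
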