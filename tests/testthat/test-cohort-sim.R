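test_that("identical configurations reproduce bit-identical cohorts", {
  cfg <- simulation_config(population_sizes = c(40, 40), fst = 0.05,
                           n_background_variants = 200,
                           n_trios_per_population = 2, n_duplicates = 1,
                           label_error_rate = 0.1, missing_rate = 0.02,
                           seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$meta, b$meta)
  expect_identical(a$annotation, b$annotation)
})

test_that("invalid configurations are rejected with explicit messages", {
  expect_error(simulation_config(population_sizes = integer(0)),
               "at least one population")
  expect_error(simulation_config(c(10, 10), fst = 1), "\\[0, 1\\)")
  expect_error(simulation_config(10, ancestral_maf_range = c(0, 0.6)),
               "\\(0, 0.5\\]")
  # carrier count larger than the population is infeasible by construction
  expect_error(
    simulation_config(10, founder_variants = data.frame(
      population = "pop01", carrier_frequency = 0.51, inheritance = "AR")),
    "\\(0, 0.5\\]")
  expect_error(
    simulation_config(10, founder_variants = data.frame(
      population = "nope", carrier_frequency = 0.1, inheritance = "AR")),
    "unknown populations")
})

test_that("planted founder variants hit their exact carrier counts", {
  cfg <- simulation_config(
    population_sizes = c(1000, 400), fst = 0.02,
    n_background_variants = 50,
    founder_variants = data.frame(
      population = c("pop01", "pop02"),
      carrier_frequency = c(0.01, 0.05),
      inheritance = c("AR", "XL")),
    seed = 3)
  sim <- simulate_cohort(cfg)
  ann <- sim$annotation[sim$annotation$is_founder, ]
  pop1 <- sim$meta$sample_id[sim$meta$population == "pop01"]
  pop2 <- sim$meta$sample_id[sim$meta$population == "pop02"]
  v1 <- ann$variant_key[ann$founder_population == "pop01"]
  v2 <- ann$variant_key[ann$founder_population == "pop02"]
  expect_equal(sum(sim$genotypes[pop1, v1] >= 1), 10)     # 0.01 * 1000
  expect_equal(sum(sim$genotypes[pop2, v1] >= 1), 0)
  expect_equal(sum(sim$genotypes[pop2, v2] >= 1), 20)     # 0.05 * 400
  expect_equal(sum(sim$genotypes[pop1, v2] >= 1), 0)
  # all planted as heterozygotes; X-linked variants live on chromosome X
  expect_true(all(sim$genotypes[, c(v1, v2)] <= 1))
  expect_equal(ann$chrom[ann$variant_key == v2], "X")
})

test_that("zero divergence yields homogeneous allele frequencies", {
  cfg <- simulation_config(population_sizes = c(300, 300), fst = 0,
                           n_background_variants = 1000, seed = 3)
  sim <- simulate_cohort(cfg)
  g <- sim$genotypes
  is1 <- sim$meta$population == "pop01"
  pvals <- vapply(seq_len(ncol(g)), function(j) {
    a <- g[is1, j]; b <- g[!is1, j]
    tab <- rbind(c(sum(a), 2 * length(a) - sum(a)),
                 c(sum(b), 2 * length(b) - sum(b)))
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("realized divergence matches the configured Fst", {
  cfg <- simulation_config(population_sizes = c(500, 500), fst = 0.05,
                           n_background_variants = 5000, seed = 1)
  sim <- simulate_cohort(cfg)
  fst_hat <- hudson_fst(sim$genotypes, sim$meta$population)
  expect_gte(fst_hat, 0.03)
  expect_lte(fst_hat, 0.07)
})

test_that("trio offspring are Mendelian-consistent and duplicates exact", {
  cfg <- simulation_config(population_sizes = c(80, 80), fst = 0.05,
                           n_background_variants = 300,
                           n_trios_per_population = 3, n_duplicates = 2,
                           seed = 21)
  sim <- simulate_cohort(cfg)
  g <- sim$genotypes
  m <- sim$meta
  for (fam in unique(stats::na.omit(m$family_id))) {
    members <- m[!is.na(m$family_id) & m$family_id == fam, ]
    child <- members$sample_id[members$role == "proband"]
    parents <- members$sample_id[members$role == "parent"]
    expect_length(parents, 2)
    gc <- g[child, ]; g1 <- g[parents[1], ]; g2 <- g[parents[2], ]
    ok <- !is.na(gc) & !is.na(g1) & !is.na(g2)
    # a child allele count must be achievable from one allele per parent
    lo <- (g1 == 2) + (g2 == 2)
    hi <- 2 - ((g1 == 0) + (g2 == 0))
    expect_true(all(gc[ok] >= lo[ok] & gc[ok] <= hi[ok]))
    expect_true(all(members$affected == (members$role == "proband")))
  }
  dups <- m[m$role == "duplicate", ]
  for (r in seq_len(nrow(dups))) {
    expect_identical(g[dups$sample_id[r], ], g[dups$duplicate_of[r], ])
  }
})

test_that("self-report label errors occur at roughly the configured rate", {
  cfg <- simulation_config(population_sizes = c(500, 500, 500), fst = 0.02,
                           n_background_variants = 20,
                           label_error_rate = 0.1, seed = 5)
  sim <- simulate_cohort(cfg)
  err <- mean(sim$meta$reported_ancestry != sim$meta$population)
  expect_gt(err, 0.06)
  expect_lt(err, 0.14)
})

test_that("planting affected families creates the advertised genotypes", {
  cfg <- simulation_config(
    population_sizes = 60, fst = 0, n_background_variants = 40,
    founder_variants = data.frame(
      population = c("pop01", "pop01"), carrier_frequency = c(0.05, 0.05),
      inheritance = "AR", gene = c("GENEA", "GENEA")),
    seed = 8)
  sim <- simulate_cohort(cfg)
  fk <- sim$annotation$variant_key[sim$annotation$is_founder]

  set.seed(1)
  hom <- plant_affected_family(sim$genotypes, sim$meta, fk[1], "pop01",
                               "homozygous")
  fam <- hom$meta[!is.na(hom$meta$family_id), ]
  proband <- fam$sample_id[fam$role == "proband"]
  parents <- fam$sample_id[fam$role == "parent"]
  expect_equal(unname(hom$genotypes[proband, fk[1]]), 2L)
  expect_equal(unname(hom$genotypes[parents, fk[1]]), c(1L, 1L))

  ch <- plant_affected_family(hom$genotypes, hom$meta, fk[1], "pop01",
                              "compound_het", partner_variant = fk[2])
  fam2 <- ch$meta[!is.na(ch$meta$family_id) &
                    ch$meta$family_id != fam$family_id[1], ]
  proband2 <- fam2$sample_id[fam2$role == "proband"]
  parents2 <- sort(fam2$sample_id[fam2$role == "parent"])
  expect_equal(unname(ch$genotypes[proband2, fk]), c(1L, 1L))
  # each parent carries exactly one of the two variants
  carried <- ch$genotypes[parents2, fk]
  expect_equal(unname(rowSums(carried)), c(1L, 1L))
  expect_equal(unname(colSums(carried)), c(1L, 1L))
})

test_that("family planting refuses when the population lacks capacity", {
  cfg <- simulation_config(population_sizes = c(5, 30), fst = 0,
                           n_background_variants = 10,
                           founder_variants = data.frame(
                             population = "pop01", carrier_frequency = 0.5,
                             inheritance = "AR"),
                           seed = 2)
  sim <- simulate_cohort(cfg)
  fk <- sim$annotation$variant_key[sim$annotation$is_founder]
  # 3 of 5 pop01 samples carry; only 2 non-carriers exist, so a second
  # family cannot be planted
  r1 <- plant_affected_family(sim$genotypes, sim$meta, fk, "pop01",
                              "homozygous")
  expect_error(plant_affected_family(r1$genotypes, r1$meta, fk, "pop01",
                                     "homozygous"),
               "no capacity")
  expect_error(plant_affected_family(sim$genotypes, sim$meta,
                                     "9:1:A:T", "pop01", "homozygous"),
               "not present")
})

test_that("planted families shift counts by two carriers per family", {
  cfg <- simulation_config(
    population_sizes = 200, fst = 0, n_background_variants = 30,
    founder_variants = data.frame(population = "pop01",
                                  carrier_frequency = 0.02,
                                  inheritance = "AR"),
    seed = 13)
  sim <- simulate_cohort(cfg)
  fk <- sim$annotation$variant_key[sim$annotation$is_founder]
  g <- sim$genotypes; m <- sim$meta
  set.seed(99)
  for (i in 1:4) {
    r <- plant_affected_family(g, m, fk, "pop01", "homozygous")
    g <- r$genotypes; m <- r$meta
  }
  labels <- stats::setNames(
    ifelse(m$role == "proband", "unassigned", "pop01"), m$sample_id)
  before <- carrier_frequencies(g, labels, fk)
  after <- remove_homozygous_proband_parents(before, g, m, labels,
                                             sim$annotation)
  expect_equal(before$n_carriers, 4L + 8L)      # 4 planted + 4 families x 2
  expect_equal(before$group_size, 200L)
  expect_equal(before$n_carriers - after$n_carriers, 8L)
  expect_equal(before$group_size - after$group_size, 8L)
})
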