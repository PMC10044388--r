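test_that("carrier frequencies count carriers, homozygotes and callable samples", {
  # 4 carriers among 301 samples renders as 1/75
  g <- dose_matrix(keys = "1:500:A:G",
                   matrix(c(rep(1L, 3), 2L, rep(0L, 297)), ncol = 1))
  rownames(g) <- sprintf("d%03d", 1:301)
  labels <- stats::setNames(rep("druze", 301), rownames(g))
  rec <- carrier_frequencies(g, labels)
  expect_equal(rec$n_carriers, 4L)
  expect_equal(rec$n_homozygous, 1L)
  expect_equal(rec$group_size, 301L)
  expect_equal(rec$one_in_n, "1/75")
  expect_equal(rec$frequency, 4 / 301)

  # zero carriers: frequency 0, no 1-in-N rendering
  g0 <- dose_matrix(c(0, 0), c(0, 0), c(0, 0))
  rec0 <- carrier_frequencies(g0, stats::setNames(rep("x", 3),
                                                  rownames(g0)))
  expect_true(all(rec0$frequency == 0))
  expect_true(all(is.na(rec0$one_in_n)))

  # missing calls leave both numerator and denominator
  gm <- dose_matrix(c(1), c(NA), c(0), c(2))
  recm <- carrier_frequencies(gm, stats::setNames(rep("p", 4),
                                                  rownames(gm)))
  expect_equal(recm$group_size, 3L)
  expect_equal(recm$n_carriers, 2L)

  # unassigned samples never enter any group
  labs <- stats::setNames(c("a", "unassigned", "a", NA), rownames(gm))
  recu <- carrier_frequencies(gm, labs)
  expect_equal(recu$group_size, 2L)   # only samples 1 and 3 are labelled
  expect_equal(recu$n_carriers, 1L)
})

test_that("per-ancestry carrier counts partition the cohort-wide count", {
  cfg <- simulation_config(population_sizes = c(90, 70, 50), fst = 0.05,
                           n_background_variants = 120,
                           missing_rate = 0.03, seed = 41)
  sim <- simulate_cohort(cfg)
  labels <- stats::setNames(sim$meta$population, sim$meta$sample_id)
  rec <- carrier_frequencies(sim$genotypes, labels)
  by_variant <- tapply(rec$n_carriers, rec$variant_key, sum)
  cohort_wide <- colSums(sim$genotypes >= 1L, na.rm = TRUE)
  expect_equal(as.vector(by_variant[names(cohort_wide)]),
               as.vector(cohort_wide))
})

test_that("planted carrier frequencies are recovered exactly on clean data", {
  cfg <- simulation_config(
    population_sizes = c(400, 250), fst = 0.05,
    n_background_variants = 60,
    founder_variants = data.frame(
      population = c("pop01", "pop02", "pop01"),
      carrier_frequency = c(0.01, 0.04, 0.025),
      inheritance = "AR"),
    seed = 42)
  sim <- simulate_cohort(cfg)
  ann <- sim$annotation[sim$annotation$is_founder, ]
  labels <- stats::setNames(sim$meta$population, sim$meta$sample_id)
  rec <- carrier_frequencies(sim$genotypes, labels, ann$variant_key)
  home <- rec[rec$ancestry == ann$founder_population[
    match(rec$variant_key, ann$variant_key)], ]
  expected <- ann$target_carrier_frequency[match(home$variant_key,
                                                 ann$variant_key)]
  expect_identical(home$frequency, expected)
  # and absent everywhere else
  away <- rec[rec$ancestry != ann$founder_population[
    match(rec$variant_key, ann$variant_key)], ]
  expect_true(all(away$n_carriers == 0L))
})

test_that("parent removal adjusts only the affected variant's record", {
  cfg <- simulation_config(
    population_sizes = 150, fst = 0, n_background_variants = 20,
    founder_variants = data.frame(
      population = c("pop01", "pop01"),
      carrier_frequency = c(0.04, 0.04), inheritance = "AR",
      gene = c("GA", "GB")),
    seed = 44)
  sim <- simulate_cohort(cfg)
  fk <- sim$annotation$variant_key[sim$annotation$is_founder]
  set.seed(5)
  r <- plant_affected_family(sim$genotypes, sim$meta, fk[1], "pop01",
                             "homozygous")
  labels <- stats::setNames(
    ifelse(r$meta$role == "proband", "unassigned", "pop01"),
    r$meta$sample_id)
  before <- carrier_frequencies(r$genotypes, labels, fk)
  after <- remove_homozygous_proband_parents(before, r$genotypes, r$meta,
                                             labels, sim$annotation)
  i1 <- which(after$variant_key == fk[1])
  i2 <- which(after$variant_key == fk[2])
  expect_equal(after$group_size[i1], before$group_size[i1] - 2L)
  expect_equal(after$n_carriers[i1], before$n_carriers[i1] - 2L)
  # untouched sibling variant
  expect_equal(after[i2, c("n_carriers", "group_size")],
               before[i2, c("n_carriers", "group_size")])

  # adjusted counts equal a brute-force recount on the reduced sample set
  fam <- r$meta$family_id[r$meta$role == "proband" & r$meta$affected]
  parents <- r$meta$sample_id[!is.na(r$meta$family_id) &
                                r$meta$family_id %in% fam &
                                r$meta$role == "parent"]
  ids <- setdiff(names(labels)[labels == "pop01"], parents)
  expect_equal(after$n_carriers[i1],
               sum(r$genotypes[ids, fk[1]] >= 1, na.rm = TRUE))
  expect_equal(after$group_size[i1],
               sum(!is.na(r$genotypes[ids, fk[1]])))
})

test_that("a compound-het proband's parent is removed for both involved variants", {
  cfg <- simulation_config(
    population_sizes = 1013, fst = 0, n_background_variants = 10,
    founder_variants = data.frame(
      population = c("pop01", "pop01"),
      carrier_frequency = c(8 / 1013, 0.005), inheritance = "AR",
      gene = c("USH_GENE", "USH_GENE")),
    seed = 45)
  sim <- simulate_cohort(cfg)
  fk <- sim$annotation$variant_key[sim$annotation$is_founder]
  set.seed(6)
  r <- plant_affected_family(sim$genotypes, sim$meta, fk[1], "pop01",
                             "compound_het", partner_variant = fk[2])
  labels <- stats::setNames(
    ifelse(r$meta$role == "proband", "unassigned", "ashkenazi"),
    r$meta$sample_id)
  before <- carrier_frequencies(r$genotypes, labels, fk)
  after <- remove_homozygous_proband_parents(before, r$genotypes, r$meta,
                                             labels, sim$annotation)
  i1 <- which(after$variant_key == fk[1])
  # 8 planted + 1 planted parent = 9 carriers / 1013; both parents of the
  # compound-het proband leave the denominator, the carrying one also
  # leaves the numerator
  expect_equal(before$n_carriers[i1], 9L)
  expect_equal(after$n_carriers[i1], 8L)
  expect_equal(after$group_size[i1], 1011L)
  expect_equal(after$n_parents_removed[i1], 2L)
  # tier unchanged by this correction (well above 1/200 either way)
  expect_equal(assign_tier(before[i1, ])$tier,
               assign_tier(after[i1, ])$tier)
})

test_that("cohorts without affected probands are left untouched", {
  cfg <- simulation_config(population_sizes = 80, fst = 0,
                           n_background_variants = 30, seed = 46)
  sim <- simulate_cohort(cfg)
  labels <- stats::setNames(sim$meta$population, sim$meta$sample_id)
  rec <- carrier_frequencies(sim$genotypes, labels)
  adj <- remove_homozygous_proband_parents(rec, sim$genotypes, sim$meta,
                                           labels, sim$annotation)
  expect_equal(adj[names(rec)], rec)
})

test_that("orphaned family links warn instead of removing", {
  g <- dose_matrix(c(2), c(1), c(1), keys = "1:10:A:G")
  meta <- data.frame(sample_id = rownames(g),
                     family_id = c("F1", NA, NA),
                     role = c("proband", "unrelated", "unrelated"),
                     affected = c(TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  labels <- stats::setNames(c("unassigned", "a", "a"), rownames(g))
  rec <- carrier_frequencies(g, labels)
  expect_warning(
    adj <- remove_homozygous_proband_parents(rec, g, meta, labels,
                                             annotation_for("1:10:A:G")),
    "no parent samples")
  expect_equal(adj$n_carriers, rec$n_carriers)
})

test_that("tier assignment reproduces the four-tier rules at exact fractions", {
  rec <- function(n, g) list(n_carriers = n, group_size = g)
  # worked examples: 1/68 -> tier 2; 1/154 and 1/113 -> tier 3
  expect_equal(assign_tier(rec(1, 68))$tier, 2L)
  expect_equal(assign_tier(rec(1, 154))$tier, 3L)
  expect_equal(assign_tier(rec(1, 113))$tier, 3L)
  expect_equal(assign_tier(rec(1, 250))$tier, 4L)
  # X-linked conditions are tier 3 regardless of frequency
  xl <- assign_tier(rec(1, 5000), inheritance = "XL")
  expect_equal(xl$tier, 3L)
  expect_equal(xl$basis, "x_linked")
  # tier 1 only through the explicit gene list
  t1 <- assign_tier(rec(1, 5000), gene = "HEXA", tier1_genes = c("HEXA"))
  expect_equal(t1$tier, 1L)
  expect_equal(t1$basis, "tier1_list")

  # inclusive boundaries: exactly 1/100 is tier 2, exactly 1/200 tier 3
  expect_equal(assign_tier(rec(5, 500))$tier, 2L)
  expect_equal(assign_tier(rec(5, 1000))$tier, 3L)
  # strict mode pushes the exact 1/200 boundary to tier 4
  expect_equal(assign_tier(rec(5, 1000), strict_tier3 = TRUE)$tier, 4L)
  expect_equal(assign_tier(rec(5, 1000), inheritance = "XL",
                           strict_tier3 = TRUE)$tier, 3L)

  expect_error(assign_tier(rec(0, 0)), "group_size > 0")
})

test_that("AR tier is monotone non-increasing in carrier frequency", {
  set.seed(7)
  for (i in 1:200) {
    g1 <- sample(50:2000, 1); n1 <- sample(0:20, 1)
    g2 <- sample(50:2000, 1); n2 <- sample(0:20, 1)
    if (n1 / g1 < n2 / g2) {   # ensure f1 >= f2
      tmp <- c(n1, g1); n1 <- n2; g1 <- g2; n2 <- tmp[1]; g2 <- tmp[2]
    }
    t1 <- assign_tier(list(n_carriers = n1, group_size = g1))$tier
    t2 <- assign_tier(list(n_carriers = n2, group_size = g2))$tier
    expect_lte(t1, t2)
  }
})

test_that("tier_table matches record-wise assignment", {
  keys <- sprintf("1:%d:A:G", 1:4)
  ann <- annotation_for(keys, gene = c("A", "B", "C", "D"),
                        inheritance = c("AR", "AR", "XL", "AR"))
  rec <- data.frame(ancestry = "p", variant_key = keys,
                    n_carriers = c(6L, 3L, 0L, 1L),
                    n_homozygous = 0L,
                    group_size = c(300L, 500L, 400L, 90L),
                    frequency = c(6 / 300, 3 / 500, 0, 1 / 90),
                    one_in_n = NA_character_, stringsAsFactors = FALSE)
  tt <- tier_table(rec, ann, tier1_genes = "D")
  expect_equal(tt$tier, c(2L, 3L, 3L, 1L))
  expect_equal(tt$tier_basis,
               c("frequency", "frequency", "x_linked", "tier1_list"))
})
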