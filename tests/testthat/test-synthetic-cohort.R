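test_that("the generator is deterministic in the seed and seeds differ", {
  a <- small_sim(21)
  b <- small_sim(21)
  c <- small_sim(22)
  expect_identical(as.data.frame(a$genotypes), as.data.frame(b$genotypes))
  expect_identical(as.data.frame(a$variants), as.data.frame(b$variants))
  expect_identical(a$truth$group, b$truth$group)
  expect_false(identical(as.data.frame(a$genotypes),
                         as.data.frame(c$genotypes)))
})

test_that("generated artifacts pass every reader validation and round-trip through files", {
  sim <- simulate_cohort(sim_config(seed = 8, n_samples = 50,
                                    genes = synthetic_gene_panel(3, 4, 3),
                                    n_duplicates = 3, n_metric_fail = 2,
                                    n_sex_discordant = 1))
  dir <- withr::local_tempdir()
  write_genotype_matrix(sim$genotypes, file.path(dir, "g.tsv"))
  readr::write_tsv(sim$variants, file.path(dir, "v.tsv"), na = "NA")
  write_gene_panel(sim$panel, file.path(dir, "p.tsv"))
  readr::write_tsv(sim$samples, file.path(dir, "s.tsv"), na = "NA")
  expect_identical(as.data.frame(read_genotype_matrix(file.path(dir, "g.tsv"))),
                   as.data.frame(sim$genotypes))
  expect_identical(as.data.frame(read_variant_table(file.path(dir, "v.tsv"))),
                   as.data.frame(sim$variants))
  expect_identical(as.data.frame(read_gene_panel(file.path(dir, "p.tsv"))),
                   as.data.frame(sim$panel))
  expect_identical(as.data.frame(read_sample_table(file.path(dir, "s.tsv"))),
                   as.data.frame(sim$samples))
})

test_that("carrier counts are reproducible per seed and zero frequency yields an all-group-1 cohort", {
  genes <- synthetic_gene_panel(1, 0, 1)
  cfg <- sim_config(seed = 4, n_samples = 100, genes = genes,
                    carrier_freq = 0.05, n_duplicates = 0,
                    n_metric_fail = 0, n_sex_discordant = 0,
                    missing_rate = 0)
  n1 <- sum(simulate_cohort(cfg)$genotypes[[2]] > 0)
  n2 <- sum(simulate_cohort(cfg)$genotypes[[2]] > 0)
  expect_identical(n1, n2)
  expect_gt(n1, 0)
  expect_lt(n1, 20)  # ~Binomial(100, 0.05)

  cfg0 <- sim_config(seed = 4, n_samples = 50, genes = genes,
                     carrier_freq = 0, n_duplicates = 0,
                     n_metric_fail = 0, n_sex_discordant = 0)
  sim0 <- simulate_cohort(cfg0)
  expect_true(all(sim0$truth$group == 1L))
  expect_true(all(sim0$genotypes[[2]] %in% c(0L, NA_integer_)))
})

test_that("marginal carrier frequencies match the configured rates over an ensemble", {
  genes <- synthetic_gene_panel(2, 0, 1)
  freq <- c(0.03, 0.10)
  counts <- matrix(0, nrow = 200, ncol = 2)
  for (r in 1:200) {
    sim <- simulate_cohort(sim_config(seed = 1000 + r, n_samples = 50,
                                      genes = genes, carrier_freq = freq,
                                      n_duplicates = 0, n_metric_fail = 0,
                                      n_sex_discordant = 0, missing_rate = 0))
    counts[r, ] <- colSums(as.matrix(sim$genotypes[, -1]) > 0)
  }
  for (j in 1:2) {
    se <- sqrt(freq[j] * (1 - freq[j]) / (50 * 200))
    expect_lt(abs(mean(counts[, j]) / 50 - freq[j]), 3 * se)
  }
})

test_that("duplicate simulation perturbs calls at the configured rate and is exact at zero", {
  base <- small_sim(6, n_samples = 30)
  cfg0 <- sim_config(seed = 6, n_samples = 30,
                     genes = synthetic_gene_panel(3, 5, 3),
                     n_duplicates = 5, dup_discordance = 0)
  dup <- simulate_duplicates(base$genotypes, cfg0)
  expect_equal(nrow(dup$genotypes), 35)
  dc <- duplicate_concordance(dup$genotypes, dup$pairs)
  expect_true(all(dc$overall == 1))

  cfg_none <- sim_config(seed = 6, n_samples = 30,
                         genes = synthetic_gene_panel(3, 5, 3),
                         n_duplicates = 0)
  none <- simulate_duplicates(base$genotypes, cfg_none)
  expect_identical(as.data.frame(none$genotypes),
                   as.data.frame(base$genotypes))
  expect_equal(nrow(none$pairs), 0)

  expect_error(simulate_duplicates(
    base$genotypes[1:3, ],
    sim_config(seed = 1, n_samples = 30,
               genes = synthetic_gene_panel(3, 5, 3), n_duplicates = 5)))
  expect_error(sim_config(seed = 1, n_samples = 10,
                          genes = synthetic_gene_panel(2, 2, 2),
                          dup_discordance = 1.5))
})

test_that("adding duplicates does not perturb the genotype draws (stream isolation)", {
  mk <- function(nd) simulate_cohort(sim_config(
    seed = 17, n_samples = 40, genes = synthetic_gene_panel(3, 5, 3),
    n_duplicates = nd, n_metric_fail = 0, n_sex_discordant = 0,
    missing_rate = 0))
  with_dups <- mk(4)
  without <- mk(0)
  expect_identical(
    as.data.frame(with_dups$genotypes[1:40, ]),
    as.data.frame(without$genotypes))
})

test_that("a planted pair enriches joint carriage and an infeasible multiplier is capped with a warning", {
  marg <- setNames(rep(0.2, 4), c("A", "B", "C", "D"))
  m <- simulate_gene_loads(2000, marg,
                           planted = list(gene_a = "A", gene_b = "B",
                                          joint_multiplier = 4),
                           seed = 12)
  joint_ab <- mean(m[, "A"] & m[, "B"])
  joint_cd <- mean(m[, "C"] & m[, "D"])
  expect_gt(joint_ab, 3 * 0.04)  # target 0.16 vs independence 0.04
  expect_lt(joint_cd, 0.07)
  # marginals are preserved under planting
  expect_lt(abs(mean(m[, "A"]) - 0.2), 0.03)

  expect_warning(
    simulate_gene_loads(100, marg,
                        planted = list(gene_a = "A", gene_b = "B",
                                       joint_multiplier = 100),
                        seed = 1),
    "capped")

  expect_warning(
    simulate_cohort(sim_config(
      seed = 2, n_samples = 50, genes = synthetic_gene_panel(2, 2, 2),
      carrier_freq = rep(0.2, 8), n_duplicates = 0, n_metric_fail = 0,
      n_sex_discordant = 0,
      planted_pair = list(gene_a = "OBG001", gene_b = "OBG002",
                          joint_multiplier = 1000))),
    "capped")
})

test_that("a multiplier of one leaves the planted pair independent (calibration)", {
  # chi-square p-values over replicates should be roughly uniform; test a
  # coarse consequence: rejection at 0.05 happens at about the nominal rate
  marg <- setNames(c(0.3, 0.3), c("A", "B"))
  pvals <- vapply(1:300, function(r) {
    m <- simulate_gene_loads(200, marg,
                             planted = list(gene_a = "A", gene_b = "B",
                                            joint_multiplier = 1),
                             seed = r)
    suppressWarnings(stats::chisq.test(table(m[, "A"], m[, "B"]))$p.value)
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(mean(pvals), 0.35)  # not degenerate
})

test_that("planted QC defects are recovered by the QC ledger", {
  sim <- simulate_cohort(sim_config(seed = 30, n_samples = 120,
                                    genes = synthetic_gene_panel(2, 2, 2),
                                    n_duplicates = 6, n_metric_fail = 7,
                                    n_sex_discordant = 3))
  rep <- qc_filter_samples(sim$samples)
  expect_equal(rep$n_input, 126)
  expect_equal(rep$n_fail_metrics, 7)
  expect_equal(rep$n_duplicates_removed, 6)
  expect_equal(rep$n_sex_discordant, 3)
  expect_equal(rep$n_retained, 126 - 16)
  r <- tidy(rep)
  expect_setequal(r$sample_id[r$reason == "qc_metrics"],
                  sim$truth$metric_fail_ids)
  expect_setequal(r$sample_id[r$reason == "sex_discordant"],
                  sim$truth$sex_discordant_ids)
  expect_setequal(r$sample_id[r$reason == "qc_duplicate"],
                  sim$truth$dup_pairs$duplicate)
})
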