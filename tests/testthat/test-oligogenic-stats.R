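test_that("the Wald interval reproduces the printed formula and clamps at the boundaries", {
  # 15 carriers in 1,714 samples prints as 0.88%
  est <- proportion_ci(15, 1714)
  expect_equal(round(100 * est$p, 2), 0.88)
  # 45 / 1,714 prints as 2.6%
  expect_equal(round(100 * proportion_ci(45, 1714)$p, 1), 2.6)

  est <- proportion_ci(50, 100)
  expect_equal(est$ci_low, 0.5 - 1.96 * 0.05)
  expect_equal(est$ci_high, 0.5 + 1.96 * 0.05)

  est <- proportion_ci(0, 100)  # degenerate at p = 0
  expect_equal(c(est$p, est$ci_low, est$ci_high), c(0, 0, 0))

  est <- proportion_ci(99, 100)
  expect_lte(est$ci_high, 1)
  expect_error(proportion_ci(5, 0))
  expect_error(proportion_ci(6, 5))
})

test_that("fisher_exact matches spot values and handles degenerate tables", {
  expect_equal(fisher_exact(1, 2, 1, 2), 1)
  expect_equal(fisher_exact(2, 10, 8, 10), 4252 / 184756, tolerance = 1e-10)
  expect_equal(fisher_exact(0, 5, 5, 5), 2 / 252, tolerance = 1e-10)
  expect_error(fisher_exact(0, 0, 0, 0))
})

test_that("fisher_exact equals hypergeometric enumeration on all tables with total <= 30", {
  tables <- list()
  for (a in 0:15) for (b in 0:15) for (c in 0:15) for (d in 0:15) {
    t <- a + b + c + d
    if (t >= 2 && t <= 30 && a + b >= 1 && c + d >= 1) {
      tables[[length(tables) + 1]] <- c(a, b, c, d)
    }
  }
  tab <- do.call(rbind, tables)
  # subsample deterministically for speed, always keeping the small tables
  keep <- unique(c(which(rowSums(tab) <= 12),
                   seq(1, nrow(tab), by = 7)))
  tab <- tab[keep, , drop = FALSE]
  got <- fisher_exact(tab[, 1], tab[, 1] + tab[, 2],
                      tab[, 3], tab[, 3] + tab[, 4])
  want <- apply(tab, 1, function(r) fisher_oracle(r[1], r[2], r[3], r[4]))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("binomial_exact_test equals direct tail summation up to n = 10,000", {
  cases <- expand.grid(n = c(5, 50, 435, 2000, 10000),
                       p0 = c(1.25e-4, 0.013, 0.2, 1))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]
    p0 <- cases$p0[i]
    for (k in unique(c(0, 1, 2, round(n / 2), n))) {
      expect_equal(binomial_exact_test(k, n, p0), binom_tail_oracle(k, n, p0),
                   tolerance = 1e-12, info = sprintf("k=%d n=%d p0=%g", k, n, p0))
    }
  }
  # spot values: k = 0 is the full tail; p0 = 1 is certain success
  expect_equal(binomial_exact_test(0, 100, 0.3), 1)
  expect_equal(binomial_exact_test(7, 10, 1), 1)
  # same order as a 2-in-435 double-carrier observation at p0 = 1.25e-4
  expect_equal(binomial_exact_test(2, 435, 1.25e-4), 0.001422764,
               tolerance = 1e-6)
  # complement identity upper(k) = 1 - lower(k-1)
  for (k in c(1, 5, 17)) {
    expect_equal(binomial_exact_test(k, 100, 0.1),
                 1 - pbinom(k - 1, 100, 0.1), tolerance = 1e-12)
  }
  # two-sided option agrees with the central exact test
  expect_equal(binomial_exact_test(8, 20, 0.2, alternative = "two.sided"),
               binom.test(8, 20, 0.2)$p.value)
})

test_that("bh_fdr matches the hand step-up recursion, including ties and long random lists", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(0.05, 0.05)), c(0.05, 0.05))
  set.seed(99)
  for (m in c(2, 17, 1000)) {
    p <- runif(m)^2
    got <- bh_fdr(p)
    expect_equal(got, bh_oracle(p), tolerance = 1e-12)
    # monotone along the sorted raw order and never below raw p
    ord <- order(p)
    expect_true(all(diff(got[ord]) >= -1e-15))
    expect_true(all(got >= p - 1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("expected pair probability is the product of marginals, bounded by the smaller", {
  expect_equal(pair_expected_probability(0, 0.7), 0)
  expect_equal(pair_expected_probability(1, 1), 1)
  expect_equal(pair_expected_probability(4 / 438, 6 / 438), 1.251016e-4,
               tolerance = 1e-6)
  set.seed(3)
  pa <- runif(50)
  pb <- runif(50)
  expect_true(all(pair_expected_probability(pa, pb) <= pmin(pa, pb) + 1e-15))
  expect_equal(pair_expected_probability(0.3, 1), 0.3)
})

test_that("multi-gene carriage uses the capped load, never counting same-gene variants twice", {
  profiles <- profiles_from_loads(rbind(
    c(1L, 0L, 0L),   # 3 variants in one gene would still be this row
    c(1L, 1L, 0L),
    c(0L, 0L, 1L),
    c(1L, 1L, 1L)
  ) |> `colnames<-`(c("A", "B", "C")))
  est <- multi_gene_proportion(profiles)
  expect_equal(est$k, 2L)
  expect_equal(est$n, 4L)
  expect_equal(est$p, 0.5)

  # a sample with several qualifying variants all in one gene is not multi-gene
  v <- dplyr::bind_rows(
    make_variant("v1", gene = "DOM", cadd_phred = 20),
    make_variant("v2", gene = "DOM", cadd_phred = 22),
    make_variant("v3", gene = "DOM", cadd_phred = 25)
  )
  p <- make_panel("DOM", "dominant")
  g <- tibble::tibble(sample_id = c("a", "b"),
                      v1 = c(1L, 1L), v2 = c(1L, 0L), v3 = c(1L, 0L))
  prof <- classify_carriers(g, v, p)
  expect_true(all(prof$group == 3L))
  expect_equal(multi_gene_proportion(prof)$k, 0L)
  expect_error(multi_gene_proportion(prof[prof$group == 1, ]), "group-3")
})

test_that("gene-pair tests report observed vs expected joint carriage with a separate FDR family", {
  loads <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 0L), c(1L, 0L, 0L))
  colnames(loads) <- c("A", "B", "C")
  res <- test_gene_pairs(profiles_from_loads(loads))
  expect_identical(res$gene_a, c("A", "A", "B"))
  expect_identical(res$gene_b, c("B", "C", "C"))
  ab <- res[res$gene_a == "A" & res$gene_b == "B", ]
  expect_equal(ab$k_obs, 2L)
  expect_equal(ab$p_expected, (3 / 4) * (3 / 4))
  expect_equal(ab$p_value,
               binom_tail_oracle(2, 4, 9 / 16), tolerance = 1e-12)
  expect_equal(res$fdr_q, bh_oracle(res$p_value), tolerance = 1e-12)
})

test_that("carrier-sharing edges enumerate all pairs per sample with multiplicities", {
  loads <- rbind(
    c(1L, 1L, 1L, 1L),  # C(4,2) = 6 edges from this sample
    c(0L, 1L, 1L, 0L),
    c(0L, 1L, 1L, 0L),
    c(1L, 0L, 0L, 0L)   # single-gene carrier: no edges
  )
  colnames(loads) <- c("SLC35D3", "PTEN", "DYRK1B", "MCHR1")
  edges <- gene_pair_edges(profiles_from_loads(loads))
  expect_equal(sum(edges$n_participants), 6 + 1 + 1)
  pten_dyrk <- edges$n_participants[edges$gene_a == "DYRK1B" &
                                      edges$gene_b == "PTEN"]
  expect_equal(pten_dyrk, 3L)
  expect_true(all(edges$gene_a < edges$gene_b))

  none <- gene_pair_edges(profiles_from_loads(
    matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(NULL, c("A", "B")))))
  expect_equal(nrow(none), 0)
})

test_that("cohort comparison wraps per-row Fisher tests with one FDR family", {
  comp <- tibble::tibble(label = c("g3_ext", "g3_nhs"),
                         k1 = c(463, 147), n1 = c(1714, 1714),
                         k2 = c(437, 130), n2 = c(1714, 1714))
  res <- compare_cohorts(comp)
  expect_equal(res$fisher_p,
               c(fisher_oracle(463, 1714 - 463, 437, 1714 - 437),
                 fisher_oracle(147, 1714 - 147, 130, 1714 - 130)),
               tolerance = 1e-9)
  expect_equal(res$fdr_q, bh_oracle(res$fisher_p), tolerance = 1e-12)
})
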