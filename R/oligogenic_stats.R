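#' Wald 95% confidence interval for a proportion
#'
#' The error-bar formula `p +/- 1.96 * sqrt(p(1-p)/n)`, with bounds clamped
#' to \[0, 1\]. This is the plain Wald interval, chosen deliberately over
#' Wilson or Clopper-Pearson so that plotted error bars match the formula
#' exactly; it degenerates to a zero-width interval at p = 0 or 1.
#' Vectorised over `k` (and `n`).
#'
#' @param k Number of carriers (successes), `0 <= k <= n`.
#' @param n Denominator, `>= 1`.
#' @return A tibble with columns `k`, `n`, `p`, `ci_low`, `ci_high`.
#' @examples
#' proportion_ci(15, 1714)  # 0.88% of the cohort
#' @export
proportion_ci <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n >= 1),
            all(k >= 0), all(k <= n))
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  tibble(k = as.integer(k), n = as.integer(n), p = p,
         ci_low = pmax(0, p - half), ci_high = pmin(1, p + half))
}

#' Two-sided Fisher's exact test for two carrier proportions
#'
#' Exact test on the 2x2 table `[[k1, n1-k1], [k2, n2-k2]]`, two-sided by
#' the probability-mass convention (summing hypergeometric outcomes no more
#' probable than the observed table), as implemented by
#' [stats::fisher.test()]. Vectorised over its arguments.
#'
#' @param k1,n1 Carriers and total in the first cohort.
#' @param k2,n2 Carriers and total in the second cohort.
#' @return Numeric vector of two-sided p-values.
#' @export
fisher_exact <- function(k1, n1, k2, n2) {
  stopifnot(all(k1 >= 0), all(k2 >= 0), all(n1 >= 1), all(n2 >= 1),
            all(k1 <= n1), all(k2 <= n2))
  mapply(function(k1, n1, k2, n2) {
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
    if (all(tab == 0)) abort("degenerate 2x2 table: all cells zero")
    stats::fisher.test(tab)$p.value
  }, k1, n1, k2, n2)
}

#' Compare carrier proportions between two cohorts
#'
#' One Fisher's exact test per row, with Benjamini-Hochberg adjustment
#' across the whole table (one family per call, the usual layout for a
#' per-variant or per-gene comparison table).
#'
#' @param comparisons Tibble with columns `label`, `k1`, `n1`, `k2`, `n2`.
#' @param fdr Adjust across rows with [bh_fdr()] (default `TRUE`).
#' @return The input with added `p1`, `p2`, `fisher_p` and (when requested)
#'   `fdr_q`.
#' @export
compare_cohorts <- function(comparisons, fdr = TRUE) {
  stopifnot(all(c("label", "k1", "n1", "k2", "n2") %in% names(comparisons)))
  out <- as_tibble(comparisons) |>
    mutate(
      p1 = .data$k1 / .data$n1,
      p2 = .data$k2 / .data$n2,
      fisher_p = fisher_exact(.data$k1, .data$n1, .data$k2, .data$n2)
    )
  if (isTRUE(fdr)) out$fdr_q <- bh_fdr(out$fisher_p)
  out
}

#' Proportion of multi-gene carriers among MOI-consistent samples
#'
#' Among group-3 samples, the fraction carrying qualifying variants in two
#' or more distinct genes — the oligogenic-carriage summary. Because
#' per-gene load is capped at 1, several variants in one gene never count
#' as multi-gene carriage.
#'
#' @param profiles A `carrier_profiles` tibble ([classify_carriers()]);
#'   rows with `group != 3` are ignored.
#' @return A one-row [proportion_ci()] tibble with `n` = number of group-3
#'   samples.
#' @export
multi_gene_proportion <- function(profiles) {
  stopifnot(all(c("group", "n_genes_loaded") %in% names(profiles)))
  g3 <- profiles[profiles$group == 3L, , drop = FALSE]
  if (nrow(g3) == 0) abort("no group-3 samples: multi-gene proportion undefined")
  proportion_ci(sum(g3$n_genes_loaded >= 2L), nrow(g3))
}

#' Expected probability of joint carriage in a gene pair
#'
#' Under independence, the probability that one individual carries at least
#' one qualifying variant in each gene of a pair is the product of the two
#' marginal carriage proportions. By construction the product never exceeds
#' the smaller marginal.
#'
#' @param marginal_a,marginal_b Carriage proportions in \[0, 1\].
#' @return `marginal_a * marginal_b`, vectorised.
#' @export
pair_expected_probability <- function(marginal_a, marginal_b) {
  stopifnot(all(marginal_a >= 0 & marginal_a <= 1),
            all(marginal_b >= 0 & marginal_b <= 1))
  marginal_a * marginal_b
}

#' Exact binomial test for observed vs expected joint carriage
#'
#' Tests whether the observed number of double carriers differs from the
#' count expected under independence. The default alternative is
#' enrichment (upper tail, `sum_(j >= k) C(n,j) p0^j (1-p0)^(n-j)`), since
#' excess co-occurrence is the hypothesis of interest; for rare `p0` well
#' below the observed proportion the two-sided value coincides with it to
#' reported precision. Vectorised for `alternative = "greater"`.
#'
#' @param k_obs Observed double-carrier count, `0 <= k_obs <= n`.
#' @param n Number of samples tested.
#' @param p0 Null joint-carriage probability (product of marginals).
#' @param alternative `"greater"` (default) or `"two.sided"` (the central
#'   method of [stats::binom.test()]).
#' @return p-value(s) in (0, 1].
#' @export
binomial_exact_test <- function(k_obs, n, p0,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(all(k_obs >= 0), all(k_obs <= n), all(p0 >= 0), all(p0 <= 1))
  if (alternative == "greater") {
    pbinom(k_obs - 1, n, p0, lower.tail = FALSE)
  } else {
    mapply(function(k, n, p) binom.test(k, n, p)$p.value, k_obs, n, p0)
  }
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): sorted p-values are
#' scaled by `m / rank` and monotonised from the largest down, clamped at
#' 1, with the input order restored.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-pair co-occurrence tests over a carrier cohort
#'
#' For every pair of genes carried by at least one group-3 sample each,
#' compares the observed proportion of double carriers against the
#' product-of-marginals expectation with [binomial_exact_test()].
#' Benjamini-Hochberg adjustment is computed across the full pair grid as
#' its own family (`fdr_q`); the unadjusted `p_value` is always reported
#' alongside it.
#'
#' @param profiles A `carrier_profiles` tibble; only `group == 3` rows
#'   enter, matching the definition of the co-occurrence analysis.
#' @param alternative Passed to [binomial_exact_test()].
#' @param fdr Compute `fdr_q` across the pair grid (default `TRUE`).
#' @return A tibble of class `gene_pair_tests`: `gene_a`, `gene_b`
#'   (lexicographic, `gene_a < gene_b`), `k_obs`, `n`, `p_obs`,
#'   `p_expected`, `p_value`, `fdr_q`.
#' @export
test_gene_pairs <- function(profiles, alternative = "greater", fdr = TRUE) {
  loads <- load_matrix(profiles)
  n <- nrow(loads)
  if (n == 0) abort("no group-3 samples: pair tests undefined")
  marg <- colMeans(loads)
  genes <- sort(colnames(loads)[marg > 0])
  if (length(genes) < 2) {
    out <- tibble(gene_a = character(), gene_b = character(),
                  k_obs = integer(), n = integer(), p_obs = numeric(),
                  p_expected = numeric(), p_value = numeric(),
                  fdr_q = numeric())
    class(out) <- c("gene_pair_tests", class(out))
    return(out)
  }
  joint <- crossprod(loads[, genes, drop = FALSE])
  pairs <- t(utils::combn(genes, 2))
  k_obs <- joint[pairs]
  out <- tibble(
    gene_a = pairs[, 1], gene_b = pairs[, 2],
    k_obs = as.integer(k_obs), n = n,
    p_obs = k_obs / n,
    p_expected = unname(pair_expected_probability(marg[pairs[, 1]],
                                                  marg[pairs[, 2]]))
  )
  out$p_value <- binomial_exact_test(out$k_obs, out$n, out$p_expected,
                                     alternative = alternative)
  out$fdr_q <- if (isTRUE(fdr)) bh_fdr(out$p_value) else NA_real_
  class(out) <- c("gene_pair_tests", class(out))
  out
}

# group-3 profiles -> samples x genes 0/1 load matrix
load_matrix <- function(profiles) {
  stopifnot(all(c("group", "loaded_genes") %in% names(profiles)))
  g3 <- profiles[profiles$group == 3L, , drop = FALSE]
  genes <- sort(unique(unlist(g3$loaded_genes)))
  m <- matrix(0L, nrow = nrow(g3), ncol = length(genes),
              dimnames = list(g3$sample_id, genes))
  for (i in seq_len(nrow(g3))) {
    m[i, match(g3$loaded_genes[[i]], genes)] <- 1L
  }
  m
}

#' Carrier-sharing edges between genes
#'
#' The network-plot summary: each group-3 sample loaded in `|G| >= 2` genes
#' contributes all `choose(|G|, 2)` unordered gene pairs, and an edge's
#' multiplicity is the number of contributing samples. Pairs are emitted in
#' canonical lexicographic order.
#'
#' @param profiles A `carrier_profiles` tibble; only group-3 rows
#'   contribute.
#' @return A tibble `gene_a`, `gene_b`, `n_participants`, sorted by
#'   decreasing multiplicity then gene pair.
#' @export
gene_pair_edges <- function(profiles) {
  stopifnot(all(c("group", "loaded_genes") %in% names(profiles)))
  g3 <- profiles[profiles$group == 3L, , drop = FALSE]
  multi <- g3$loaded_genes[vapply(g3$loaded_genes, length, integer(1)) >= 2]
  if (length(multi) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  n_participants = integer()))
  }
  edges <- purrr::map(multi, function(g) {
    pr <- t(utils::combn(sort(g), 2))
    tibble(gene_a = pr[, 1], gene_b = pr[, 2])
  })
  bind_rows(edges) |>
    count(.data$gene_a, .data$gene_b, name = "n_participants") |>
    arrange(dplyr::desc(.data$n_participants), .data$gene_a, .data$gene_b)
}
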