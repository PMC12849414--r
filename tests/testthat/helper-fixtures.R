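# In-code fixtures and independent oracles shared across the suite.

make_variant <- function(variant_id = "v1", chrom = "1", pos = 100L,
                         ref = "A", alt = "T", gene = "G1",
                         consequence = "missense", cadd_phred = 20,
                         sift = "damaging", polyphen = "probably_damaging",
                         loftee = NA_character_, maf = 0.001,
                         source = "gnomAD", gof_excluded = FALSE) {
  tibble::tibble(variant_id, chrom, pos = as.integer(pos), ref, alt, gene,
                 consequence, cadd_phred, sift, polyphen, loftee, maf,
                 source, gof_excluded)
}

make_panel <- function(genes, moi, nhs = rep(FALSE, length(genes))) {
  tibble::tibble(gene = genes, moi = moi, nhs_panel = nhs,
                 extended_panel = TRUE)
}

make_samples <- function(n, prefix = "S") {
  tibble::tibble(
    sample_id = sprintf("%s%04d", prefix, seq_len(n)),
    cohort = "test",
    reported_sex = rep_len(c("F", "M"), n),
    genetic_sex = rep_len(c("F", "M"), n),
    dqc = 0.95,
    duplicate_of = NA_character_,
    relatedness_flag = FALSE,
    het_outlier_flag = FALSE
  )
}

small_sim <- function(seed, n_samples = 40, n_nhs = 3, n_ext = 5,
                      n_var = 3, ...) {
  simulate_cohort(sim_config(
    seed = seed, n_samples = n_samples,
    genes = synthetic_gene_panel(n_nhs, n_ext, n_var),
    n_duplicates = 0, n_metric_fail = 0, n_sex_discordant = 0,
    missing_rate = 0, ...
  ))
}

# drop the reason-log attribute so filter outputs compare on content
strip_log <- function(x) {
  attr(x, "filter_reasons") <- NULL
  as.data.frame(x)
}

# --- independent oracles -----------------------------------------------------

# Two-sided Fisher p by full hypergeometric enumeration over the support,
# probability-mass convention (same relative tie tolerance as standard
# software).
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  x <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(x, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Upper-tail binomial p by direct summation of the mass function.
binom_tail_oracle <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p0))
}

# Benjamini-Hochberg by the hand step-up recursion: sort ascending, scale
# by m/rank, monotonise from the largest down, clamp, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

# Per-sample carrier grouping by direct enumeration over every variant,
# independent of the vectorised implementation.
oracle_groups <- function(geno, variants, panel, cadd_min = 15,
                          scope = "extended") {
  genes <- panel$gene[if (scope == "nhs") panel$nhs_panel
                      else panel$extended_panel]
  out <- integer(nrow(geno))
  for (i in seq_len(nrow(geno))) {
    any_q <- FALSE
    consistent <- FALSE
    for (v in names(geno)[-1]) {
      d <- geno[[v]][i]
      if (is.na(d) || d == 0L) next
      row <- variants[variants$variant_id == v, ]
      if (row$consequence == "intronic") next
      if (is.na(row$cadd_phred) || row$cadd_phred < cadd_min) next
      if (!is.na(row$loftee) && row$loftee == "LC") next
      if (!row$gene %in% genes) next
      any_q <- TRUE
      moi <- panel$moi[panel$gene == row$gene]
      if (moi == "dominant" && d >= 1L) consistent <- TRUE
      if (moi == "recessive" && d == 2L) consistent <- TRUE
    }
    out[i] <- if (!any_q) 1L else if (consistent) 3L else 2L
  }
  out
}

write_mini_vcf <- function(path, alt = "T", gt = "0/1") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    paste("1", "100", "v1", "A", alt, ".", "PASS", ".", "GT", gt, sep = "\t")
  ), path)
  path
}
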