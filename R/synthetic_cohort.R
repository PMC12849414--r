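# Seeded generator for schema-valid synthetic screening cohorts.
#
# One sub-stream of the RNG per artifact (variants, genotypes, defects,
# duplicates), derived from the single config seed, so that e.g. turning
# duplicates on or off never perturbs the genotype draws. The user's RNG
# state is saved and restored around every draw.

stream_offsets <- c(variants = 1000003, genotypes = 2000003,
                    defects = 3000017, duplicates = 4000037,
                    loads = 5000011)

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.numeric(seed) + stream_offsets[[stream]]) %% 2147483629)
  force(code)
}

#' A synthetic mode-of-inheritance gene panel
#'
#' Deterministic panel of invented gene symbols emulating a clinical
#' screening panel: a clinically used (NHS-style) core that is a subset of
#' a larger extended research panel, with alternating dominant/recessive
#' expected modes of inheritance. Defaults mirror the scale of a severe-
#' obesity screening panel: 27 core genes plus 51 extended-only genes, a
#' few probes-worth of rare variants per gene.
#'
#' @param n_nhs Number of core (clinical) genes.
#' @param n_extended_only Number of additional extended-panel genes.
#' @param n_variants_per_gene Variants simulated per gene (recycled).
#' @return A tibble `gene`, `moi`, `nhs_panel`, `extended_panel`,
#'   `n_variants`, usable directly as the `genes` field of [sim_config()].
#' @export
synthetic_gene_panel <- function(n_nhs = 27, n_extended_only = 51,
                                 n_variants_per_gene = 8) {
  n <- n_nhs + n_extended_only
  stopifnot(n >= 1)
  tibble(
    gene = sprintf("OBG%03d", seq_len(n)),
    moi = rep_len(c("dominant", "recessive"), n),
    nhs_panel = seq_len(n) <= n_nhs,
    extended_panel = TRUE,
    n_variants = rep_len(as.integer(n_variants_per_gene), n)
  )
}

#' Configuration for a synthetic screening cohort
#'
#' Collects every knob of the generator. The defaults emulate the scale of
#' a real array-screening study: ~1,700 samples, a 78-gene panel carrying
#' ~600 rare variants, per-variant carrier frequencies drawn log-uniformly
#' between the singleton frequency `1/(2 n_samples)` and 0.005 (so most
#' carried variants are singletons), 22 designated duplicate samples with a
#' 0.3% per-call discordance, 25 QC-metric failures and 5 sex-discordant
#' samples. Homozygous carriage at recessive genes is planted directly at
#' rate `hom_fraction` per carrier rather than via Hardy-Weinberg, because
#' rare-variant homozygote counts would otherwise be essentially zero at
#' this cohort size; this is a deliberate departure from population-
#' genetic realism so that MOI-consistent recessive carriage exists to
#' classify.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_samples Cohort size before QC defects.
#' @param genes Gene tibble as from [synthetic_gene_panel()].
#' @param carrier_freq Optional numeric vector (one per variant) of carrier
#'   frequencies; default drawn log-uniformly in `[1/(2 n_samples), 0.005]`.
#' @param hom_fraction Probability that a carrier at a recessive gene is
#'   homozygous (default 0.05).
#' @param cadd_mix Mixture for CADD-PHRED scores: list with `weight_high`,
#'   `mean_high`, `mean_low`, `sd` — two normal components truncated to
#'   \[0, 40\]; the default puts most mass above 20, as on a deleteriousness-
#'   selected array.
#' @param consequence_mix Named probabilities over consequence classes;
#'   default mostly missense with small frameshift/stop-gain/splice/intronic
#'   fractions.
#' @param planted_pair Optional list `(gene_a, gene_b, joint_multiplier)`:
#'   the two genes' joint carriage probability is the product of their
#'   marginals times the multiplier, capped at the smaller marginal (a
#'   warning is emitted when the cap binds).
#' @param missing_rate Per-call missingness probability.
#' @param n_duplicates Designated QC duplicate samples to append.
#' @param dup_discordance Per-call probability that a duplicate's call
#'   differs from its primary's.
#' @param n_sex_discordant,n_metric_fail Planted QC defects (disjoint
#'   sample sets).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 1714,
                       genes = synthetic_gene_panel(),
                       carrier_freq = NULL,
                       hom_fraction = 0.05,
                       cadd_mix = list(weight_high = 0.85, mean_high = 27,
                                       mean_low = 11, sd = 5),
                       consequence_mix = c(missense = 0.875,
                                           frameshift = 0.05,
                                           stop_gain = 0.03,
                                           splice = 0.02,
                                           intronic = 0.025),
                       planted_pair = NULL,
                       missing_rate = 0.001,
                       n_duplicates = 22,
                       dup_discordance = 0.003,
                       n_sex_discordant = 5,
                       n_metric_fail = 25) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            n_samples >= 1, is.data.frame(genes),
            all(c("gene", "moi", "nhs_panel", "n_variants") %in% names(genes)),
            hom_fraction >= 0, hom_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            dup_discordance >= 0, dup_discordance <= 1,
            n_duplicates >= 0, n_duplicates <= n_samples,
            n_sex_discordant + n_metric_fail <= n_samples)
  stopifnot(abs(sum(consequence_mix) - 1) < 1e-8,
            all(names(consequence_mix) %in% consequence_levels))
  if (!is.null(planted_pair)) {
    stopifnot(all(c("gene_a", "gene_b", "joint_multiplier") %in%
                    names(planted_pair)),
              all(c(planted_pair$gene_a, planted_pair$gene_b) %in%
                    genes$gene),
              planted_pair$gene_a != planted_pair$gene_b)
  }
  structure(
    list(seed = seed, n_samples = as.integer(n_samples), genes = genes,
         carrier_freq = carrier_freq, hom_fraction = hom_fraction,
         cadd_mix = cadd_mix, consequence_mix = consequence_mix,
         planted_pair = planted_pair, missing_rate = missing_rate,
         n_duplicates = as.integer(n_duplicates),
         dup_discordance = dup_discordance,
         n_sex_discordant = as.integer(n_sex_discordant),
         n_metric_fail = as.integer(n_metric_fail)),
    class = "sim_config"
  )
}

#' Simulate a complete screening cohort
#'
#' Generates a schema-valid set of the four input artifacts — genotype
#' matrix, variant annotation table, gene panel, sample metadata — plus a
#' truth record of everything that was planted, for recovery tests.
#' Deterministic given the config seed; per-variant carriers are drawn
#' independently at their carrier frequency except a planted gene pair,
#' whose joint carriage is enriched as configured.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes`, `variants`, `panel`,
#'   `samples`, `dup_pairs` and `truth`. `truth` records per-variant
#'   carrier frequencies, the pre-missingness carrier list, each original
#'   sample's carrier group at the default threshold (CADD-PHRED 15,
#'   extended scope), the planted pair with its realised joint probability,
#'   the planted QC-defect sample ids and the duplicate pairs.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  genes <- config$genes
  variants <- with_stream(config$seed, "variants",
                          simulate_variant_table(config))
  geno_mat <- with_stream(config$seed, "genotypes",
                          simulate_dosages(config, variants))
  sample_ids <- sprintf("S%05d", seq_len(n))
  rownames(geno_mat$dosage) <- sample_ids

  # truth groups from the pre-missingness calls at the default threshold
  truth_group <- truth_groups(geno_mat$dosage, variants, genes)

  dosage <- geno_mat$dosage
  if (config$missing_rate > 0) {
    dosage[geno_mat$missing_mask] <- NA_integer_
  }
  geno <- bind_cols(tibble(sample_id = sample_ids),
                    as_tibble(as.data.frame(dosage)))

  samples <- with_stream(config$seed, "defects",
                         simulate_samples(config, sample_ids))
  metric_fail_ids <- attr(samples, "metric_fail_ids")
  sex_discordant_ids <- attr(samples, "sex_discordant_ids")
  attr(samples, "metric_fail_ids") <- NULL
  attr(samples, "sex_discordant_ids") <- NULL

  dup_pairs <- tibble(primary = character(), duplicate = character())
  if (config$n_duplicates > 0) {
    dup <- simulate_duplicates(geno, config)
    geno <- dup$genotypes
    dup_pairs <- dup$pairs
    samples <- bind_rows(
      samples,
      tibble(sample_id = dup_pairs$duplicate, cohort = samples$cohort[1],
             reported_sex = samples$reported_sex[
               match(dup_pairs$primary, samples$sample_id)],
             # QC copies are removed as duplicates; keep them sex-concordant
             # so planted sex-discordance counts stay exactly as configured
             genetic_sex = samples$reported_sex[
               match(dup_pairs$primary, samples$sample_id)],
             dqc = 0.95, duplicate_of = dup_pairs$primary,
             relatedness_flag = FALSE, het_outlier_flag = FALSE)
    )
  }

  panel <- genes |>
    select("gene", "moi", "nhs_panel", "extended_panel") |>
    validate_gene_panel()

  list(
    genotypes = validate_genotypes(geno),
    variants = validate_variants(variants[, variant_columns]),
    panel = panel,
    samples = validate_samples(samples),
    dup_pairs = dup_pairs,
    truth = list(
      carrier_freq = setNames(variants$carrier_freq, variants$variant_id),
      carriers = geno_mat$carriers,
      group = truth_group,
      planted_pair = geno_mat$planted,
      metric_fail_ids = metric_fail_ids,
      sex_discordant_ids = sex_discordant_ids,
      dup_pairs = dup_pairs
    )
  )
}

simulate_variant_table <- function(config) {
  genes <- config$genes
  n_var <- sum(genes$n_variants)
  gene_of <- rep(genes$gene, genes$n_variants)
  moi_of <- rep(genes$moi, genes$n_variants)
  mix <- config$cadd_mix
  high <- runif(n_var) < mix$weight_high
  cadd <- ifelse(high, rnorm(n_var, mix$mean_high, mix$sd),
                 rnorm(n_var, mix$mean_low, mix$sd))
  cadd <- round(pmin(40, pmax(0, cadd)), 2)
  consequence <- sample(names(config$consequence_mix), n_var, replace = TRUE,
                        prob = config$consequence_mix)
  freq <- config$carrier_freq
  if (is.null(freq)) {
    # log-uniform between the singleton carrier frequency and 0.5%; in tiny
    # test cohorts the singleton frequency can exceed 0.5%, so sort bounds
    bounds <- sort(log10(c(1 / (2 * config$n_samples), 0.005)))
    freq <- 10^runif(n_var, min = bounds[1], max = bounds[2])
  }
  stopifnot(length(freq) == n_var)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  lof <- consequence %in% c("frameshift", "stop_gain", "splice")
  loftee <- rep(NA_character_, n_var)
  loftee[lof] <- ifelse(runif(sum(lof)) < 0.93, "HC", "LC")
  tibble(
    variant_id = sprintf("sv%05d", seq_len(n_var)),
    chrom = as.character(((match(gene_of, genes$gene) - 1) %% 22) + 1),
    pos = 1000L + 50L * seq_len(n_var),
    ref = ref, alt = unname(alt),
    gene = gene_of,
    consequence = consequence,
    cadd_phred = cadd,
    sift = sample(sift_levels, n_var, replace = TRUE, prob = c(0.7, 0.3)),
    polyphen = sample(polyphen_levels, n_var, replace = TRUE,
                      prob = c(0.6, 0.2, 0.2)),
    loftee = loftee,
    maf = freq / 2,
    source = sample(source_levels, n_var, replace = TRUE,
                    prob = c(0.08, 0.9, 0.02)),
    gof_excluded = FALSE,
    carrier_freq = freq,
    moi = moi_of
  )
}

simulate_dosages <- function(config, variants) {
  n <- config$n_samples
  n_var <- nrow(variants)
  dosage <- matrix(0L, nrow = n, ncol = n_var,
                   dimnames = list(NULL, variants$variant_id))
  planted_genes <- character()
  planted <- NULL
  if (!is.null(config$planted_pair)) {
    pp <- config$planted_pair
    planted_genes <- c(pp$gene_a, pp$gene_b)
    idx_a <- which(variants$gene == pp$gene_a)
    idx_b <- which(variants$gene == pp$gene_b)
    p_a <- 1 - prod(1 - variants$carrier_freq[idx_a])
    p_b <- 1 - prod(1 - variants$carrier_freq[idx_b])
    joint <- pp$joint_multiplier * p_a * p_b
    if (joint > min(p_a, p_b)) {
      warn("planted joint carriage exceeds a marginal; capped at the smaller marginal")
      joint <- min(p_a, p_b)
    }
    cells <- c(joint, p_a - joint, p_b - joint, 1 - p_a - p_b + joint)
    draw <- sample(c("ab", "a", "b", "none"), n, replace = TRUE, prob = cells)
    for (g in c("a", "b")) {
      idx <- if (g == "a") idx_a else idx_b
      carrier <- draw == "ab" | draw == g
      pick <- idx[sample.int(length(idx), sum(carrier), replace = TRUE,
                             prob = variants$carrier_freq[idx])]
      dosage[cbind(which(carrier), pick)] <- 1L
    }
    planted <- list(gene_a = pp$gene_a, gene_b = pp$gene_b,
                    joint_multiplier = pp$joint_multiplier,
                    marginal_a = p_a, marginal_b = p_b, joint_prob = joint)
  }
  indep <- which(!variants$gene %in% planted_genes)
  for (j in indep) {
    carriers <- which(runif(n) < variants$carrier_freq[j])
    if (length(carriers) > 0) dosage[carriers, j] <- 1L
  }
  # homozygous carriage at recessive genes, planted per carrier
  rec <- which(variants$moi == "recessive")
  if (config$hom_fraction > 0 && length(rec) > 0) {
    for (j in rec) {
      carriers <- which(dosage[, j] == 1L)
      if (length(carriers) > 0) {
        hom <- carriers[runif(length(carriers)) < config$hom_fraction]
        dosage[hom, j] <- 2L
      }
    }
  }
  missing_mask <- matrix(runif(n * n_var) < config$missing_rate,
                         nrow = n, ncol = n_var)
  carriers_long <- which(dosage > 0L, arr.ind = TRUE)
  carriers <- tibble(
    sample = carriers_long[, 1],
    variant_id = variants$variant_id[carriers_long[, 2]],
    dosage = dosage[carriers_long]
  )
  list(dosage = dosage, missing_mask = missing_mask,
       carriers = carriers, planted = planted)
}

# group labels from pre-missingness dosages: analysis filter at CADD 15,
# extended scope, capped load, MOI-consistency rule
truth_groups <- function(dosage, variants, genes) {
  keep <- variants$consequence != "intronic" &
    !is.na(variants$cadd_phred) & variants$cadd_phred >= 15 &
    (is.na(variants$loftee) | variants$loftee != "LC")
  d <- dosage[, keep, drop = FALSE]
  moi <- variants$moi[keep]
  any_carried <- rowSums(d > 0L) > 0L
  consistent <- rowSums(
    sweep(d > 0L, 2, moi == "dominant", "&") |
      sweep(d == 2L, 2, moi == "recessive", "&")
  ) > 0L
  out <- ifelse(!any_carried, 1L, ifelse(consistent, 3L, 2L))
  setNames(as.integer(out), rownames(dosage))
}

simulate_samples <- function(config, sample_ids) {
  n <- length(sample_ids)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.7, 0.3))
  dqc <- runif(n, 0.9, 1)
  defect_idx <- sample.int(n, config$n_metric_fail + config$n_sex_discordant)
  metric_idx <- head(defect_idx, config$n_metric_fail)
  sex_idx <- setdiff(defect_idx, metric_idx)
  dqc[metric_idx] <- runif(length(metric_idx), 0.5, 0.81)
  genetic_sex <- sex
  genetic_sex[sex_idx] <- ifelse(sex[sex_idx] == "F", "M", "F")
  out <- tibble(
    sample_id = sample_ids, cohort = "synthetic",
    reported_sex = sex, genetic_sex = genetic_sex, dqc = dqc,
    duplicate_of = NA_character_,
    relatedness_flag = FALSE, het_outlier_flag = FALSE
  )
  attr(out, "metric_fail_ids") <- sample_ids[metric_idx]
  attr(out, "sex_discordant_ids") <- sample_ids[sex_idx]
  out
}

#' Append designated QC duplicate samples
#'
#' Copies `n_duplicates` randomly chosen samples onto the end of the
#' genotype matrix under new ids, perturbing each non-missing call
#' independently with probability `dup_discordance` (a perturbed call is
#' resampled uniformly from the other two codes). The expected pairwise
#' concordance measured by [pairwise_concordance()] is therefore
#' `1 - dup_discordance`.
#'
#' @param geno Genotype tibble.
#' @param config A [sim_config()]; uses `seed`, `n_duplicates`,
#'   `dup_discordance`.
#' @return A list: `genotypes` (augmented tibble) and `pairs` (tibble
#'   `primary`, `duplicate`).
#' @export
simulate_duplicates <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- validate_genotypes(geno)
  if (config$n_duplicates == 0) {
    return(list(genotypes = geno,
                pairs = tibble(primary = character(), duplicate = character())))
  }
  stopifnot(config$n_duplicates <= nrow(geno))
  with_stream(config$seed, "duplicates", {
    primaries <- sort(sample.int(nrow(geno), config$n_duplicates))
    mat <- as.matrix(geno[primaries, -1, drop = FALSE])
    if (config$dup_discordance > 0 && length(mat) > 0) {
      flip <- !is.na(mat) & runif(length(mat)) < config$dup_discordance
      mat[flip] <- vapply(mat[flip],
                          function(g) sample(setdiff(0:2, g), 1L), integer(1))
    }
    pairs <- tibble(primary = geno$sample_id[primaries],
                    duplicate = paste0(geno$sample_id[primaries], "_dup"))
    dup_rows <- bind_cols(tibble(sample_id = pairs$duplicate),
                          as_tibble(as.data.frame(mat)))
    list(genotypes = bind_rows(geno, dup_rows), pairs = pairs)
  })
}

#' Simulate per-gene carrier loads directly
#'
#' A gene-level shortcut used for statistical calibration: a samples-by-
#' genes 0/1 load matrix with independent Bernoulli marginals, optionally
#' with one planted pair whose joint carriage probability is
#' `joint_multiplier` times the product of its marginals (capped at the
#' smaller marginal). This bypasses variants entirely and feeds
#' [test_gene_pairs()] via [profiles_from_loads()].
#'
#' @param n_samples Number of samples (rows).
#' @param marginals Named numeric vector of per-gene carriage
#'   probabilities.
#' @param planted Optional list `(gene_a, gene_b, joint_multiplier)`.
#' @param seed Integer seed.
#' @return An integer 0/1 matrix with gene column names.
#' @export
simulate_gene_loads <- function(n_samples, marginals, planted = NULL,
                                seed = 1) {
  stopifnot(!is.null(names(marginals)), all(marginals >= 0 & marginals <= 1))
  with_stream(seed, "loads", {
    m <- matrix(0L, nrow = n_samples, ncol = length(marginals),
                dimnames = list(NULL, names(marginals)))
    skip <- character()
    if (!is.null(planted)) {
      pa <- marginals[[planted$gene_a]]
      pb <- marginals[[planted$gene_b]]
      joint <- planted$joint_multiplier * pa * pb
      if (joint > min(pa, pb)) {
        warn("planted joint carriage exceeds a marginal; capped")
        joint <- min(pa, pb)
      }
      draw <- sample(c("ab", "a", "b", "none"), n_samples, replace = TRUE,
                     prob = c(joint, pa - joint, pb - joint,
                              1 - pa - pb + joint))
      m[draw %in% c("ab", "a"), planted$gene_a] <- 1L
      m[draw %in% c("ab", "b"), planted$gene_b] <- 1L
      skip <- c(planted$gene_a, planted$gene_b)
    }
    for (g in setdiff(names(marginals), skip)) {
      m[runif(n_samples) < marginals[[g]], g] <- 1L
    }
    m
  })
}

#' Wrap a load matrix as carrier profiles
#'
#' Presents a 0/1 samples-by-genes load matrix (e.g. from
#' [simulate_gene_loads()]) as a `carrier_profiles` tibble of group-3
#' samples, so the pair-test and edge operations can consume it.
#'
#' @param loads Integer 0/1 matrix with gene column names.
#' @return A `carrier_profiles` tibble, every sample labelled group 3.
#' @export
profiles_from_loads <- function(loads) {
  stopifnot(is.matrix(loads), !is.null(colnames(loads)))
  genes <- colnames(loads)
  out <- tibble(
    sample_id = rownames(loads) %||% sprintf("S%05d", seq_len(nrow(loads))),
    group = 3L,
    n_qualifying = as.integer(rowSums(loads)),
    n_genes_loaded = as.integer(rowSums(loads > 0)),
    loaded_genes = purrr::map(seq_len(nrow(loads)),
                              \(i) genes[loads[i, ] > 0]),
    consistent_genes = purrr::map(seq_len(nrow(loads)),
                                  \(i) genes[loads[i, ] > 0])
  )
  class(out) <- c("carrier_profiles", class(out))
  out
}
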