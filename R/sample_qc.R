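#' Apply the sample-exclusion ledger
#'
#' Evaluates the standard array-QC exclusion criteria in a fixed order:
#' array QC-metric failure (DQC below `dqc_min`, or missing), designated QC
#' duplicates (`duplicate_of` set; the primary sample is retained, the
#' flagged copy removed), heterozygosity/relatedness outliers (flag columns,
#' computed upstream), and discordant genetic vs self-reported sex. A sample
#' may carry several reasons but is removed once, so the ledger identity
#' `n_input - n_retained = number of distinct removed samples` always holds.
#'
#' @param samples Sample tibble (see [read_sample_table()]).
#' @param dqc_min Minimum acceptable DQC (default 0.82, the usual array
#'   guideline threshold).
#' @return An object of class `qc_report`: retained samples in `$retained`,
#'   ledger counts as fields, per-sample reasons in `$reasons`. Use
#'   [glance()] for the one-row ledger and [tidy()] for per-sample reasons.
#' @examples
#' s <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), cohort = "x",
#'   reported_sex = c("F", "M", "F"), genetic_sex = c("F", "F", "F"),
#'   dqc = c(0.99, 0.95, 0.5), duplicate_of = NA_character_,
#'   relatedness_flag = FALSE, het_outlier_flag = FALSE)
#' glance(qc_filter_samples(s))
#' @export
qc_filter_samples <- function(samples, dqc_min = 0.82) {
  samples <- validate_samples(samples)
  stopifnot(is.numeric(dqc_min), length(dqc_min) == 1)

  metric_fail <- is.na(samples$dqc) | samples$dqc < dqc_min
  dup_copy <- !is.na(samples$duplicate_of)
  het_rel <- samples$het_outlier_flag | samples$relatedness_flag
  sex_disc <- !is.na(samples$reported_sex) & !is.na(samples$genetic_sex) &
    samples$reported_sex != samples$genetic_sex

  reasons <- bind_rows(
    tibble(sample_id = samples$sample_id[metric_fail], reason = "qc_metrics"),
    tibble(sample_id = samples$sample_id[dup_copy], reason = "qc_duplicate"),
    tibble(sample_id = samples$sample_id[het_rel], reason = "het_or_related"),
    tibble(sample_id = samples$sample_id[sex_disc], reason = "sex_discordant")
  )
  removed <- unique(reasons$sample_id)
  retained <- samples[!samples$sample_id %in% removed, , drop = FALSE]

  structure(
    list(
      retained = retained,
      reasons = reasons,
      n_input = nrow(samples),
      n_fail_metrics = sum(metric_fail),
      n_duplicates_removed = sum(dup_copy),
      n_het_related_removed = sum(het_rel),
      n_sex_discordant = sum(sex_disc),
      n_retained = nrow(retained),
      dqc_min = dqc_min
    ),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Sample QC ledger\n")
  cat("  input:                 ", x$n_input, "\n")
  cat("  QC-metric failures:    ", x$n_fail_metrics, "\n")
  cat("  QC duplicates removed: ", x$n_duplicates_removed, "\n")
  cat("  het/relatedness:       ", x$n_het_related_removed, "\n")
  cat("  sex-discordant:        ", x$n_sex_discordant, "\n")
  cat("  retained:              ", x$n_retained, "\n")
  invisible(x)
}

#' @rdname qc_filter_samples
#' @param x A `qc_report`.
#' @param ... Unused.
#' @method glance qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble(n_input = x$n_input, n_fail_metrics = x$n_fail_metrics,
         n_duplicates_removed = x$n_duplicates_removed,
         n_het_related_removed = x$n_het_related_removed,
         n_sex_discordant = x$n_sex_discordant, n_retained = x$n_retained)
}

#' @rdname qc_filter_samples
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  as_tibble(x$reasons)
}

#' Classify a variant's array clustering category
#'
#' Mirrors the three probe-cluster categories used in array genotyping QC:
#' `MonoHighResolution` (monomorphic: all non-missing calls identical),
#' `NoMinorHom` (heterozygotes but no alternate homozygotes) and
#' `PolyHighResolution` (alternate homozygotes present in a polymorphic
#' column). A polymorphic column with homozygous-alternate calls but no
#' heterozygotes does not occur in practice for rare variants; it is mapped
#' to `PolyHighResolution` since alternate homozygotes are present.
#'
#' @param dosage Integer vector of allele-dosage codes 0/1/2, NA missing.
#' @return One of `"MonoHighResolution"`, `"NoMinorHom"`,
#'   `"PolyHighResolution"`.
#' @export
classify_cluster_category <- function(dosage) {
  obs <- dosage[!is.na(dosage)]
  if (length(obs) == 0) {
    abort("uncallable variant: all genotype calls are missing")
  }
  if (length(unique(obs)) == 1) return("MonoHighResolution")
  if (any(obs == 2)) return("PolyHighResolution")
  "NoMinorHom"
}

#' Cluster categories for every variant in a genotype matrix
#'
#' @param geno Genotype tibble ([read_genotype_matrix()]).
#' @return A tibble with columns `variant_id`, `category`.
#' @export
classify_cluster_categories <- function(geno) {
  geno <- validate_genotypes(geno)
  vids <- names(geno)[-1]
  tibble(
    variant_id = vids,
    category = vapply(vids, function(v) classify_cluster_category(geno[[v]]),
                      character(1), USE.NAMES = FALSE)
  )
}

#' Concordance between two genotype call vectors
#'
#' Agreement fraction between two aligned call vectors, e.g. a sample and
#' its designated QC duplicate, or array calls vs sequencing calls. A
#' comparison requires both calls non-missing; pairs with a missing call on
#' either side are skipped and counted in `n_missing_skipped`, keeping the
#' proportion interpretable. When per-variant cluster categories are
#' supplied, the same rule is applied within each category; the overall
#' value is then exactly the comparison-weighted mean of the per-category
#' values.
#'
#' @param a,b Integer dosage vectors over the same variant list, same
#'   order.
#' @param categories Optional character vector (same length) of cluster
#'   categories, e.g. from [classify_cluster_categories()].
#' @return An object of class `concordance_result` with fields
#'   `n_variants_compared`, `overall`, `by_category`, `n_missing_skipped`.
#'   [tidy()] gives one row per category plus the overall row; [glance()]
#'   one row.
#' @export
pairwise_concordance <- function(a, b, categories = NULL) {
  if (length(a) != length(b)) {
    abort("genotype vectors must be aligned on the same variant list")
  }
  if (!is.null(categories) && length(categories) != length(a)) {
    abort("categories must have one entry per variant")
  }
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    abort("no valid comparisons: every variant has a missing call")
  }
  by_category <- NULL
  if (!is.null(categories)) {
    cats <- intersect(cluster_levels, unique(categories))
    by_category <- vapply(cats, function(cl) {
      sel <- ok & categories == cl
      if (!any(sel)) return(NA_real_)
      mean(a[sel] == b[sel])
    }, numeric(1))
  }
  structure(
    list(
      n_variants_compared = sum(ok),
      overall = mean(a[ok] == b[ok]),
      by_category = by_category,
      n_missing_skipped = sum(!ok)
    ),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Genotype concordance: %.4f over %d calls (%d skipped for missingness)\n",
              x$overall, x$n_variants_compared, x$n_missing_skipped))
  if (!is.null(x$by_category)) {
    for (cl in names(x$by_category)) {
      cat(sprintf("  %-20s %.4f\n", cl, x$by_category[[cl]]))
    }
  }
  invisible(x)
}

#' @rdname pairwise_concordance
#' @param x A `concordance_result`.
#' @param ... Unused.
#' @method tidy concordance_result
#' @export
tidy.concordance_result <- function(x, ...) {
  out <- tibble(category = "overall", concordance = x$overall,
                n_compared = x$n_variants_compared)
  if (!is.null(x$by_category)) {
    out <- bind_rows(
      tibble(category = names(x$by_category),
             concordance = unname(x$by_category),
             n_compared = NA_integer_),
      out
    )
  }
  out
}

#' @rdname pairwise_concordance
#' @method glance concordance_result
#' @export
glance.concordance_result <- function(x, ...) {
  tibble(overall = x$overall,
         n_variants_compared = x$n_variants_compared,
         n_missing_skipped = x$n_missing_skipped)
}

#' Concordance for a set of duplicate sample pairs
#'
#' Convenience wrapper computing [pairwise_concordance()] for each
#' (primary, duplicate) pair in a genotype matrix.
#'
#' @param geno Genotype tibble containing both members of every pair.
#' @param pairs Tibble with columns `primary`, `duplicate` (sample ids).
#' @param categories Optional per-variant categories, as in
#'   [pairwise_concordance()]; when `NULL` they are computed from `geno`.
#' @return A tibble with one row per pair: `primary`, `duplicate`,
#'   `overall`, one column per cluster category present, and `n_skipped`.
#' @export
duplicate_concordance <- function(geno, pairs, categories = NULL) {
  geno <- validate_genotypes(geno)
  stopifnot(all(c("primary", "duplicate") %in% names(pairs)))
  if (is.null(categories)) {
    categories <- classify_cluster_categories(geno)$category
  }
  rows <- purrr::pmap(pairs[, c("primary", "duplicate")], function(primary, duplicate) {
    a <- unlist(geno[match(primary, geno$sample_id), -1], use.names = FALSE)
    b <- unlist(geno[match(duplicate, geno$sample_id), -1], use.names = FALSE)
    if (anyNA(match(c(primary, duplicate), geno$sample_id))) {
      abort(paste0("pair (", primary, ", ", duplicate,
                   ") not found in genotype matrix"))
    }
    res <- pairwise_concordance(a, b, categories)
    out <- tibble(primary = primary, duplicate = duplicate,
                  overall = res$overall)
    for (cl in names(res$by_category)) out[[cl]] <- res$by_category[[cl]]
    out$n_skipped <- res$n_missing_skipped
    out
  })
  bind_rows(rows)
}
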