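#' Capped per-gene carrier load and MOI consistency
#'
#' Collapses a sample's qualifying variants to a per-gene carrier indicator
#' capped at 1 — several variants in one gene still count as a genetic load
#' of 1, because without phase data compound heterozygosity cannot be
#' distinguished from variants on one haplotype. A gene is
#' *mode-of-inheritance consistent* when carriage matches its expected MOI:
#' at least one copy for a dominant gene, a homozygous (dosage 2) variant
#' for a recessive gene. Two heterozygous variants in a recessive gene do
#' NOT make it consistent (the conservative no-phase reading); a homozygous
#' variant in a dominant gene does, a fortiori.
#'
#' @param variant_dosages Tibble with columns `gene` and `dosage` (1 or 2),
#'   one row per qualifying variant carried by one sample.
#' @param panel Gene panel tibble ([read_gene_panel()]).
#' @return A tibble with one row per carried panel gene: `gene`, `load`
#'   (always 1), `consistent` (logical). Variants in genes absent from the
#'   panel are skipped with a warning.
#' @export
gene_load <- function(variant_dosages, panel) {
  stopifnot(all(c("gene", "dosage") %in% names(variant_dosages)))
  panel <- validate_gene_panel(panel)
  vd <- as_tibble(variant_dosages)
  if (nrow(vd) > 0 && !all(vd$dosage %in% c(1L, 2L))) {
    abort("dosage must be 1 or 2 for carried variants")
  }
  off_panel <- setdiff(unique(vd$gene), panel$gene)
  if (length(off_panel) > 0) {
    warn(paste0("skipping variant(s) in gene(s) absent from the panel: ",
                paste(off_panel, collapse = ", ")))
    vd <- vd[vd$gene %in% panel$gene, , drop = FALSE]
  }
  vd |>
    left_join(panel[, c("gene", "moi")], by = "gene") |>
    group_by(.data$gene) |>
    summarise(
      load = 1L,
      consistent = any(
        (.data$moi == "dominant" & .data$dosage >= 1L) |
          (.data$moi == "recessive" & .data$dosage == 2L)
      ),
      .groups = "drop"
    )
}

#' Assign a carrier group from per-gene loads
#'
#' The three carrier strata: group 1, no qualifying rare variants at all;
#' group 2, carries qualifying variants but none in an MOI-consistent
#' state (heterozygous-only carriage in recessive genes); group 3, at least
#' one gene carried consistently with its expected mode of inheritance
#' (heterozygous in a dominant gene and/or homozygous in a recessive gene).
#' Group 3 takes precedence when a sample satisfies both the group-2 and
#' group-3 descriptions.
#'
#' @param load Tibble from [gene_load()] (possibly zero rows).
#' @return Integer 1, 2 or 3.
#' @export
assign_group <- function(load) {
  stopifnot(all(c("gene", "load", "consistent") %in% names(load)))
  if (nrow(load) == 0) return(1L)
  if (any(load$consistent)) return(3L)
  2L
}

#' Classify every sample in a cohort into carrier groups
#'
#' The cohort-level driver: applies the analysis-stage variant filters at
#' the requested CADD-PHRED threshold, restricts to the requested panel
#' scope, computes each sample's capped per-gene load, and assigns carrier
#' groups. Filtering always precedes grouping, so sub-threshold variants
#' can neither qualify a sample nor demote it. Missing genotype calls are
#' treated as non-carrier for classification.
#'
#' @param geno Genotype tibble ([read_genotype_matrix()]).
#' @param variants Variant tibble ([read_variant_table()]).
#' @param panel Gene panel tibble ([read_gene_panel()]).
#' @param cadd_min CADD-PHRED threshold for the analysis filter.
#' @param scope `"extended"` (all panel genes) or `"nhs"` (clinical subset).
#' @param config Optional [filter_config()]; `cadd_min` overrides its
#'   threshold.
#' @return A tibble of class `carrier_profiles`, one row per sample:
#'   `sample_id`, `group` (1/2/3), `n_qualifying` (variant count),
#'   `n_genes_loaded`, plus list-columns `loaded_genes` and
#'   `consistent_genes`.
#' @export
classify_carriers <- function(geno, variants, panel,
                              cadd_min = 15,
                              scope = c("extended", "nhs"),
                              config = NULL) {
  scope <- match.arg(scope)
  geno <- validate_genotypes(geno)
  variants <- validate_variants(variants)
  panel <- validate_gene_panel(panel)
  if (nrow(geno) == 0) abort("empty cohort: genotype matrix has no samples")
  config <- config %||% filter_config()
  config$cadd_min <- cadd_min
  kept <- apply_analysis_filters(variants, config)

  scoped <- if (scope == "nhs") panel[panel$nhs_panel, , drop = FALSE]
            else panel[panel$extended_panel, , drop = FALSE]

  off_panel <- setdiff(unique(kept$gene), panel$gene)
  if (length(off_panel) > 0) {
    warn(paste0("filter-passing variant(s) in gene(s) absent from the ",
                "panel are ignored: ", paste(off_panel, collapse = ", ")))
  }
  kept <- kept[kept$gene %in% scoped$gene,
               c("variant_id", "gene"), drop = FALSE]

  long <- geno |>
    tidyr::pivot_longer(-"sample_id", names_to = "variant_id",
                        values_to = "dosage") |>
    filter(!is.na(.data$dosage), .data$dosage > 0L) |>
    inner_join(kept, by = "variant_id") |>
    left_join(scoped[, c("gene", "moi")], by = "gene")

  per_gene <- long |>
    group_by(.data$sample_id, .data$gene) |>
    summarise(
      consistent = any(
        (.data$moi == "dominant" & .data$dosage >= 1L) |
          (.data$moi == "recessive" & .data$dosage == 2L)
      ),
      .groups = "drop"
    )

  counts <- long |> count(.data$sample_id, name = "n_qualifying")
  loads <- per_gene |>
    group_by(.data$sample_id) |>
    summarise(
      n_genes_loaded = n(),
      loaded_genes = list(sort(.data$gene)),
      consistent_genes = list(sort(.data$gene[.data$consistent])),
      .groups = "drop"
    )

  out <- tibble(sample_id = geno$sample_id) |>
    left_join(counts, by = "sample_id") |>
    left_join(loads, by = "sample_id") |>
    mutate(
      n_qualifying = dplyr::coalesce(.data$n_qualifying, 0L),
      n_genes_loaded = dplyr::coalesce(.data$n_genes_loaded, 0L),
      loaded_genes = purrr::map(.data$loaded_genes, \(g) g %||% character()),
      consistent_genes = purrr::map(.data$consistent_genes,
                                    \(g) g %||% character()),
      group = dplyr::case_when(
        n_qualifying == 0L ~ 1L,
        purrr::map_int(consistent_genes, length) > 0L ~ 3L,
        TRUE ~ 2L
      )
    ) |>
    select("sample_id", "group", "n_qualifying", "n_genes_loaded",
           "loaded_genes", "consistent_genes")
  class(out) <- c("carrier_profiles", class(out))
  attr(out, "cadd_min") <- cadd_min
  attr(out, "scope") <- scope
  out
}

#' @rdname classify_carriers
#' @param x A `carrier_profiles` tibble.
#' @param ... Unused.
#' @method glance carrier_profiles
#' @export
glance.carrier_profiles <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_group1 = sum(x$group == 1L),
    n_group2 = sum(x$group == 2L),
    n_group3 = sum(x$group == 3L),
    cadd_min = attr(x, "cadd_min") %||% NA_real_,
    scope = attr(x, "scope") %||% NA_character_
  )
}

#' Carrier-group prevalence over thresholds and panel scopes
#'
#' Re-runs the filter-then-classify pipeline at each CADD-PHRED threshold
#' and panel scope and tabulates the proportion of the cohort in each
#' carrier group with a 95% Wald interval ([proportion_ci()]). Raising the
#' threshold can only shrink the qualifying variant set, so the group-3
#' proportion is non-increasing in the threshold; the clinical (NHS) scope
#' is a gene subset of the extended scope, so its group-3 samples are a
#' subset sample-wise.
#'
#' @inheritParams classify_carriers
#' @param thresholds Ascending numeric vector of CADD-PHRED thresholds.
#' @param scopes Character vector drawn from `c("nhs", "extended")`.
#' @return A tibble of class `prevalence_sweep`: one row per
#'   (threshold, scope, group) with `k`, `n`, `p`, `ci_low`, `ci_high`.
#'   Proportions sum to 1 within each (threshold, scope) cell. Plot with
#'   [autoplot()].
#' @export
prevalence_sweep <- function(geno, variants, panel,
                             thresholds = c(15, 20, 25),
                             scopes = c("nhs", "extended"),
                             config = NULL) {
  stopifnot(!is.unsorted(thresholds))
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (nrow(geno) == 0) abort("empty cohort: genotype matrix has no samples")
  grid <- tidyr::expand_grid(cadd_min = thresholds, scope = scopes)
  out <- purrr::pmap(grid, function(cadd_min, scope) {
    profiles <- classify_carriers(geno, variants, panel,
                                  cadd_min = cadd_min, scope = scope,
                                  config = config)
    counts <- vapply(1:3, function(g) sum(profiles$group == g), integer(1))
    bind_cols(
      tibble(cadd_min = cadd_min, scope = scope, group = 1:3),
      proportion_ci(counts, nrow(profiles))
    )
  })
  out <- bind_rows(out)
  class(out) <- c("prevalence_sweep", class(out))
  out
}
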