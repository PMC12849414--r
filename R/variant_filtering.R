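#' Variant prioritisation settings
#'
#' Bundles the thresholds used by the two prioritisation stages.
#' `cadd_min` is a CADD-PHRED score (scaled deleteriousness; 20 marks the
#' top 1% of possible substitutions), `maf_max` a minor allele frequency
#' (rare means below 0.01 here). The array-design stage applies the strict
#' comparison `cadd_phred > cadd_min` to catalogue-derived missense
#' candidates; the analysis stage removes variants with `cadd_phred <
#' cadd_min`, so a variant scoring exactly `cadd_min` is dropped at design
#' but kept at analysis. The two comparators are deliberate, matching how
#' each stage is defined.
#'
#' @param cadd_min CADD-PHRED threshold (default 15).
#' @param maf_max Maximum minor allele frequency for catalogue candidates
#'   (default 0.01).
#' @param allowed_consequences Consequence classes eligible at the design
#'   stage.
#' @param drop_intronic_only Drop variants annotated only as intronic at the
#'   analysis stage.
#' @param drop_loftee_lc Drop LOFTEE low-confidence loss-of-function calls
#'   at the analysis stage.
#' @param gof_exclusion_ids Variant ids of known gain-of-function alleles to
#'   exclude from carrier analyses (e.g. leanness-associated MC4R
#'   rs2229616).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cadd_min = 15,
                          maf_max = 0.01,
                          allowed_consequences = c("missense", "frameshift",
                                                   "stop_gain"),
                          drop_intronic_only = TRUE,
                          drop_loftee_lc = TRUE,
                          gof_exclusion_ids = character()) {
  stopifnot(is.numeric(cadd_min), length(cadd_min) == 1, cadd_min >= 0,
            is.numeric(maf_max), length(maf_max) == 1,
            maf_max > 0, maf_max <= 1)
  if (!all(allowed_consequences %in% consequence_levels)) {
    abort("allowed_consequences must be drawn from the consequence vocabulary")
  }
  structure(
    list(cadd_min = cadd_min, maf_max = maf_max,
         allowed_consequences = allowed_consequences,
         drop_intronic_only = isTRUE(drop_intronic_only),
         drop_loftee_lc = isTRUE(drop_loftee_lc),
         gof_exclusion_ids = as.character(gof_exclusion_ids)),
    class = "filter_config"
  )
}

#' Select rare predicted-deleterious array candidates
#'
#' The content-design rule for a rare-variant genotyping array. Variants
#' present in the disease-mutation catalogue (`source` HGMD or both) are
#' retained unconditionally, irrespective of predicted pathogenicity.
#' Population-catalogue (gnomAD-only) variants must be rare
#' (`maf < maf_max`), of an allowed consequence class (missense, frameshift
#' or stop-gain by default), and missense variants must additionally be
#' called damaging by SIFT, probably damaging by PolyPhen, and score
#' strictly above `cadd_min` on CADD-PHRED. A gnomAD-only variant with no
#' MAF fails with a logged reason rather than an error.
#'
#' @param variants Variant tibble (see [validate_variants()]).
#' @param config A [filter_config()].
#' @return The retained subset, input order preserved, with a
#'   per-variant reason log for the removed rows available via
#'   [filter_reasons()].
#' @export
select_array_candidates <- function(variants, config = filter_config()) {
  variants <- validate_variants(variants)
  stopifnot(inherits(config, "filter_config"))
  in_hgmd <- variants$source %in% c("HGMD", "both")
  rare <- !is.na(variants$maf) & variants$maf < config$maf_max
  allowed <- variants$consequence %in% config$allowed_consequences
  missense_ok <- variants$consequence != "missense" |
    (!is.na(variants$sift) & variants$sift == "damaging" &
     !is.na(variants$polyphen) & variants$polyphen == "probably_damaging" &
     !is.na(variants$cadd_phred) & variants$cadd_phred > config$cadd_min)
  keep <- in_hgmd | (rare & allowed & missense_ok)

  reason <- rep(NA_character_, nrow(variants))
  gnomad_only <- !in_hgmd
  reason[gnomad_only & is.na(variants$maf)] <- "missing_maf"
  reason[gnomad_only & !is.na(variants$maf) & !rare] <- "maf_above_max"
  reason[gnomad_only & rare & !allowed] <- "consequence_not_allowed"
  reason[gnomad_only & rare & allowed & !missense_ok] <- "missense_scores_fail"
  with_reasons(variants[keep, , drop = FALSE],
               tibble(variant_id = variants$variant_id[!keep],
                      reason = reason[!keep]))
}

#' Apply analysis-stage annotation filters
#'
#' Post-genotyping removal of variants that should not enter carrier
#' analyses: exclusively intronic annotations, CADD-PHRED below `cadd_min`,
#' and LOFTEE low-confidence loss-of-function calls. Retention is
#' `cadd_phred >= cadd_min` (removal is "score below threshold"), unlike the
#' strict design-stage comparison — see [filter_config()].
#'
#' @inheritParams select_array_candidates
#' @return The retained subset (possibly empty), input order preserved,
#'   with removal reasons available via [filter_reasons()].
#' @export
apply_analysis_filters <- function(variants, config = filter_config()) {
  variants <- validate_variants(variants)
  stopifnot(inherits(config, "filter_config"))
  intronic <- config$drop_intronic_only & variants$consequence == "intronic"
  low_cadd <- is.na(variants$cadd_phred) | variants$cadd_phred < config$cadd_min
  loftee_lc <- config$drop_loftee_lc & !is.na(variants$loftee) &
    variants$loftee == "LC"
  keep <- !intronic & !low_cadd & !loftee_lc
  reason <- rep(NA_character_, nrow(variants))
  reason[loftee_lc] <- "loftee_low_confidence"
  reason[low_cadd] <- "cadd_below_min"
  reason[intronic] <- "intronic_only"
  with_reasons(variants[keep, , drop = FALSE],
               tibble(variant_id = variants$variant_id[!keep],
                      reason = reason[!keep]))
}

with_reasons <- function(kept, reasons) {
  attr(kept, "filter_reasons") <- reasons
  kept
}

#' Per-variant removal reasons from the last filter call
#'
#' @param variants The tibble returned by [select_array_candidates()] or
#'   [apply_analysis_filters()].
#' @return A tibble with columns `variant_id`, `reason`, one row per removed
#'   variant.
#' @export
filter_reasons <- function(variants) {
  attr(variants, "filter_reasons") %||%
    tibble(variant_id = character(), reason = character())
}

#' Exclude known gain-of-function variants
#'
#' Partitions the variant table into carriers-analysis variants and an
#' excluded set of known gain-of-function alleles (activating variants
#' associated with the opposite phenotype, which would dilute risk-carrier
#' estimates). The partition is exact: every input row appears in exactly
#' one of the two outputs.
#'
#' @param variants Variant tibble.
#' @param exclusion_ids Character vector of variant ids to exclude.
#' @return A list with elements `retained` and `excluded`; excluded rows are
#'   marked `gof_excluded = TRUE`. Ids in `exclusion_ids` absent from the
#'   input produce a warning.
#' @export
exclude_gof_variants <- function(variants, exclusion_ids) {
  variants <- validate_variants(variants)
  exclusion_ids <- as.character(exclusion_ids)
  absent <- setdiff(exclusion_ids, variants$variant_id)
  if (length(absent) > 0) {
    warn(paste0("gain-of-function exclusion id(s) not present in the ",
                "variant table: ", paste(absent, collapse = ", ")))
  }
  hit <- variants$variant_id %in% exclusion_ids
  excluded <- variants[hit, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$gof_excluded <- TRUE
  list(retained = variants[!hit, , drop = FALSE], excluded = excluded)
}
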