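# Controlled vocabularies shared across the package. Missingness is always
# encoded as NA (written as "NA" in TSV), never as a sentinel string.

consequence_levels <- c("missense", "frameshift", "stop_gain", "splice",
                        "intronic", "other")
sift_levels      <- c("damaging", "tolerated")
polyphen_levels  <- c("probably_damaging", "possibly_damaging", "benign")
loftee_levels    <- c("HC", "LC")
source_levels    <- c("HGMD", "gnomAD", "both")
moi_levels       <- c("dominant", "recessive")
cluster_levels   <- c("PolyHighResolution", "NoMinorHom", "MonoHighResolution")

variant_columns <- c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                     "consequence", "cadd_phred", "sift", "polyphen",
                     "loftee", "maf", "source", "gof_excluded")

#' Validate a variant annotation table
#'
#' Checks the schema and value invariants of a variant table: required
#' columns present, positions >= 1, MAF (when present) in \[0, 1\],
#' CADD-PHRED non-negative, and controlled vocabularies respected.
#' Consequence strings outside the known vocabulary are mapped to `"other"`;
#' every other violation is an error.
#'
#' @param variants A data frame of variant annotations.
#' @return The validated tibble (invisibly coerced), with `consequence`
#'   normalised.
#' @export
validate_variants <- function(variants) {
  variants <- as_tibble(variants)
  missing_cols <- setdiff(variant_columns, names(variants))
  if (length(missing_cols) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_row <- function(what, idx) {
    abort(paste0("variant table row ", idx[1], ": ", what))
  }
  if (anyDuplicated(variants$variant_id)) {
    abort("variant table has duplicated variant_id values")
  }
  if (any(bad <- !is.na(variants$pos) & variants$pos < 1)) {
    bad_row("pos must be >= 1", which(bad))
  }
  if (any(bad <- !is.na(variants$maf) & (variants$maf < 0 | variants$maf > 1))) {
    bad_row("maf outside [0, 1]", which(bad))
  }
  if (any(bad <- !is.na(variants$cadd_phred) & variants$cadd_phred < 0)) {
    bad_row("cadd_phred must be non-negative", which(bad))
  }
  variants$consequence <- if_else(
    variants$consequence %in% consequence_levels,
    variants$consequence, "other"
  )
  check_vocab(variants$sift, sift_levels, "sift")
  check_vocab(variants$polyphen, polyphen_levels, "polyphen")
  check_vocab(variants$loftee, loftee_levels, "loftee")
  check_vocab(variants$source, source_levels, "source")
  variants
}

check_vocab <- function(x, levels, field) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(paste0("unknown ", field, " value(s): ",
                 paste(unique(x[bad]), collapse = ", "),
                 " (allowed: ", paste(levels, collapse = ", "), ", or NA)"))
  }
  invisible(x)
}
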