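#' Read a variant annotation table
#'
#' Reads a tab-delimited variant annotation table into a validated tibble.
#' One row per variant, with gene symbol, consequence class, deleteriousness
#' scores (CADD-PHRED, SIFT, PolyPhen), LOFTEE confidence, minor allele
#' frequency and source catalogue. Empty cells and the literal `"NA"` are
#' missing values; consequence strings outside the known vocabulary are
#' mapped to `"other"`.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param schema Optional named character vector mapping canonical field
#'   names (`variant_id`, `chrom`, `pos`, ..., see [validate_variants()]) to
#'   the column names used in the file, for files whose headers differ.
#'   Unmapped canonical names are looked up verbatim.
#' @return A tibble with one row per input row and the canonical columns.
#'   Row order is preserved.
#' @examples
#' path <- tempfile(fileext = ".tsv")
#' sim <- simulate_cohort(sim_config(seed = 1, n_samples = 20,
#'   genes = synthetic_gene_panel(2, 2)))
#' readr::write_tsv(sim$variants, path, na = "NA")
#' read_variant_table(path)
#' @export
read_variant_table <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  cols <- setNames(variant_columns, variant_columns)
  if (!is.null(schema)) cols[names(schema)] <- schema
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols) > 0) {
    abort(paste0("variant file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    variant_id = raw[[cols["variant_id"]]],
    chrom = raw[[cols["chrom"]]],
    pos = parse_num(raw[[cols["pos"]]], "pos", integer = TRUE),
    ref = raw[[cols["ref"]]],
    alt = raw[[cols["alt"]]],
    gene = raw[[cols["gene"]]],
    consequence = raw[[cols["consequence"]]],
    cadd_phred = parse_num(raw[[cols["cadd_phred"]]], "cadd_phred"),
    sift = raw[[cols["sift"]]],
    polyphen = raw[[cols["polyphen"]]],
    loftee = raw[[cols["loftee"]]],
    maf = parse_num(raw[[cols["maf"]]], "maf"),
    source = raw[[cols["source"]]],
    gof_excluded = parse_logical(raw[[cols["gof_excluded"]]], "gof_excluded")
  )
  out$consequence[is.na(out$consequence)] <- "other"
  validate_variants(out)
}

# numeric parser that reports the 1-based data-row number on failure
parse_num <- function(x, field, integer = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0("row ", which(bad)[1], ": cannot parse ", field,
                 " value '", x[which(bad)[1]], "'"))
  }
  if (integer) as.integer(out) else out
}

parse_logical <- function(x, field) {
  if (is.null(x)) return(rep(FALSE, 0))
  low <- tolower(x)
  out <- rep(NA, length(x))
  out[low %in% c("true", "t", "1")] <- TRUE
  out[low %in% c("false", "f", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    abort(paste0("row ", which(bad)[1], ": cannot parse ", field,
                 " value '", x[which(bad)[1]], "' as true/false"))
  }
  out[is.na(x)] <- FALSE
  out
}

#' Read a genotype matrix
#'
#' Reads sample-by-variant allele dosages. Two formats are supported:
#' a wide TSV (first column `sample_id`, one integer column per variant,
#' codes 0/1/2 and `NA` for missing) or a bi-allelic VCF whose `GT` field is
#' converted as `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`.
#' Phased separators (`|`) are accepted. Sample and variant order follow the
#' file.
#'
#' @param path Path to the genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A tibble whose first column is `sample_id` and whose remaining
#'   integer columns are one variant each.
#' @export
read_genotype_matrix <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  geno <- switch(format,
    tsv = read_genotype_tsv(path),
    vcf = read_genotype_vcf(path)
  )
  validate_genotypes(geno)
}

read_genotype_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed genotype TSV (ragged row near line ",
                 probs$row[1], ")"))
  }
  if (names(raw)[1] != "sample_id") {
    abort("genotype TSV must have 'sample_id' as its first column")
  }
  codes <- lapply(names(raw)[-1], function(v) {
    parse_num(raw[[v]], paste0("genotype code for ", v), integer = TRUE)
  })
  names(codes) <- names(raw)[-1]
  bind_cols(tibble(sample_id = raw$sample_id), as_tibble(codes))
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort("multi-allelic VCF records are not supported; split them first (e.g. `bcftools norm -m-`)")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM, "_", fix$POS, "_", fix$REF, "_", fix$ALT)[blank]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    out
  }
  mat <- apply(gt, 2, code)
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(gt),
                                       dimnames = list(NULL, colnames(gt)))
  out <- as_tibble(t(mat), .name_repair = "minimal")
  names(out) <- ids
  bind_cols(tibble(sample_id = colnames(gt)), out)
}

#' Validate a genotype matrix
#'
#' @param geno A genotype tibble as returned by [read_genotype_matrix()].
#' @return The validated tibble.
#' @export
validate_genotypes <- function(geno) {
  geno <- as_tibble(geno)
  if (ncol(geno) < 1 || names(geno)[1] != "sample_id") {
    abort("genotype matrix must have 'sample_id' as its first column")
  }
  if (anyDuplicated(geno$sample_id)) {
    dup <- geno$sample_id[duplicated(geno$sample_id)][1]
    abort(paste0("duplicated sample_id in genotype matrix: ", dup))
  }
  codes <- as.matrix(geno[, -1, drop = FALSE])
  if (length(codes) > 0 && !all(codes %in% c(0L, 1L, 2L, NA))) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  geno
}

#' Write a genotype matrix to TSV
#'
#' Inverse of `read_genotype_matrix(format = "tsv")`: codes 0/1/2, missing
#' written as `NA`. Round-trips bit-exactly.
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(geno, path) {
  readr::write_tsv(validate_genotypes(geno), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a mode-of-inheritance gene panel
#'
#' Reads a TSV with columns `gene`, `moi` and `nhs_panel` (and optionally
#' `extended_panel`). The clinically used panel is a subset of the extended
#' panel, so `nhs_panel = TRUE` rows are always marked
#' `extended_panel = TRUE`. The mode-of-inheritance vocabulary is restricted
#' to autosomal `dominant` and `recessive`; anything else (e.g. X-linked) is
#' rejected with an explicit error, since hemizygous carriage is outside the
#' model.
#'
#' @param path Path to the panel TSV.
#' @return A tibble with columns `gene`, `moi`, `nhs_panel`,
#'   `extended_panel`.
#' @export
read_gene_panel <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  need <- c("gene", "moi", "nhs_panel")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("gene panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  panel <- tibble(
    gene = raw$gene,
    moi = raw$moi,
    nhs_panel = parse_logical(raw$nhs_panel, "nhs_panel"),
    extended_panel = if ("extended_panel" %in% names(raw)) {
      parse_logical(raw$extended_panel, "extended_panel")
    } else TRUE
  )
  validate_gene_panel(panel)
}

#' Validate a gene panel
#'
#' @param panel A data frame with columns `gene`, `moi`, `nhs_panel` and
#'   optionally `extended_panel`.
#' @return The validated tibble with `extended_panel` enforced to cover the
#'   NHS subset.
#' @export
validate_gene_panel <- function(panel) {
  panel <- as_tibble(panel)
  if (!"extended_panel" %in% names(panel)) panel$extended_panel <- TRUE
  if (anyDuplicated(panel$gene)) {
    abort(paste0("duplicated gene symbol in panel: ",
                 panel$gene[duplicated(panel$gene)][1]))
  }
  bad <- !panel$moi %in% moi_levels
  if (any(bad)) {
    abort(paste0("unsupported mode of inheritance '", panel$moi[bad][1],
                 "' for gene ", panel$gene[bad][1],
                 "; only 'dominant' and 'recessive' are modelled ",
                 "(X-linked/hemizygous inheritance is out of scope)"))
  }
  # the NHS clinical list is a subset of the extended list by construction
  panel$extended_panel <- panel$extended_panel | panel$nhs_panel
  panel
}

#' Write a gene panel to TSV
#'
#' @param panel Gene panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_panel <- function(panel, path) {
  readr::write_tsv(validate_gene_panel(panel), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Columns: `sample_id`, `cohort`, `reported_sex`, `genetic_sex` (F/M/NA),
#' `dqc` (array dish quality control metric in \[0, 1\]), `duplicate_of`
#' (sample_id of the primary sample for designated QC duplicates),
#' `relatedness_flag`, `het_outlier_flag`.
#'
#' @param path Path to the sample TSV.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  need <- c("sample_id", "cohort", "reported_sex", "genetic_sex", "dqc",
            "duplicate_of", "relatedness_flag", "het_outlier_flag")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("sample table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- tibble(
    sample_id = raw$sample_id,
    cohort = raw$cohort,
    reported_sex = raw$reported_sex,
    genetic_sex = raw$genetic_sex,
    dqc = parse_num(raw$dqc, "dqc"),
    duplicate_of = raw$duplicate_of,
    relatedness_flag = parse_logical(raw$relatedness_flag, "relatedness_flag"),
    het_outlier_flag = parse_logical(raw$het_outlier_flag, "het_outlier_flag")
  )
  validate_samples(samples)
}

#' Validate a sample metadata table
#'
#' @param samples Sample tibble.
#' @return The validated tibble.
#' @export
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  if (anyDuplicated(samples$sample_id)) {
    abort("duplicated sample_id in sample table")
  }
  check_vocab(samples$reported_sex, c("F", "M"), "reported_sex")
  check_vocab(samples$genetic_sex, c("F", "M"), "genetic_sex")
  if (any(bad <- !is.na(samples$dqc) & (samples$dqc < 0 | samples$dqc > 1))) {
    abort(paste0("dqc outside [0, 1] for sample ",
                 samples$sample_id[bad][1]))
  }
  ref <- samples$duplicate_of
  bad <- !is.na(ref) & (!(ref %in% samples$sample_id) | ref == samples$sample_id)
  if (any(bad)) {
    abort(paste0("duplicate_of for sample ", samples$sample_id[bad][1],
                 " does not name a distinct existing sample"))
  }
  samples
}

#' Read a run configuration
#'
#' A YAML file pointing at the three input artifacts, e.g.
#' ```yaml
#' genotypes: geno.tsv
#' genotype_format: tsv
#' variants: variants.tsv
#' panel: panel.tsv
#' samples: samples.tsv
#' ```
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path Path to the YAML config.
#' @return A named list with loaded `genotypes`, `variants`, `panel` and,
#'   when configured, `samples`.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  need <- c("genotypes", "variants", "panel")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys) > 0) {
    abort(paste0("run config is missing key(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(dirname(path), p)
  }
  out <- list(
    genotypes = read_genotype_matrix(resolve(cfg$genotypes),
                                     format = cfg$genotype_format %||% "tsv"),
    variants = read_variant_table(resolve(cfg$variants)),
    panel = read_gene_panel(resolve(cfg$panel))
  )
  if (!is.null(cfg$samples)) {
    out$samples <- read_sample_table(resolve(cfg$samples))
  }
  out
}
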