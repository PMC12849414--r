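#' Plot a carrier-group prevalence sweep
#'
#' Grouped bars of carrier-group percentages by CADD-PHRED threshold,
#' faceted by panel scope, with 95% Wald error bars — the standard
#' presentation of carriage rates by predicted deleteriousness.
#'
#' @param object A `prevalence_sweep` tibble ([prevalence_sweep()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prevalence_sweep
#' @export
autoplot.prevalence_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = factor(.data$cadd_min), y = 100 * .data$p,
                 fill = factor(.data$group))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$ci_low, ymax = 100 * .data$ci_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope)) +
    ggplot2::labs(x = "CADD-PHRED threshold", y = "% of cohort",
                  fill = "Carrier group") +
    ggplot2::theme_minimal()
}

#' Plot gene-pair co-occurrence test results
#'
#' Observed double-carrier proportion against the product-of-marginals
#' expectation, one point per tested gene pair, sized by the double-carrier
#' count and coloured by the exact binomial p-value; the identity line
#' marks independence.
#'
#' @param object A `gene_pair_tests` tibble ([test_gene_pairs()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_pair_tests
#' @export
autoplot.gene_pair_tests <- function(object, ...) {
  ggplot2::ggplot(object,
    ggplot2::aes(x = .data$p_expected, y = .data$p_obs,
                 size = .data$k_obs, colour = -log10(.data$p_value))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Expected joint carriage (product of marginals)",
                  y = "Observed joint carriage",
                  colour = expression(-log[10](p)), size = "Double carriers") +
    ggplot2::theme_minimal()
}

#' Plot a sample-QC exclusion ledger
#'
#' Bar chart of removal reasons from a [qc_filter_samples()] report.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  dat <- tibble(
    reason = factor(c("QC metrics", "QC duplicate", "het/related",
                      "sex discordant"),
                    levels = c("QC metrics", "QC duplicate", "het/related",
                               "sex discordant")),
    n = c(object$n_fail_metrics, object$n_duplicates_removed,
          object$n_het_related_removed, object$n_sex_discordant)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$reason, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "Samples",
      title = sprintf("Sample QC: %d in, %d retained",
                      object$n_input, object$n_retained)) +
    ggplot2::theme_minimal()
}

#' Plot per-category genotype concordance
#'
#' @param object A `concordance_result` ([pairwise_concordance()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot concordance_result
#' @export
autoplot.concordance_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat,
    ggplot2::aes(x = .data$category, y = 100 * .data$concordance)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::coord_cartesian(
      ylim = c(100 * max(0, min(dat$concordance) - 0.01), 100)) +
    ggplot2::labs(x = NULL, y = "Concordance (%)") +
    ggplot2::theme_minimal()
}
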