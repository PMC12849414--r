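---
title: "Rare-variant carrier screening and oligogenic co-occurrence: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant carrier screening and oligogenic co-occurrence: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligocarrier)
library(dplyr)
```

## The problem

Severe obesity (and many other complex phenotypes) has a tail of cases
driven by rare, highly penetrant variants in a limited set of genes. A
practical screening design genotypes a large clinical cohort on a custom
array carrying rare predicted-deleterious variants in those genes, then
asks three questions:

1. **Who carries what?** Which samples carry rare qualifying variants, and
   is the carriage state consistent with each gene's expected mode of
   inheritance (MOI)?
2. **Is carriage elevated relative to a comparison cohort?**
3. **Is there evidence of oligogenic inheritance** — individuals carrying
   qualifying variants in two or more genes, or in particular gene pairs,
   more often than chance predicts?

`oligocarrier` implements this pipeline end to end on tabular inputs — a
samples-by-variants dosage matrix, a per-variant annotation table, a gene
panel with per-gene MOI — and ships a seeded synthetic-cohort generator so
every stage can be exercised and calibrated without access to
individual-level human data (which such studies cannot deposit).

## Variant prioritisation

Two distinct filters are modelled, corresponding to the two places a
screening study prunes variants.

**Array-design selection** (`select_array_candidates()`). Variants present
in a disease-mutation catalogue (HGMD) are retained unconditionally,
whatever their predicted pathogenicity — the catalogue membership is itself
the evidence. Population-catalogue variants (gnomAD) must be rare
(MAF < `maf_max`, default 0.01), of a qualifying consequence class
(missense, frameshift, stop-gain), and missense variants must in addition
be SIFT-damaging, PolyPhen probably-damaging and score **strictly above**
the CADD-PHRED threshold (default 15).

**Analysis-stage filters** (`apply_analysis_filters()`). After genotyping,
variants are removed if they are exclusively intronic on the canonical
transcript, if their CADD-PHRED score is **below** the threshold (so a
score of exactly 15 is retained), or if LOFTEE calls them low-confidence
loss-of-function. The two comparators differ at the boundary by design:
each stage follows its own stated rule, and the package keeps them
separate rather than harmonising them. Whether a published analysis
treated a score of exactly 15 as pass or fail at the analysis stage is
generally ambiguous; we follow the removal rule "< 15" literally.

Known gain-of-function alleles (e.g. the MC4R rs2229616 variant, which
predisposes to *lower* BMI) are excluded from risk-carrier analyses by an
explicit id list (`exclude_gof_variants()`); an exact partition is
returned so nothing is silently dropped. Every removed variant carries one
machine-readable reason code (`filter_reasons()`), making exclusion audits
possible without cluster-plot inspection, which is out of scope here.

## Sample QC and concordance

`qc_filter_samples()` applies the standard exclusion ledger in a fixed
order: array QC-metric failure (DQC below 0.82 by default; a missing DQC
counts as a failure, since the sample cannot be certified),
designated QC duplicates (the flagged copy is removed, the primary kept),
heterozygosity/relatedness outliers (flags computed upstream — the package
does not estimate kinship), and discordant genetic vs self-reported sex. A
sample may accumulate several reasons but is removed exactly once, so
`n_input - n_retained` always equals the number of distinct removed
samples.

Reproducibility of genotyping is quantified by `pairwise_concordance()`
between designated duplicate pairs: the agreement fraction over calls
where **both** members are non-missing. Pairs with a missing call on
either side are skipped and counted — the only convention that keeps the
proportion interpretable as agreement. Concordance is also reported within
the three array cluster categories (`PolyHighResolution`, `NoMinorHom`,
`MonoHighResolution`, recomputed from the data by
`classify_cluster_category()`), and the overall value is exactly the
comparison-weighted mean of the per-category values. Per-pair values and
their mean are both available (via `duplicate_concordance()`), since
reports differ in whether they average per variant or per pair.

## Carrier groups and the capped load

For a given CADD threshold and panel scope, each sample's qualifying
variants are collapsed to a per-gene **capped load**: 1 if the sample
carries at least one qualifying variant in the gene, regardless of how
many. Without phase information, two heterozygous variants in one gene
cannot be distinguished from two variants on the same haplotype, so they
are never treated as bi-allelic carriage and never counted twice in
multi-gene statistics.

Samples are then stratified:

* **Group 1** — no qualifying variants anywhere in the scoped panel;
* **Group 2** — carries qualifying variants, but only heterozygously in
  genes with recessive expected MOI (carriage inconsistent with MOI);
* **Group 3** — at least one gene carried consistently with its MOI:
  heterozygous or homozygous in a dominant gene, homozygous in a recessive
  gene. Group 3 takes precedence where both descriptions apply.

Filtering always precedes grouping, so sub-threshold variants can neither
promote nor demote a sample. Missing genotype calls count as non-carrier —
the semantics of an array no-call. Panels are restricted to autosomal
dominant/recessive MOI; X-linked entries are rejected at input rather than
silently mishandled.

`prevalence_sweep()` repeats this over thresholds (default 15, 20, 25) and
panel scopes (clinical subset vs extended panel) and attaches 95% Wald
intervals. Two invariants follow structurally and are asserted in the
tests: group-3 prevalence is non-increasing in the threshold, and the
clinical-scope group-3 sample set is nested in the extended-scope set.

## Statistics

* **Proportion intervals** use the plain Wald formula
  $p \pm 1.96\sqrt{p(1-p)/n}$, clamped to $[0,1]$ — chosen over
  Wilson/Clopper–Pearson so intervals match the formula used for published
  error bars exactly; it is degenerate at $p \in \{0, 1\}$, which is
  accepted.
* **Cohort comparisons** use the two-sided Fisher's exact test
  (probability-mass convention, via `stats::fisher.test`), with
  Benjamini–Hochberg adjustment across each comparison table as one
  family.
* **Gene-pair co-occurrence**: under independence, the probability of one
  individual carrying qualifying variants in both genes of a pair is the
  product of the marginal carriage proportions among group-3 samples.
  `test_gene_pairs()` compares the observed double-carrier count against
  this expectation with an exact binomial test. The default is the
  upper-tail (enrichment) test, since excess co-occurrence is the
  hypothesis of interest; for the rare expectations involved the two-sided
  value coincides with it to reported precision, and a `two.sided` option
  is provided. Adjustment across the pair grid is its own BH family, and
  the unadjusted p-value is always reported alongside.
* **Edges**: `gene_pair_edges()` emits each group-3 sample's
  $\binom{|G|}{2}$ gene pairs with multiplicities — the tabular form of
  the usual carrier-sharing network figure (drawing it is out of scope).

The Fisher test, binomial tail and BH adjustment are delegated to the
standard library routines; the test suite checks each against an
independent oracle (full hypergeometric enumeration for every 2×2 table
with total ≤ 30; direct tail summation up to n = 10,000; the hand step-up
recursion on random lists up to length 1,000).

## The synthetic-cohort generator

`simulate_cohort()` produces a complete, schema-valid artifact set plus a
truth record. Its defaults emulate the scale of a real array-screening
study: 1,714 retained samples, a 78-gene panel (27 clinical + 51
extended-only, alternating dominant/recessive MOI), ~8 rare variants per
gene (~600 in total), per-variant carrier frequencies log-uniform between
the singleton frequency $1/(2n)$ and 0.5%, CADD-PHRED scores from a
two-component truncated normal mixture with most mass above 20 (as on a
deleteriousness-selected array), 22 designated duplicates with 0.3%
per-call discordance, 25 QC-metric failures and 5 sex-discordant samples.

Deliberate departures from realism, all documented because they matter for
interpreting test results:

* **Homozygosity is planted directly**: each carrier at a recessive gene
  is homozygous with probability `hom_fraction` (default 5%) rather than
  via Hardy–Weinberg, under which rare-variant homozygote counts would be
  ~0 at n ≈ 1,700 and group 3 would contain almost no recessive cases.
* **No linkage structure, no haplotypes, no realistic site-frequency
  spectrum, no phenotypes.** Carriers are independent Bernoulli draws per
  variant. The generator's carried-variant spectrum is denser than a real
  array's (where most designed variants are never observed), so synthetic
  prevalences — e.g. ≈38% group 3 at CADD 15 on the extended panel under
  the defaults — are of the right order for a deleteriousness-selected
  panel but are not matched to any published cohort's values.
* **MAF is set to carrier frequency / 2** — an allele-vs-carrier
  approximation, adequate because the filters only threshold it.
* An optional **planted gene pair** multiplies the two genes' joint
  carriage probability by a configured factor (capped at the smaller
  marginal, with a warning when the cap binds), preserving both marginals;
  `simulate_gene_loads()` exposes the same mechanism at the gene level for
  statistical calibration without simulating variants.

A single integer seed drives one RNG sub-stream per artifact (variants,
genotypes, defects, duplicates), so enabling duplicates never perturbs
genotype draws; outputs are bit-identical across runs for the same seed.

## Calibration, power, and problem sizes

The suite calibrates the pair test on independent-load cohorts of n = 400
group-3 samples over 20 genes with marginals 2–10%, 2,000 replicates: the
realised type-I rate at α = 0.05 is ~0.019 — conservative, as expected for
a discrete exact test at small expected counts — and is asserted to stay
below 0.05 plus three Monte-Carlo standard errors.

The power property plants one pair at 30× its product of ~1% marginals in
the same cohorts. Note the arithmetic of this regime: the planted joint
probability is 30 × 0.0001 = 0.003, so the expected double-carrier count
at n = 400 is 1.2, while ~7 of the 189 null pairs reach one double carrier
(p ≈ 0.04) per replicate. The planted pair therefore holds the strictly or
jointly smallest p-value in slightly under half of replicates — detection
at these margins needs larger cohorts or stronger enrichment, and the
corresponding test documents the measured recovery rate. This is a real
property of exact tests on singleton-scale counts, not an implementation
artifact: the same test attains p ≈ 3 × 10⁻⁷ on the acceptance-script
cohort, where the planted pair's marginals are several-fold larger.

Other fixed problem sizes, chosen to exercise every invariant while
keeping the default test run fast: 200 seeded cohorts of 30 samples for
the partition/monotonicity/nesting invariants; exhaustive 2×2 tables to
total 30 for the Fisher oracle; 10 duplicate pairs over 1,000 variants for
concordance recovery.

## Known limitations

* Compound heterozygosity is never inferred (no phase); recessive carriage
  requires an observed homozygote. This is conservative for group 3.
* X-linked and hemizygous inheritance are rejected, not modelled.
* DQC, relatedness and heterozygosity metrics are consumed as inputs; the
  package neither calls genotypes nor estimates kinship.
* Annotation (consequence, CADD, SIFT/PolyPhen, LOFTEE) is consumed, never
  computed, and is assumed already collapsed to the canonical transcript.
* The Wald interval is used deliberately despite its known poor coverage
  at extreme proportions; switch to `stats::binom.test` intervals downstream
  if coverage matters more than matching the plotted formula.
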