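---
title: "Methods: ultra-rare variant burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultra-rare variant burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`urvburden` implements a case–control analysis of ultra-rare variants
(URVs) for severe neurodevelopmental disease cohorts, built around the
idea that variants private to a single individual in a cohort — and absent
from large population panels — carry an interpretable signal of recent,
possibly deleterious mutation. The package covers the statistical pipeline
from an annotated, transcript-collapsed variant table to: per-class burden
odds ratios, gene-level collapsing tests, a de novo mutation (DNM)
enrichment model, tissue-expression ranking and power calculation. Read
alignment, variant calling, annotation (SnpEff/dbNSFP), ancestry PCA and
relatedness checks are out of scope; their outputs (consequence labels,
in-silico predictions, principal components, callable fractions) are
consumed as inputs.

## Rarity partitioning and QC

A variant is binned by its *qualifying* cohort allele count after removing
anything present in the selected external panels (ExAC/ESP/ToMMo flags, or
an arbitrary extra exclusion list such as a gnomAD-derived one): count 1 is
a singleton URV, 2 a doubleton, 3 a tripleton. A carrier call qualifies
only under the per-chromosome zygosity rules: autosomal and
pseudoautosomal heterozygotes; X-non-PAR heterozygotes in females and
47,XXY individuals; hemizygous (homozygous-call) X-non-PAR males; and
hemizygous Y calls in males. Allele counts are computed on the full
pre-QC cohort; individuals excluded later keep their contribution to the
rarity labels, matching the order of operations the counts were defined
under. Mitochondrial and unplaced contigs are excluded with a warning.

Per-individual singleton coding counts are screened with an iterative
two-sided Grubbs test (`grubbs_outliers()`): the most extreme count is
removed while its P value, `2N * P(T[N-2] > t)`, stays below `alpha`
(default 0.001 — equivalently, a critical value from the t distribution at
`alpha/(2N)`). Iteration continues until no value is significant, since a
single pass cannot remove multiple gross outliers; a single-pass mode is
available via `iterate = FALSE`. The procedure sees only counts, never
phenotype labels.

## Functional taxonomy

Seven mutually exclusive leaf classes: `null` (HIGH-impact
loss-of-function), `cd_missense` (missense called damaging by **all
seven** predictors: SIFT, PolyPhen-2 HumVar/HumDiv, LRT, MutationTaster,
MutationAssessor, PROVEAN), `other_moderate`, three synonymous subclasses
(`sr_synonymous` within 3 bp of an exon–intron boundary,
`fcdhs_synonymous` inside frontal-cortex DNase I hypersensitive sites,
`other_synonymous`) and `noncoding`. Protein-protein-contact and
start-lost consequences are moved from the HIGH-impact group into the
Moderate group before the consensus test. An `NA` from any predictor
disqualifies the consensus — a strict reading of "all seven algorithms"
that sends unscored inframe indels to `other_moderate`.

A synonymous variant can satisfy both the splice-region and the DHS rule.
The leaves must partition, so a precedence is required; the package
defaults to splice-region first (`synonymous_precedence = "sr"`), on the
view that a splice-region position has a concrete mechanistic reading that
dominates a regulatory-context annotation. The opposite precedence is one
argument away, and the choice only reassigns the small overlap set.
Damaging URVs (dURVs) are `null` + `cd_missense`.

## Burden regression

`fit_burden()` fits a maximum-likelihood logistic regression of
case/control status on the per-individual count plus covariates (sex coded
0/1, proportion of callable loci, ten principal components; configurable).
Inference on the count coefficient is Wald-based — the odds ratio per
additional URV with its 95% CI and two-sided P — matching the standard
output conventions for this analysis; a likelihood-ratio P is available
via `test = "lrt"`. IRLS runs with tolerance 1e-8 and up to 100
iterations; non-convergence is flagged on the result, not thrown.

When every carrier of the tested class sits in one phenotype group the
coefficient is unidentified (complete separation). Rather than dropping
the test, one variant is added to the count of a single individual of the
opposite group — deterministically the lexicographically first id, so
results are reproducible — the model is refit, and the P value is flagged
as an upper bound (`p_is_upper_bound`). This mirrors the pseudo-count
convention used for exclusively-case variant classes and deliberately errs
conservative. 47,XXY individuals keep their manifest sex in the regression;
the karyotype matters only for genotype qualification.

Families of tests built with `burden_manifest()` are corrected with
Bonferroni and Benjamini–Hochberg via `stats::p.adjust()` over the
manifest's family size.

## Gene-based collapsing and permutation overlap

`gene_burden_scan()` compares, per gene, the number of cases versus
controls carrying at least one qualifying dURV, with a two-tailed Fisher
exact test defined by the probability-mass rule (the sum of hypergeometric
probabilities no larger than the observed table's). The implementation
evaluates the hypergeometric mass directly so the permutation engine can
cache the P value as a function of the case-carrier count — per gene the
carrier total is fixed under label permutation, making each shuffle a
table lookup. Genes with zero carriers in the analysed subset are dropped:
they can never be significant. Odds ratios are cross-product ratios with
0.5 added to every cell when any cell is zero (reporting only). Flags mark
exome-wide (`p < 0.05 / 20000 = 2.5e-6`) and nominal
(`2.5e-6 <= p < 0.05`) significance.

`overlap_permutation()` shuffles case–control labels (group sizes
preserved exactly), re-runs the scan, and records the fraction of
nominally significant genes overlapping a reference set. The shuffled
scans reuse the same nominal band as the observed scan. The empirical P is
the plain fraction of iterations with an overlap fraction at least as
large as observed — not `(r+1)/(n+1)` — and is reported as
`< 1/iterations` when no iteration reaches it. All draws come from one R
RNG stream seeded once from the master seed; the same seed reproduces the
result exactly.

## DNM enrichment model

For a gene with per-haploid consequence-specific mutation rates, the null
rate is `mu_nonsense + mu_frameshift + mu_splice` and the
consensus-damaging missense rate is `mu_missense * 203/1252`, the fraction
of de novo missense mutations meeting the seven-algorithm consensus in
unaffected-sibling control trios. The expected damaging-DNM count in `n`
trios is `lambda = (mu_null + mu_cd) * 2 * n`; the test P is the Poisson
upper tail `P(X >= k)`, evaluated through `ppois()`'s regularized
incomplete-gamma tail (stable for the tiny `lambda` values per-gene rates
produce). Bonferroni corrections are applied over the number of testable
genes (defaulting conventionally to genes carrying at least one dURV) and
over the number of clinical subtypes, capped at 1 only — published
corrected values above 0.05 remain informative. `invert_lambda()` solves
`P(X >= k; lambda) = p` by bracketed root finding on the log scale
(relative tolerance better than 1e-10), which lets a published tail
probability at one cohort size be transferred to another, since `lambda`
is linear in trio count.

## Tissue-expression ranking

Expression-derived gene sets use a strict threshold (`TPM > 10`);
specificity-index (pSI) sets are accepted as precomputed inputs, since
that algorithm belongs to its own publication. Each tissue's set is run
through the same covariate-adjusted burden fit, and tissues are ordered by
the directional four-tier rule: enriched (OR > 1) tissues ascending in P,
then depleted tissues descending in P — equivalently descending signed z.
Tissues with OR exactly 1 close the enriched block (the boundary case is
not otherwise defined); ties break by tissue name so the order is total
and deterministic. The brain-versus-other contrast on the resulting ranks
uses a two-tailed Wilcoxon rank-sum test, exact when both groups have at
most 25 tissues (ranks are untied by construction), normal approximation
with continuity correction otherwise.

## Power calculation

`logistic_power()` gives the large-sample power of the Wald z-test for the
slope of a logistic regression with a normally distributed predictor, in
the "odds ratio at one SD" parameterization (`beta = log(or_1sd)` on the
standardized predictor, intercept `logit(p0)`); correlation with other
covariates deflates the effective sample size by `1 - R^2`. The slope's
asymptotic variance under the alternative is computed by numerical
integration of the expected information over the predictor distribution.
Two variants are provided: the default uses the alternative variance in
both the drift and critical-value terms; `variance = "null"` anchors the
critical value on the null variance `1/(p0 (1 - p0))`. The default was
selected by validating both against the published three-alpha power
triplet for this design and against a Monte-Carlo rejection-rate oracle
(simulate, fit, count rejections); the two variants differ by under two
percentage points everywhere we examined. `pooled_sd()` supplies the
two-group pooled SD used to put a count difference on the per-SD scale.

# The synthetic cohort generator

`simulate_cohort()` emulates the data structure the analysis assumes, with
defaults set to the study conditions: 743 cases / 2366 controls;
per-individual singleton coding URV counts approximately normal with mean
54.4 and SD 8.2 (a per-individual gamma multiplier supplies the small
overdispersion beyond Poisson); the published functional-class mixture
(7.1% null, 64.5% Moderate with 11.3% of those consensus-damaging, 28.4%
synonymous split over its three subclasses, plus noncoding variants in the
published ratio to coding); small per-URV odds ratios (default 1.07 for
dURVs outside the known genes, 1.05 for the likely-functional synonymous
classes) and a large one (default 10) for dURVs in a 58-gene known set.
Case status comes from a logistic liability on the weighted counts, with
the intercept solved so the expected case fraction matches the configured
group sizes — a prospective construction that preserves the odds ratios
the burden regression estimates. Covariates are drawn but carry no effect
by default, so their coefficients are genuinely null.

Gene "lengths" are lognormal weights that govern variant placement; each
gene's 5' 30% doubles as its DNase-hypersensitive region, and the emitted
`GRanges` index is what the classifier consumes, so DHS-synonymous calls
round-trip. A configurable fraction of autosomal coding variants is
promoted to doubletons/tripletons (the draw mean is inflated by the
promotion fraction so singleton counts stay on target), and extra
panel-flagged variants exercise the external-database exclusion.
`materialize_variants = FALSE` skips the variant table and returns only
counts and ground truth — the path used for calibration and
coverage studies, where thousands of cohorts are drawn.

What the generator does **not** emulate: linkage and site-spectrum
realism (alleles are placeholder single bases), population substructure
beyond Gaussian PCs, relatedness, batch effects in callable fraction, and
the heavy-tailed count outliers real exomes show. Passing calibration and
recovery tests therefore demonstrates correctness of the statistical
machinery under the stated model, not robustness to artefacts the QC
steps exist to catch.

# Numerical and testing choices

- Coordinates: variant positions are 1-based (VCF convention), intervals
  0-based half-open (BED) converted once at read time; chromosome names
  are stripped of the `chr` prefix at ingestion. Multi-allelic rows must
  be pre-split; that is a schema error, not a silent fix.
- Fisher ties: tables with probability equal to the observed one are
  included using a relative tolerance of 1e-7, the standard guard against
  floating-point noise in equal-mass tables.
- The Grubbs statistic beyond its attainable maximum (degenerate
  denominator) is treated as P = 0; constant vectors yield no outliers.
- `invert_lambda()` initializes from the series approximation
  `lambda ~ (p k!)^(1/k)` and expands the bracket geometrically before
  root finding.
- Test problem sizes: module tests run cohorts of 80–250 cases with
  ~150 genes; calibration uses 220 null replicates and coverage 120
  replicates per odds ratio at the full 743/2366 group sizes via the
  counts-only path. Recovery of the strongest ratio (1.5) is sensitive to
  sample size — Wald intervals undercover visibly at a quarter of the
  study size — which is why coverage is checked at study scale.
- The classifier's and generator's shared DHS convention, and the
  promotion-compensated draw mean, are covered by tests that compare the
  realized singleton mixture with the configured proportions.

# Known limitations

- Firth or exact logistic regression is not provided; the pseudo-count
  rule is a reporting convention for separated classes, not an unbiased
  estimator.
- The collapsing test treats carriers binarily; weighted or
  count-retaining gene tests (e.g. SKAT-type) are out of scope.
- HGMD phenotype strata and pSI tissue-specific sets are consumed as
  labels/inputs; the package does not reproduce those resources.
- The power formula is asymptotic; at small samples or extreme baseline
  probabilities the Monte-Carlo oracle in the test suite is the better
  guide.

# A minimal worked flow

```{r example}
library(urvburden)

sim <- simulate_cohort(sim_config(), seed = 1)
co <- partition_by_rarity(sim$cohort)
co <- classify_variants(co, dhs = sim$dhs)
co <- exclude_count_outliers(co)

counts <- count_urvs(co, class = "durv",
                     exclude_genes = sim$truth$known_genes)
fit_burden(counts, co)

scan <- gene_burden_scan(co, exclude_genes = sim$truth$known_genes)
head(scan)
overlap_permutation(co, reference_set = sim$truth$known_genes,
                    iterations = 1000, seed = 2)
```
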