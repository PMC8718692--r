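---
title: "Methods: m6A regulator subtyping and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A regulator subtyping and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, how the synthetic cohorts
used for validation are built, and where the design was genuinely open.

## The analysis in one paragraph

Bulk expression cohorts are merged into a meta-cohort on their common
gene space and quantile-normalized. Samples are clustered on the panel
of 24 m6A regulator genes by resampling consensus clustering; the three
resulting subtypes ("m6A clusters") are characterized by single-sample
enrichment of immune and pathway gene sets and by survival. Genes
differential between *all three* cluster pairs (moderated t, raw
p < 0.001) form the m6A phenotype signature; univariate Cox regression
keeps its prognostic members (Wald p < 0.05). PCA on the z-scored
prognostic signature yields the per-sample m6A score — the sum of the
sample's projections on components 1 and 2 — which is dichotomized at a
maximally selected log-rank cutpoint and crossed with tumor mutation
burden (TMB) for combined survival strata.

## Meta-cohort assembly

FPKM cohorts are rescaled to TPM per sample,
`tpm = fpkm / colSums(fpkm) * 1e6`, which is scale-invariant per column;
abundance units then go through `log2(x + 1)`. Array cohorts declared as
`log2intensity` are taken as-is: the subsequent quantile normalization
makes the two scales commensurable. Gene spaces are intersected — with
the built-in panel this is how a 24-regulator panel shrinks to the 19
regulators shared by two platforms — and normalization is applied
**once, after merging**, so all cohorts are pulled to a single reference
distribution. The alternative (normalize per cohort, then merge) leaves
cohort-specific distributions in place; with no explicit batch model in
scope, the single reference distribution is the more conservative
choice. Ties within a sample receive the mean of the reference values
across their rank span (the behaviour of limma's quantile engine, which
this package calls).

Assumptions: cohorts share a gene-symbol namespace; no residual batch
structure beyond what quantile normalization removes. ComBat-style
correction is deliberately out of scope.

## Consensus clustering

`consensus_cluster()` follows the Monti resampling recipe: for each
candidate k, `reps` subsamples of `ceiling(p_item * n)` samples are
clustered (average-linkage hierarchical clustering on 1 − Pearson
correlation between samples by default) and the consensus matrix records
the fraction of co-clusterings among co-samplings. Final labels come
from hierarchical clustering of 1 − consensus, never from a single
repetition. Because items (samples) are resampled while features stay
fixed, the sample–sample distance is computed once and subset per draw —
identical results, far less work. Per-repetition seeds are
counter-based (`seed + rep`), so results do not depend on evaluation
order.

Defaults: `reps = 1000`, `p_item = 0.8`, hierarchical/average/Pearson —
the standard settings of the consensus-clustering ecosystem; all
configurable.

**Choosing k.** Two rules are provided. The *delta-area* rule (default)
picks the largest k whose relative increase in the consensus-CDF area
exceeds 0.1 — the classic elbow criterion. The *PAC* rule picks the k
minimising the proportion of ambiguous clustering
(`CDF(0.9) − CDF(0.1)`), ties to the smaller k, and warns when the
minimum PAC exceeds 0.5 (no stable clustering anywhere). PAC is the
sharper diagnostic in noisy settings but has a structural blind spot
that decided the default: when three clean clusters are present, the
2-cluster partition that merges the two closest of them is *also*
perfectly stable, so PAC ties at 0 for k = 2 and k = 3 and its tie rule
returns 2. The delta-area elbow still sees the large jump from k = 2 to
k = 3 and the flat region after it. Both diagnostics are always
reported.

## Single-sample enrichment (ssGSEA)

The score is the sum variant: rank genes by expression (descending, ties
broken by lexicographic gene id so results are deterministic), weight
in-set genes by `rank_value^alpha` with `rank_value = n − position + 1`,
and accumulate the difference between the weighted in-set ECDF and the
unweighted out-set ECDF over all positions. Only ranks enter, so any
strictly increasing transform of a sample's expression leaves its scores
unchanged — the property that makes cross-unit comparisons defensible.
`alpha = 0.25` is the conventional default; `alpha = 0` weights all
in-set positions equally. When a collection is scored with
`normalize = TRUE`, the whole matrix is shifted/scaled by its global
range to [0, 1], the convention used when 23 immune signatures are read
off one scale.

Immune and stromal infiltration scores are ssGSEA scores on the two
signatures. The original two-signature estimator adds an affine "tumor
purity" transform whose constants are data-licensed; since every
downstream use here is a group comparison, the rank-preserving ssGSEA
scores carry the same information and are reported as relative scores.
Pathway activity uses the same engine over user-supplied GMT sets; the
Gaussian-kernel density step of GSVA is intentionally not reproduced.

## Moderated-t differential expression

Per gene, a two-group comparison on log-scale expression with
empirical-Bayes variance shrinkage: the pooled variance `s²_g` on
`d_g = n₁ + n₂ − 2` df is shrunk to
`s̃²_g = (d₀·s₀² + d_g·s²_g)/(d₀ + d_g)`, with the prior `(d₀, s₀²)`
estimated by the method of moments on `log s²_g` (digamma/trigamma
closed forms; the trigamma inverse is solved by Newton iteration). The
moderated t has `d₀ + d_g` df. `prior_df = 0` recovers the ordinary
equal-variance t-test; `prior_df = Inf` forces every posterior variance
to `s₀²`. Zero-variance genes are excluded from the moment fit and
shrunk with `s²_g = 0` in the posterior formula. When the moment
estimator of the prior variance of `log s²` is non-positive — i.e. the
observed spread is no larger than sampling noise — `d₀ = Inf` is the
limit estimate. The test suite cross-checks the whole fit against an
independent implementation of the same formulas (limma's `eBayes`) to
machine precision in the finite-`d₀` regime.

Phenotype DEGs are the genes with raw p < 0.001 in a contrast — raw, not
adjusted, as a deliberate reproduction of the published rule; a flag
switches to BH if desired. The signature is the intersection of the
three pairwise contrast lists (the center of the three-set Venn
diagram). No log-fold-change threshold accompanies the p cut, since none
is stated for the original analysis.

## Survival engine

Kaplan–Meier estimation, log-rank tests and univariate Cox regression
delegate to the survival package (Efron tie handling, Wald inference
from the observed information); five-year rates are read off the fitted
curve, never refitted on truncated data. Monotone-likelihood fits
(perfect separation) are flagged `converged = FALSE`.

The maximally selected cutpoint scans the midpoints of consecutive
distinct score values, keeps those leaving at least `ceiling(minprop*n)`
samples on each side (`minprop = 0.1`, the documented default of the
surv-cutpoint convention), computes the standardized two-group log-rank
statistic `|O − E|/sqrt(V)` at each candidate, and returns the argmax
(ties to the lower cut). The selection-bias-adjusted p-value of the
maximally selected statistic is *not* computed: the workflow stratifies
by the cutpoint and reports the ordinary log-rank on the resulting
groups, so the standardized statistic is exposed for transparency only.
A worthwhile caution for users: that downstream log-rank p-value
inherits the optimism of the selection.

One identity worth recording: under Efron tie handling, duplicating
every subject does **not** leave the Cox estimate unchanged (tie
multiplicities double and the within-tie averaging changes). The test
suite therefore validates the estimate against a brute-force Efron
partial likelihood on both the original and the duplicated instance
rather than asserting invariance.

## The m6A score

Signature genes are z-scored across samples; the samples × genes
standardized matrix is decomposed by SVD; components 1 and 2 are kept.
Each component's sign is fixed so its loading sum is non-negative
(tie: first nonzero loading positive) — without a convention the sign is
backend-dependent and scores would not reproduce. The per-sample score
is the sum of the two projections, each projection a sum over signature
genes of z-scored expression times loading. The published formula
("∑ (PC1ᵢ + PC2ᵢ)" with *i* indexing signature-gene expression) is read
this way — per-sample projections summed over genes — the construction
of the antecedent signature-score literature; the alternative reading
(sum of loadings) is a model constant and degenerate as a per-sample
score. A sample at the training gene-wise means scores exactly 0, and
adding a constant to any gene's expression leaves scores unchanged.

TMB is the raw count of nonsilent mutation records per sample — no
per-megabase normalization is applied by default because none is stated
for the original analysis; `per_mb` enables it. The TMB high/low split
reuses the maximally selected cutpoint machinery unless a fixed
threshold is supplied (the original grouping rule is unstated; this
keeps both strata prognostically meaningful by construction). The
score × TMB strata are the four crossings (H/H, H/L, L/H, L/L), tested
globally and pairwise (BH-adjusted).

## The synthetic cohort generator

`generate_m6a_data()` draws what the pipeline assumes, with ground truth
exposed:

- **Clusters**: 3 × 100 samples (A, B, C). A latent quality score is
  +1 in cluster B, 0 in C, −1 in A, plus N(0, 0.3) per-sample noise.
- **Expression** (log2-like scale, noise SD 1): per-gene baselines
  N(6, 1.5); the 24 regulators split into three blocks of 8, block j
  upshifted by 2 SD in cluster j; 50 of 80 signature genes track the
  latent score with slope 2 SD (so they differ in every pairwise
  contrast and rise toward cluster B); 30 null signature genes and 100
  background genes; 23 disjoint immune signatures of 20 genes, each with
  a per-sample co-expression factor N(0, 0.6) and a +1 SD shift in
  cluster C, plus a stromal block with the same construction.
- **Survival**: exponential event times with rates 0.020 / 0.008 / 0.012
  per month for A / B / C (median survival ≈ 35 / 87 / 58 months;
  cluster A worst, B best), censored by an independent
  Uniform(0, 120)-month administrative time; "no censoring" is a config
  flag used by the moment-recovery tests. The uniform reading of the
  administrative horizon yields a realistic ~40% censoring fraction; a
  fixed 120-month cutoff would censor almost nobody at these rates.
- **Mutations**: nonsilent counts per sample are negative binomial with
  mean 8 in the low-latent half and 4 in the high half (dispersion 2) —
  high score ⇒ low TMB — plus Poisson silent extras; genes drawn from a
  200-gene pool plus the regulators.
- **CNV**: iid 5-level calls on the regulator panel with 15% gain and
  15% loss mass (split 3:1 between single- and double-copy events).

Everything is deterministic under the seed, which is set locally and
restored (the generator never clobbers the session RNG).

What the generator does **not** emulate — and hence what passing tests
cannot certify about real cohorts: real marginal distributions and
gene–gene correlation structure beyond the planted blocks, batch
effects, informative censoring, mutation hotspots and signatures,
copy-number segments (calls are iid per cell), and any coupling between
immune infiltration and survival. Recovery results on this generator
validate the *machinery* (identifiability under the assumed model, error
calibration, determinism), not clinical performance.

## Validation design and problem sizes

The test suite pairs every engine with an independent oracle: an
exhaustive ECDF walk for ssGSEA (universes ≤ 8 genes, tolerance 1e−12),
limma for the moderated t, `survdiff`-based brute force for the cutpoint
search, a literal pair-counting ARI, a quadratic step-up BH, and a
brute-force Efron partial likelihood for Cox. Calibration suites use
sizes chosen to make their bands meaningful at interactive runtimes:
20 × 1000 null genes for the p < 0.001 count (binomial 99% band),
500 null log-rank replicates at n = 100/arm (type-I in [0.03, 0.07]),
200 Cox replicates at n = 500 (±3 se coverage ≥ 95%), 20 consensus
recovery seeds at the generator defaults (k = 3 and ARI ≥ 0.9 required
in ≥ 18), and 10 end-to-end pipeline seeds (log-rank p < 0.01 for the
score split and negative score–TMB Spearman correlation required in
≥ 9).

## Known limitations

- No multivariate Cox, competing risks or time-varying covariates; the
  prognostic filter is univariate by design.
- The cutpoint's post-selection inference is not adjusted (see above).
- Quantile normalization is the only cross-cohort harmonization; cohorts
  with strong batch structure need external correction first.
- The ssGSEA normalization couples all sets scored in one call through
  the global range; score *differences* across calls are not comparable.
- Consensus clustering at k = 2 can be perfectly stable in the presence
  of finer true structure; inspect the full diagnostics table rather
  than any single rule's answer.
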