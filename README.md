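# m6ascore

Consensus molecular subtyping and prognostic scoring of lung
adenocarcinoma (LUAD) from the expression of N6-methyladenosine (m6A)
RNA-methylation regulators.

m6A modification is controlled by three classes of regulator proteins —
*writers* (methyltransferases such as METTL3/14/16, WTAP, KIAA1429),
*erasers* (the demethylases FTO and ALKBH5) and *readers* (binding
proteins such as the YTHDF/YTHDC families, IGF2BPs, HNRNPs). Their joint
expression pattern stratifies LUAD tumors into subtypes that differ in
prognosis, immune-cell infiltration and mutational burden. This package
implements that analysis as a tested, reusable pipeline:

- a curated **registry of 24 m6A regulators** (10 writers, 2 erasers,
  12 readers);
- **meta-cohort assembly**: FPKM→TPM conversion
  (`tpm[g,s] = fpkm[g,s] / Σ_g fpkm[g,s] × 10⁶`), log2 transformation,
  gene-space intersection across cohorts and quantile normalization;
- **consensus clustering** of samples on the regulator panel (Monti-style
  item resampling, 1000 repetitions by default, average-linkage
  hierarchical clustering on 1 − Pearson distance), with k selection by
  the relative CDF-area increase (delta area) or the proportion of
  ambiguous clustering (PAC);
- **single-sample gene-set enrichment (ssGSEA)** — the rank-weighted
  sum-of-ECDF-differences variant with exponent α = 0.25 — for
  immune-cell infiltration (23 cell types), pathway activity and
  immune/stromal scores, plus hypergeometric over-representation tests;
- **moderated-t differential expression** with empirical-Bayes variance
  shrinkage `s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`, the three pairwise
  cluster contrasts at raw p < 0.001, and their intersection (the m6A
  phenotype signature);
- a **survival engine**: Kaplan–Meier curves, log-rank tests, univariate
  Cox regression (Efron ties) and maximally selected rank-statistic
  cutpoints;
- the **m6A score**: per-gene z-scoring, PCA of the prognostic signature,
  and `score(s) = PC1(s) + PC2(s)` per sample, stratified at a
  survival-driven cutpoint;
- **tumor mutation burden** (nonsilent counts from MAF-lite tables),
  score × TMB strata, mutation/CNV frequency summaries, Spearman
  correlations and rank-based group tests;
- a **synthetic-data generator** that emulates the meta-cohort's
  statistical structure (3 latent clusters, cluster-dependent survival,
  score-linked negative-binomial mutation counts, block-structured
  immune signatures) with exposed ground truth for parameter-recovery
  testing.

## Worked example

```r
library(m6ascore)

bundle <- generate_m6a_data(seed = 7)           # synthetic LUAD-like cohort
cfg <- run_config(k_range = 2:6, reps = 1000, seed = 7, outdir = "m6a_out")
run <- run_m6a_pipeline(bundle$expression, bundle$clinical,
                        mutations = bundle$mutations,
                        gene_sets = bundle$gene_sets, config = cfg)
print(run)
```

```
m6ascore 0.1.0 pipeline run: 8 stages
  m6A clusters: k = 3 (100/100/100)
  phenotype signature: 68 DEGs, 60 prognostic
  m6A score groups: 257 high / 43 low
  log-rank (m6a_cluster): chi2 = 21.72, p = 1.92e-05
  log-rank (gene_cluster): chi2 = 20.02, p = 7.67e-06
  log-rank (score_group): chi2 = 22.93, p = 1.68e-06
  log-rank (stratum): chi2 = 26.94, p = 6.05e-06
```

The consensus diagnostics show why k = 3 is selected — the CDF area
jumps by 50% from k = 2 to k = 3 and is flat afterwards, and PAC drops
to 0 at k = 3:

```r
print(run$consensus)
```

```
consensus clustering: 1000 reps, p_item = 0.80, hclust/pearson
 k cdf_area delta_area    pac
 2   0.4459     0.4459 0.4459
 3   0.6689     0.5002 0.0000
 4   0.6722     0.0049 0.0090
 5   0.6766     0.0067 0.0147
 6   0.6814     0.0070 0.0190
chosen k = 3
```

The three recovered clusters match the generator's planted subtypes
exactly (`truth_report(bundle, run$m6a_cluster)$ari` is 1.0). The 68
genes differential between all three cluster pairs shrink to 60
prognostic genes under univariate Cox filtering (p < 0.05); PCA on that
signature gives the per-sample m6A score:

```r
print(run$score_model)
#> PCA score model: 60 genes; PC1/PC2 explain 62.7% / 5.6% of variance

ct <- correlate(run$score_table$m6a_score, run$score_table$tmb)
#> Spearman(m6A score, TMB): rho = -0.236, p = 3.5e-05
```

High-score samples live longer (log-rank p = 1.7e-06 above) and carry
fewer nonsilent mutations (negative score–TMB correlation), matching the
structure the generator plants: cluster-B-like samples have the lowest
hazard, the highest latent score and the lowest mutation rate.

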