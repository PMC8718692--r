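Package: m6ascore
Title: m6A Regulator Modification Patterns, Immune Landscape and
    Prognostic Scoring in Lung Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Consensus molecular subtyping of lung adenocarcinoma on a
    curated 24-gene panel of N6-methyladenosine (m6A) regulators, with
    the downstream analyses that characterise the subtypes: single-sample
    gene-set enrichment (ssGSEA) for immune-cell infiltration and pathway
    activity, empirical-Bayes moderated-t differential expression and the
    three-way DEG intersection that defines the m6A phenotype signature,
    Kaplan-Meier / log-rank / univariate Cox survival analysis with
    maximally selected rank-statistic cutpoints, a PCA-based per-sample
    m6A score, tumor mutation burden stratification, and a synthetic-data
    generator that emulates the statistical structure of the meta-cohort
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    limma,
    mclust
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
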