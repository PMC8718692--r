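# PCA score model, TMB, strata, frequency summaries, correlation and
# group comparisons.

test_that("the PCA model reproduces an independent eigendecomposition", {
  set.seed(41)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  model <- fit_score_model(x, rownames(x))
  # oracle: eigenvectors of the gene-gene correlation matrix
  ev <- eigen(cor(t(x)))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (sum(v) < 0) v <- -v
    expect_equal(abs(unname(model$rotation[, j])), abs(v), tolerance = 1e-8)
    expect_equal(unname(model$rotation[, j]), v, tolerance = 1e-8)
  }
  expect_equal(sum(model$rotation[, 1]^2), 1)
  expect_gte(model$explained[1], model$explained[2])
})

test_that("rank-1 structure loads PC1 with almost all variance", {
  set.seed(42)
  f <- rnorm(50)
  x <- outer(rep(1, 10), f) * 3 + matrix(rnorm(500, sd = 0.01), 10)
  dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:50))
  model <- fit_score_model(x, rownames(x))
  expect_gt(model$explained[1], 0.99)
})

test_that("scores are centered, shift-invariant and fail on missing genes", {
  set.seed(43)
  x <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  model <- fit_score_model(x, rownames(x))
  # a sample at the training gene-wise means scores 0
  mean_sample <- matrix(model$center, ncol = 1,
                        dimnames = list(model$genes, "m"))
  expect_equal(unname(m6a_score(model, mean_sample)), 0, tolerance = 1e-12)
  # training scores are centered overall
  expect_equal(mean(m6a_score(model, x)), 0, tolerance = 1e-10)
  # adding a constant to one gene does not change scores (z-scoring)
  x2 <- x; x2["g1", ] <- x2["g1", ] + 50
  model2 <- fit_score_model(x2, rownames(x2))
  expect_equal(m6a_score(model2, x2), m6a_score(model, x), tolerance = 1e-8)

  expect_error(m6a_score(model, x[1:3, ]), "missing model gene")
  expect_identical(predict(model, x), m6a_score(model, x))
})

test_that("cluster-B-like samples receive the highest m6A score", {
  b <- generate_m6a_data(m6a_sim_config(n_per_cluster = c(60, 60, 60)), seed = 44)
  model <- fit_score_model(b$expression, b$truth$markers)
  sc <- m6a_score(model, b$expression)
  means <- tapply(sc, b$truth$cluster, mean)
  expect_equal(names(which.max(means)), "B")
  expect_equal(names(which.min(means)), "A")
  kw <- group_compare(sc, b$truth$cluster, test = "kruskal")
  expect_lt(kw$p_value, 0.001)
})

test_that("half-cohort models track the full model on unseen samples", {
  b <- generate_m6a_data(m6a_sim_config(n_per_cluster = c(170, 170, 160)), seed = 45)
  x <- b$expression
  set.seed(46)
  half <- sample(ncol(x), ncol(x) / 2)
  full <- fit_score_model(x, b$truth$markers)
  m1 <- fit_score_model(x[, half], b$truth$markers)
  m2 <- fit_score_model(x[, -half], b$truth$markers)
  # each half-trained model reproduces the full model's ranking on the
  # samples it never saw
  expect_gt(cor(m6a_score(m1, x[, -half]), m6a_score(full, x[, -half])), 0.99)
  expect_gt(cor(m6a_score(m2, x[, half]), m6a_score(full, x[, half])), 0.99)
})

test_that("TMB counts nonsilent records with optional per-Mb scaling", {
  mut <- data.frame(sample = c("P1", "P1", "P1"),
                    gene = c("KRAS", "TP53", "EGFR"),
                    variant_class = factor(c("missense", "missense", "silent"),
                                           levels = m6ascore:::.VARIANT_CLASSES))
  expect_equal(unname(tmb_per_sample(mut)), 2)
  expect_equal(unname(tmb_per_sample(mut, nonsilent_only = FALSE)), 3)
  expect_equal(unname(tmb_per_sample(mut, per_mb = 38)), 2 / 38)
  expect_warning(tmb <- tmb_per_sample(mut, samples = c("P1", "P2")), "absent")
  expect_equal(unname(tmb), c(2, 0))
})

test_that("generated TMB separates score halves and correlates negatively", {
  b <- generate_m6a_data(m6a_sim_config(n_per_cluster = c(100, 100, 100)), seed = 47)
  tmb <- suppressWarnings(tmb_per_sample(b$mutations, samples = b$clinical$sample))
  grp <- b$truth$tmb_group
  w <- stats::wilcox.test(tmb[grp == "low"], tmb[grp == "high"], alternative = "greater")
  expect_lt(w$p.value, 0.01)
  ct <- correlate(b$truth$latent_score, tmb)
  expect_lt(ct$rho[1, 1], 0)
  expect_lt(ct$p_value[1, 1], 0.01)
})

test_that("combined strata put the worst survival in low-score/low-TMB", {
  set.seed(48)
  n <- 400
  score_group <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  tmb_group <- factor(sample(c("low", "high"), n, TRUE), levels = c("low", "high"))
  protect <- 0.5 * (score_group == "high") + 0.5 * (tmb_group == "high")
  tm <- rexp(n, 0.03 * exp(-protect))
  ev <- rep(1L, n)
  res <- combine_strata(score_group, tmb_group, tm, ev)
  expect_setequal(levels(res$stratum), c("H/H", "H/L", "L/H", "L/L"))
  km <- km_fit(tm, ev, res$stratum)
  five_yr <- vapply(km, km_rate_at, numeric(1), horizon = 60)
  expect_equal(names(which.min(five_yr)), "L/L")
  expect_equal(nrow(res$pairwise), 6L)
  expect_true(all(res$pairwise$padj >= res$pairwise$p_value))

  # an empty stratum is dropped with a warning, leaving a 3-group test
  sg <- factor(rep("high", 60), levels = c("low", "high"))
  tg <- factor(sample(c("low", "high"), 60, TRUE), levels = c("low", "high"))
  expect_warning(res3 <- combine_strata(sg, tg, rexp(60), rbinom(60, 1, 0.9)),
                 "empty stratum")
  expect_lte(nlevels(res3$stratum), 2L)
})

test_that("mutation frequency counts samples once per gene", {
  mut <- data.frame(sample = c("P1", "P1", "P2", "P3"),
                    gene = c("ZC3H13", "ZC3H13", "ZC3H13", "KIAA1429"),
                    variant_class = factor(c("missense", "nonsense", "missense", "silent"),
                                           levels = m6ascore:::.VARIANT_CLASSES))
  mf <- mutation_frequency(mut, c("ZC3H13", "KIAA1429", "CBLL1"), n_samples = 4)
  expect_equal(mf$count, c(2, 0, 0))  # silent hit does not count; P1 counts once
  expect_equal(mf$percent, c(50, 0, 0))
  expect_equal(attr(mf, "altered_fraction"), 2 / 4)

  empty <- mutation_frequency(mut[0, ], c("ZC3H13"), n_samples = 4)
  expect_equal(empty$count, 0)
})

test_that("CNV frequencies count gains and losses per gene", {
  cnv <- matrix(c(1L, -1L, 0L, 2L,
                  0L, 0L, 0L, 0L), 2, 4, byrow = TRUE,
                dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  cf <- cnv_frequency(cnv)
  expect_equal(cf$gain_freq, c(0.5, 0))
  expect_equal(cf$loss_freq, c(0.25, 0))
  expect_true(all(cf$gain_freq + cf$loss_freq <= 1))
})

test_that("Spearman correlation hits the monotone extremes and flags constants", {
  x <- 1:20
  expect_equal(correlate(x, exp(x / 3))$rho[1, 1], 1)
  expect_equal(correlate(x, -x^3)$rho[1, 1], -1)
  expect_warning(ct <- correlate(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(ct$rho[1, 1]))
})

test_that("group comparisons behave at the null and under shift", {
  set.seed(49)
  v <- rnorm(100)
  same <- group_compare(c(v, v), rep(c("a", "b"), each = 100))
  expect_gt(same$p_value, 0.9)

  shifted <- group_compare(c(rnorm(50), rnorm(50) + 1), rep(c("a", "b"), each = 50))
  expect_lt(shifted$p_value, 0.01)

  # Kruskal-Wallis on two groups is the chi-square form of the Wilcoxon
  vals <- rnorm(60); lab <- rep(c("a", "b"), 30)
  kw <- group_compare(vals, lab, "kruskal")
  wx <- group_compare(vals, lab, "wilcoxon")
  expect_equal(kw$p_value, wx$p_value, tolerance = 1e-10)

  expect_error(group_compare(1:5, c("a", "a", "a", "a", "a")), "2 non-empty")
})
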