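# Moderated-t differential expression, its shrinkage limits, calibration
# and the contrast intersection.

sim_two_group <- function(G = 200, n = 6, n_true = 0, effect = 0, het = TRUE, seed = 1) {
  set.seed(seed)
  sds <- if (het) sqrt(1 / rgamma(G, shape = 3, rate = 3)) else rep(1, G)
  x <- matrix(rnorm(G * 2 * n, sd = rep(sds, 2 * n)), G,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:(2 * n))))
  if (n_true > 0) x[1:n_true, (n + 1):(2 * n)] <- x[1:n_true, (n + 1):(2 * n)] + effect
  list(x = x, groups = rep(c("a", "b"), each = n), true = rownames(x)[seq_len(n_true)])
}

test_that("shrinkage limits recover the ordinary t and the full pool", {
  d <- sim_two_group(G = 100, n = 5, seed = 2)
  fit0 <- fit_moderated_t(d$x, d$groups, prior_df = 0)
  plain <- apply(d$x, 1, function(r)
    stats::t.test(r[d$groups == "b"], r[d$groups == "a"], var.equal = TRUE)$statistic)
  expect_equal(unname(fit0$t), unname(plain), tolerance = 1e-10)

  fitI <- fit_moderated_t(d$x, d$groups, prior_df = Inf)
  expect_true(all(fitI$s2_post == fitI$s2_post[1]))
  expect_equal(fitI$s2_post[1], attr(fitI, "s0_2"))
})

test_that("moderated statistics agree with the limma implementation", {
  d <- sim_two_group(G = 400, n = 6, n_true = 30, effect = 1.5, seed = 3)
  fit <- fit_moderated_t(d$x, d$groups)
  eb <- limma::eBayes(limma::lmFit(d$x, stats::model.matrix(~factor(d$groups))))
  expect_equal(attr(fit, "d0"), eb$df.prior, tolerance = 1e-6)
  expect_equal(attr(fit, "s0_2"), eb$s2.prior, tolerance = 1e-6)
  expect_equal(unname(fit$t), unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(unname(fit$p_value), unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("posterior variances sit between the gene and prior variances", {
  d <- sim_two_group(G = 300, n = 5, seed = 4)
  fit <- fit_moderated_t(d$x, d$groups)
  s0 <- attr(fit, "s0_2")
  expect_true(all(fit$s2_post >= pmin(fit$s2, s0) - 1e-12))
  expect_true(all(fit$s2_post <= pmax(fit$s2, s0) + 1e-12))
  expect_true(all(fit$padj >= fit$p_value))
  # the reported t binds the reported fields: diff / (s_post * sqrt(2/n))
  expect_equal(fit$t, fit$diff / sqrt(fit$s2_post * (1 / 5 + 1 / 5)))
  # monotone in the mean difference at fixed variance: same residual
  # pattern per gene, growing group difference
  base <- c(-2, -1, 0, 1, 2)
  flat <- rbind(g1 = c(base, base + 1), g2 = c(base, base + 2), g3 = c(base, base + 3))
  colnames(flat) <- paste0("s", 1:10)
  ft <- fit_moderated_t(flat, rep(c("a", "b"), each = 5))
  expect_true(all(ft$s2 == ft$s2[1]))
  expect_true(all(diff(abs(ft$t)) > 0))
})

test_that("null p-values are uniform under label permutation", {
  d <- sim_two_group(G = 1000, n = 10, seed = 5)
  set.seed(6)
  fit <- fit_moderated_t(d$x, sample(d$groups))
  ks <- stats::ks.test(fit$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("planted effects are recovered with controlled error", {
  d <- sim_two_group(G = 200, n = 10, n_true = 20, effect = 2, seed = 7)
  fit <- fit_moderated_t(d$x, d$groups)
  called <- fit$gene[fit$padj < 0.05]
  tp <- length(intersect(called, d$true))
  expect_gte(tp / 20, 0.8)
  expect_lte(1 - tp / max(length(called), 1), 0.25)
})

test_that("pairwise cluster contrasts isolate single-cluster shifts", {
  set.seed(8)
  x <- matrix(rnorm(100 * 30), 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:30)))
  cl <- rep(c("A", "B", "C"), each = 10)
  x["g1", cl == "A"] <- x["g1", cl == "A"] + 5  # shifted in A only
  degs <- pairwise_cluster_degs(x, cl, p_cut = 0.001)
  expect_named(degs, c("A_vs_B", "A_vs_C", "B_vs_C"))
  expect_true("g1" %in% degs$A_vs_B)
  expect_true("g1" %in% degs$A_vs_C)
  expect_false("g1" %in% degs$B_vs_C)

  all_g <- pairwise_cluster_degs(x, cl, p_cut = 1)
  expect_equal(sort(all_g$A_vs_B), sort(rownames(x)))

  expect_error(pairwise_cluster_degs(x, rep(c("A", "B"), 15)), "exactly 3")
})

test_that("DEG intersection is plain set algebra with empty-set warning", {
  expect_equal(intersect_degs(list(c("a", "b", "c"), c("b", "c", "d"), c("c", "b"))),
               c("b", "c"))
  expect_warning(out <- intersect_degs(list("a", "b")), "empty")
  expect_length(out, 0)
  expect_error(intersect_degs(list("a")), "at least 2")
})

test_that("planted pan-cluster markers survive the three-way intersection", {
  b <- generate_m6a_data(m6a_sim_config(n_per_cluster = c(50, 50, 50)), seed = 9)
  degs <- pairwise_cluster_degs(b$expression, b$truth$cluster, p_cut = 0.001)
  overlap <- intersect_degs(degs)
  expect_gte(length(intersect(overlap, b$truth$markers)), 45)
})
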