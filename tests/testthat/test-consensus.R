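# Resampling consensus clustering: inner step, consensus matrix
# semantics, k selection and determinism.

test_that("inner clustering recovers separable clusters and handles edge k", {
  toy <- toy_three_clusters(n_per = 8, effect = 10)
  lab <- inner_cluster(toy$x, k = 3)
  expect_equal(adjusted_rand_index(lab, toy$cluster), 1)

  # k = n: every sample its own cluster
  small <- toy$x[, 1:5]
  expect_equal(sort(unique(inner_cluster(small, k = 5))), 1:5)
  expect_error(inner_cluster(small, k = 6), "k must be in")

  # identical samples: deterministic tie-break by sample order
  const <- matrix(1, 4, 6, dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
  const[1, ] <- c(1, 1, 1, 2, 2, 2)  # one informative feature, rest constant
  l1 <- inner_cluster(const, k = 2)
  l2 <- inner_cluster(const, k = 2)
  expect_identical(l1, l2)
})

test_that("one deterministic rep yields the 0/1 co-membership matrix", {
  toy <- toy_three_clusters(n_per = 5, effect = 8)
  res <- consensus_cluster(toy$x, k_range = 2:3, reps = 1, p_item = 1, seed = 1)
  cm <- res$consensus[["3"]]
  expect_true(all(cm %in% c(0, 1)))
  part <- inner_cluster(toy$x, k = 3)
  expect_equal(unname(cm), unname(outer(part, part, "==") * 1))
})

test_that("consensus matrices are valid and recover planted structure", {
  toy <- toy_three_clusters(n_per = 10, effect = 5)
  res <- consensus_cluster(toy$x, k_range = 2:5, reps = 100, p_item = 0.8, seed = 2)
  for (k in names(res$consensus)) {
    cm <- res$consensus[[k]]
    expect_true(isSymmetric(cm))
    expect_true(all(cm >= 0 & cm <= 1))
    expect_true(all(diag(cm) == 1))
    expect_equal(length(unique(res$labels[[k]])), as.integer(k))
  }
  expect_true(all(res$pac >= 0 & res$pac <= 1))
  expect_true(all(res$delta_area >= 0))
  expect_equal(res$chosen_k, 3L)
  expect_equal(adjusted_rand_index(res$labels[["3"]], toy$cluster), 1)

  # separation limit: within-block consensus high, between-block low
  cm <- res$consensus[["3"]]
  same <- outer(toy$cluster, toy$cluster, "==")
  off_diag <- !diag(ncol(toy$x))
  expect_gt(mean(cm[same & off_diag]), 0.95)
  expect_lt(mean(cm[!same]), 0.05)
})

test_that("consensus is seed-deterministic and conjugation-equivariant at p_item = 1", {
  toy <- toy_three_clusters(n_per = 6, effect = 4)
  r1 <- consensus_cluster(toy$x, k_range = 2:4, reps = 25, seed = 7)
  r2 <- consensus_cluster(toy$x, k_range = 2:4, reps = 25, seed = 7)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$consensus, r2$consensus)

  # with p_item = 1 the resampling is degenerate, so permuting samples
  # must conjugate the consensus matrix exactly
  perm <- sample(ncol(toy$x))
  ra <- consensus_cluster(toy$x, k_range = 3, reps = 1, p_item = 1, seed = 1)
  rb <- consensus_cluster(toy$x[, perm], k_range = 3, reps = 1, p_item = 1, seed = 1)
  expect_equal(unname(rb$consensus[["3"]]),
               unname(ra$consensus[["3"]][perm, perm]))
})

test_that("k selection follows the PAC and delta-area rules", {
  fake <- structure(list(k_range = 2:5,
                         pac = c(`2` = 0.30, `3` = 0.05, `4` = 0.05, `5` = 0.20),
                         delta_area = c(`2` = 0.5, `3` = 0.3, `4` = 0.05, `5` = 0.01),
                         cdf_area = c(`2` = 0.5, `3` = 0.65, `4` = 0.68, `5` = 0.69)),
                    class = "consensus_result")
  expect_equal(select_k(fake, "pac"), 3L)          # tie at 3 and 4 -> smaller k
  expect_equal(select_k(fake, "delta_area"), 3L)   # largest k above threshold

  # monotone areas with no elbow -> smallest k
  flat <- fake; flat$delta_area <- c(`2` = 0.05, `3` = 0.04, `4` = 0.03, `5` = 0.02)
  expect_equal(select_k(flat, "delta_area"), 2L)

  # pure noise: PAC stays high, selection is flagged low-confidence
  set.seed(11)
  noise <- matrix(rnorm(12 * 40), 12, 40,
                  dimnames = list(paste0("f", 1:12), paste0("s", 1:40)))
  res <- consensus_cluster(noise, k_range = 2:4, reps = 60, seed = 3)
  expect_gt(min(res$pac), 0.2)  # nothing close to a clean partition
  if (min(res$pac) > 0.5) expect_warning(select_k(res, "pac"), "low-confidence")
})

test_that("never-co-sampled pairs are zeroed with a warning at tiny reps", {
  toy <- toy_three_clusters(n_per = 8, effect = 5)
  expect_warning(consensus_cluster(toy$x, k_range = 2, reps = 1, p_item = 0.5, seed = 1),
                 "never co-sampled")
})
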