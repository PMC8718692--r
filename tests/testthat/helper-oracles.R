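# Independent oracles, written without reference to the package engines,
# plus small fixture builders used across test files.

# Exhaustive position-by-position ECDF evaluation of the single-sample
# enrichment score (sum variant). Deliberately literal: walks every
# position and recomputes both ECDFs from scratch.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  nm <- names(expr)
  ord <- nm[order(-expr, nm)]
  n <- length(ord)
  in_set <- ord %in% gene_set
  n_in <- sum(in_set)
  es <- 0
  w_total <- 0
  for (pos in seq_len(n)) if (in_set[pos]) w_total <- w_total + (n - pos + 1)^alpha
  for (pos in seq_len(n)) {
    p_in <- 0; p_out <- 0
    for (j in seq_len(pos)) {
      if (in_set[j]) p_in <- p_in + (n - j + 1)^alpha / w_total
      else p_out <- p_out + 1 / (n - n_in)
    }
    es <- es + (p_in - p_out)
  }
  es
}

# Step-up Benjamini-Hochberg by its definition (literal, quadratic).
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)  # rank of p[i]
    adj[i] <- min(vapply(k:m, function(j) m * p[ord[j]] / j, numeric(1)), 1)
  }
  adj
}

# Adjusted Rand index by explicit pair counting over all item pairs.
oracle_ari_paircount <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a && same_b) s11 <- s11 + 1
    else if (!same_a && !same_b) s00 <- s00 + 1
    else if (same_a) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / total
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(0)
  (s11 - expected) / (maxidx - expected)
}

# Brute-force maximally selected cutpoint: scan every admissible midpoint
# with survival::survdiff and return the argmax of its chi-square
# (ties -> lower cut).
oracle_cutpoint <- function(time, event, score, minprop) {
  n <- length(score)
  s <- sort(unique(score))
  mids <- (s[-1] + s[-length(s)]) / 2
  min_n <- ceiling(minprop * n)
  best_cut <- NA; best_stat <- -Inf
  for (cut in mids) {
    hi <- score > cut
    if (sum(hi) < min_n || sum(!hi) < min_n) next
    ch <- tryCatch(survival::survdiff(survival::Surv(time, event) ~ hi)$chisq,
                   error = function(e) NA)
    if (is.na(ch)) next
    if (sqrt(ch) > best_stat + 1e-12) { best_stat <- sqrt(ch); best_cut <- cut }
  }
  list(cutpoint = best_cut, statistic = best_stat)
}

# Efron-tie Cox partial log-likelihood for a single covariate, by its
# definition (only usable at tiny n).
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(beta * x[D])
    sumR <- sum(exp(beta * x[R]))
    sumD <- sum(exp(beta * x[D]))
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# Write a small TSV matrix fixture, returning its path.
write_matrix_fixture <- function(genes, values, samples = paste0("s", seq_len(ncol(values)))) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  df <- data.frame(gene = genes, values)
  colnames(df) <- c("gene", samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A tiny well-separated three-cluster matrix (features x samples).
toy_three_clusters <- function(n_per = 10, effect = 5, n_feat = 12, seed = 42) {
  set.seed(seed)
  n <- 3 * n_per
  cl <- rep(1:3, each = n_per)
  x <- matrix(rnorm(n_feat * n), n_feat, n,
              dimnames = list(paste0("f", seq_len(n_feat)), paste0("s", seq_len(n))))
  block <- rep(1:3, length.out = n_feat)
  for (j in 1:3) x[block == j, cl == j] <- x[block == j, cl == j] + effect
  list(x = x, cluster = cl)
}
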