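# Resampling-based consensus clustering of samples (Monti-style): repeated
# subsampling of items, inner clustering, co-clustering proportions, and
# k selection by PAC or the relative CDF-area increase.

#' Inner clustering step
#'
#' One deterministic partition of a (sub)matrix of samples, as used inside
#' the consensus resampling loop. Hierarchical clustering uses average
#' linkage on 1 - Pearson correlation between samples by default.
#'
#' @param x features x samples matrix.
#' @param k number of clusters (2..n_samples).
#' @param method "hclust" (default) or "kmeans".
#' @param distance "pearson" (default) or "euclidean"; ignored by kmeans.
#' @param seed RNG seed for kmeans starts.
#' @return integer vector of cluster labels, named by sample.
#' @export
inner_cluster <- function(x, k, method = c("hclust", "kmeans"),
                          distance = c("pearson", "euclidean"), seed = 1L) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  n <- ncol(x)
  if (k < 1L || k > n) stopf("k must be in 1..%d (got %d)", n, k)
  if (method == "hclust") {
    d <- sample_dist(x, distance)
    lab <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k)
  } else {
    lab <- with_seed(seed, stats::kmeans(t(x), centers = k, nstart = 5)$cluster)
  }
  names(lab) <- colnames(x)
  lab
}

#' @noRd
sample_dist <- function(x, distance) {
  if (distance == "pearson") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      # constant columns have undefined correlation; treat them as
      # maximally distant from everything and identical to each other
      d <- matrix(1, ncol(x), ncol(x))
      ok <- sds > 0
      if (sum(ok) > 1) d[ok, ok] <- 1 - stats::cor(x[, ok, drop = FALSE])
      const <- which(!ok)
      if (length(const) > 1) d[const, const] <- 0
      diag(d) <- 0
      d
    } else 1 - stats::cor(x)
  } else {
    as.matrix(stats::dist(t(x)))
  }
}

#' Consensus clustering with item resampling
#'
#' For each k in \code{k_range}, \code{reps} subsamples of
#' \code{ceiling(p_item * n)} samples are drawn and clustered; the
#' consensus matrix entry (i, j) is the fraction of co-clusterings among
#' the draws where both samples appeared. Final per-k labels come from
#' average-linkage hierarchical clustering of 1 - consensus. Stability
#' diagnostics per k: the empirical CDF area of off-diagonal consensus
#' values, its relative increase over k-1 (delta area), and the
#' proportion of ambiguous clustering PAC = CDF(0.9) - CDF(0.1).
#'
#' Subsample draws use a counter-based per-repetition seed
#' (\code{seed + rep}), so runs are reproducible and independent of
#' evaluation order.
#'
#' @param x features x samples matrix (e.g. the regulator panel of a
#'   meta-cohort).
#' @param k_range integer vector of candidate cluster numbers.
#' @param reps number of resampling repetitions (default 1000).
#' @param p_item item (sample) subsampling proportion, default 0.8.
#' @param method,distance inner clustering, see \code{\link{inner_cluster}}.
#' @param seed base RNG seed.
#' @param select_rule rule used to fill \code{chosen_k}; see
#'   \code{\link{select_k}}.
#' @return Object of class \code{consensus_result}: list with
#'   \code{consensus} (list of n x n matrices by k), \code{labels} (list
#'   of integer label vectors by k), \code{cdf_area}, \code{delta_area},
#'   \code{pac} (named numeric vectors), \code{chosen_k}, \code{k_range}.
#' @export
consensus_cluster <- function(x, k_range = 2:6, reps = 1000, p_item = 0.8,
                              method = c("hclust", "kmeans"),
                              distance = c("pearson", "euclidean"),
                              seed = 1L, select_rule = c("delta_area", "pac")) {
  method <- match.arg(method)
  distance <- match.arg(distance)
  select_rule <- match.arg(select_rule)
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(x)
  if (nrow(x) < 2L) stopf("need at least 2 features")
  if (any(k_range < 2L)) stopf("k_range must start at 2")
  if (n < max(k_range) + 1L) stopf("need at least max(k_range)+1 samples")
  if (p_item <= 0 || p_item > 1) stopf("p_item must be in (0, 1]")
  m <- ceiling(p_item * n)

  # items (samples) are resampled while features stay fixed, so the
  # sample-sample distance can be computed once and subset per draw
  d_full <- if (method == "hclust") sample_dist(x, distance) else NULL

  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  copair <- matrix(0, n, n)

  for (r in seq_len(reps)) {
    idx <- with_seed(seed + r, sort(sample.int(n, m)))
    copair[idx, idx] <- copair[idx, idx] + 1
    if (method == "hclust") {
      hc <- stats::hclust(stats::as.dist(d_full[idx, idx]), method = "average")
      for (k in k_range) {
        lab <- stats::cutree(hc, k)
        for (cl in unique(lab)) {
          mem <- idx[lab == cl]
          conn[[as.character(k)]][mem, mem] <- conn[[as.character(k)]][mem, mem] + 1
        }
      }
    } else {
      for (k in k_range) {
        lab <- with_seed(seed + r, stats::kmeans(t(x[, idx, drop = FALSE]),
                                                 centers = k, nstart = 5)$cluster)
        for (cl in unique(lab)) {
          mem <- idx[lab == cl]
          conn[[as.character(k)]][mem, mem] <- conn[[as.character(k)]][mem, mem] + 1
        }
      }
    }
  }

  never <- sum(copair[upper.tri(copair)] == 0)
  if (never > 0)
    warnf("%d sample pair(s) were never co-sampled; their consensus is set to 0 (increase reps)", never)

  consensus <- list(); labels <- list()
  cdf_area <- pac <- numeric(length(k_range))
  names(cdf_area) <- names(pac) <- as.character(k_range)
  for (k in k_range) {
    kk <- as.character(k)
    cm <- conn[[kk]] / pmax(copair, 1)
    cm[copair == 0] <- 0
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(colnames(x), colnames(x))
    consensus[[kk]] <- cm
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    lab <- stats::cutree(hc, k)
    names(lab) <- colnames(x)
    labels[[kk]] <- lab
    v <- cm[upper.tri(cm)]
    xs <- sort(v)
    cdf_area[kk] <- sum(diff(xs) * seq_along(xs)[-length(xs)] / length(xs))
    pac[kk] <- mean(v > 0.1 & v <= 0.9)
  }
  # relative CDF-area increase; areas floored to be non-decreasing so the
  # delta is >= 0 by definition
  delta_area <- numeric(length(k_range))
  names(delta_area) <- as.character(k_range)
  run_max <- -Inf
  for (i in seq_along(k_range)) {
    a <- cdf_area[i]
    delta_area[i] <- if (i == 1L) a else max(0, (a - run_max) / run_max)
    run_max <- max(run_max, a)
  }

  res <- structure(list(consensus = consensus, labels = labels,
                        cdf_area = cdf_area, delta_area = delta_area,
                        pac = pac, k_range = k_range, chosen_k = NA_integer_,
                        reps = reps, p_item = p_item, seed = seed,
                        method = method, distance = distance),
                   class = "consensus_result")
  res$chosen_k <- select_k(res, rule = select_rule)
  res
}

#' Select the number of clusters from a consensus run
#'
#' \code{"delta_area"} (default): the largest k whose relative CDF-area
#' increase exceeds \code{threshold}; if none exceeds it, the smallest
#' candidate k. \code{"pac"}: the k minimising the proportion of
#' ambiguous clustering (ties to the smaller k; a minimum PAC above 0.5
#' is flagged as low confidence). PAC can tie at 0 for nested stable
#' partitions (a clean 2-way merge of 3 true clusters), where the
#' delta-area elbow still resolves the full structure.
#'
#' @param result a \code{consensus_result}.
#' @param rule "pac" or "delta_area".
#' @param threshold delta-area threshold (default 0.1).
#' @return the selected k (integer); attribute \code{low_confidence} set
#'   when the PAC rule fires its warning.
#' @export
select_k <- function(result, rule = c("delta_area", "pac"), threshold = 0.1) {
  rule <- match.arg(rule)
  ks <- result$k_range
  if (length(ks) < 2L) {
    k <- ks[1]
  } else if (rule == "pac") {
    k <- ks[which.min(result$pac)]  # which.min takes the first (smaller k) on ties
    if (min(result$pac) > 0.5) {
      warnf("minimum PAC = %.2f > 0.5: no stable clustering; k = %d is low-confidence",
            min(result$pac), k)
      attr(k, "low_confidence") <- TRUE
    }
  } else {
    ok <- which(result$delta_area > threshold)
    k <- if (length(ok)) ks[max(ok)] else ks[1]
  }
  as.integer(k)
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus clustering: %d reps, p_item = %.2f, %s/%s\n",
              x$reps, x$p_item, x$method, x$distance))
  diag <- data.frame(k = x$k_range, cdf_area = round(x$cdf_area, 4),
                     delta_area = round(x$delta_area, 4), pac = round(x$pac, 4))
  print(diag, row.names = FALSE)
  cat(sprintf("chosen k = %d\n", x$chosen_k))
  invisible(x)
}
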