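# Empirical-Bayes moderated-t differential expression between two groups,
# pairwise contrasts between the three molecular clusters, and the
# three-way DEG intersection that defines the m6A phenotype signature.

#' Inverse of the trigamma function
#'
#' Newton iteration on 1/trigamma (which is almost linear), used by the
#' method-of-moments fit of the variance prior.
#' @noRd
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene two-sample comparison on log-scale expression. The pooled
#' residual variance s2_g (d_g = n1 + n2 - 2 df) is shrunk toward a
#' prior: s2_post = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g), with the prior
#' df d0 and prior variance s0^2 estimated by the method of moments on
#' log s2_g (closed forms of Smyth 2004). The moderated t is
#' diff / (s_post * sqrt(1/n1 + 1/n2)) on d0 + d_g df.
#'
#' Zero-variance genes are excluded from the moment fit and shrunk with
#' s2_g = 0 in the posterior formula (the limit rule); with an infinite
#' prior df every posterior variance equals s0^2.
#'
#' @param x gene x sample matrix, log scale.
#' @param groups two-level factor/vector over samples; the reported
#'   difference is level 2 minus level 1.
#' @param prior_df optional override of the estimated d0: \code{0}
#'   recovers the ordinary t-test, \code{Inf} full shrinkage to s0^2.
#' @return data.frame of class \code{de_result}: gene, diff (log units),
#'   s2, df, s2_post, t, p_value, padj; attributes \code{d0}, \code{s0_2},
#'   \code{contrast}.
#' @export
fit_moderated_t <- function(x, groups, prior_df = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stopf("groups must have exactly two levels")
  if (length(groups) != ncol(x)) stopf("one group label per sample required")
  n1 <- sum(groups == levels(groups)[1]); n2 <- sum(groups == levels(groups)[2])
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 samples")
  i1 <- groups == levels(groups)[1]; i2 <- groups == levels(groups)[2]
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  d_g <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d_g
  diff <- m2 - m1

  pos <- s2 > 0
  if (!any(pos)) stopf("all genes have zero residual variance")
  z <- log(s2[pos])
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  e_bar <- mean(e)
  G <- length(e)
  ev <- mean((e - e_bar)^2 * G / (G - 1) - trigamma(d_g / 2))
  if (is.finite(ev) && ev > 0) {
    d0 <- 2 * trigamma_inverse(ev)
    s0_2 <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(e_bar)
  }
  if (!is.null(prior_df)) d0 <- prior_df

  if (is.infinite(d0)) {
    s2_post <- rep(s0_2, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d_g
  } else {
    s2_post <- (d0 * s0_2 + d_g * s2) / (d0 + d_g)
    df_total <- d0 + d_g
  }
  tstat <- diff / sqrt(s2_post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(gene = rownames(x), diff = diff, s2 = s2, df = d_g,
                    s2_post = s2_post, t = tstat, p_value = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- d0
  attr(res, "s0_2") <- s0_2
  attr(res, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  class(res) <- c("de_result", "data.frame")
  res
}

#' Pairwise differential expression between three clusters
#'
#' Fits the moderated t for each of the three pairwise contrasts and
#' returns the genes passing the raw p-value cut (the phenotype-DEG rule:
#' raw p < 0.001; set \code{adjusted = TRUE} to filter on BH-adjusted p
#' instead).
#'
#' @param x gene x sample matrix, log scale.
#' @param cluster_labels three-level factor/vector over samples.
#' @param p_cut p-value threshold (default 0.001).
#' @param adjusted filter on BH-adjusted p instead of raw p.
#' @return named list of gene vectors, one per contrast; the full fits in
#'   attribute \code{fits}.
#' @export
pairwise_cluster_degs <- function(x, cluster_labels, p_cut = 0.001, adjusted = FALSE) {
  cl <- factor(cluster_labels)
  if (nlevels(cl) != 3L) stopf("expected exactly 3 clusters, got %d", nlevels(cl))
  if (any(table(cl) < 2L)) stopf("every cluster needs at least 2 samples")
  lv <- levels(cl)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list(); fits <- list()
  for (p in pairs) {
    sel <- cl %in% lv[p]
    fit <- fit_moderated_t(x[, sel, drop = FALSE], droplevels(cl[sel]))
    nm <- paste(lv[p[1]], "vs", lv[p[2]], sep = "_")
    pv <- if (adjusted) fit$padj else fit$p_value
    out[[nm]] <- fit$gene[pv < p_cut]
    fits[[nm]] <- fit
  }
  attr(out, "fits") <- fits
  out
}

#' Intersect DEG lists across contrasts
#'
#' The center of the Venn diagram: genes differential in every contrast,
#' sorted lexicographically.
#'
#' @param contrast_sets list (length >= 2) of gene vectors.
#' @return sorted character vector (possibly empty, with a warning).
#' @export
intersect_degs <- function(contrast_sets) {
  if (length(contrast_sets) < 2L) stopf("need at least 2 contrast sets")
  out <- sort(Reduce(intersect, contrast_sets))
  if (!length(out)) warnf("empty DEG intersection across contrasts")
  out
}
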