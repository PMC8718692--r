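# Rank-based single-sample gene-set enrichment (ssGSEA, the sum-variant
# of Barbie et al.), reused for immune-cell infiltration, pathway
# activity and immune/stromal scoring, plus hypergeometric
# over-representation testing for DEG annotation.

#' Single-sample gene-set enrichment score
#'
#' Genes are ranked by expression, descending; ties are broken by
#' lexicographic gene id so the score is deterministic. With positions
#' pos = 1..n (1 = highest), each gene carries rank value
#' n - pos + 1, and in-set genes are weighted by rank_value^alpha. The
#' score is the sum over positions of the difference between the
#' weighted in-set ECDF and the unweighted out-set ECDF (the sum
#' variant, not the maximum deviation). Because only ranks enter, the
#' score is invariant under any strictly increasing transform of the
#' expression column.
#'
#' @param expr named numeric vector: one sample's expression over the
#'   gene universe.
#' @param gene_set character vector of gene ids; the overlap with the
#'   universe must be non-empty and a strict subset of it.
#' @param alpha rank-weighting exponent (default 0.25).
#' @return numeric enrichment score.
#' @export
ssgsea_sample <- function(expr, gene_set, alpha = 0.25) {
  if (is.null(names(expr))) stopf("expr must be a named vector (gene ids)")
  n <- length(expr)
  in_set <- names(expr) %in% gene_set
  n_in <- sum(in_set)
  if (n_in == 0L) stopf("gene set has no overlap with the expression universe")
  if (n_in == n) stopf("gene set covers the whole universe; score undefined")
  ord <- order(-expr, names(expr))
  in_ord <- in_set[ord]
  rank_value <- n - seq_len(n) + 1
  w <- rank_value^alpha
  num <- cumsum(ifelse(in_ord, w, 0))
  p_in <- num / num[n]
  p_out <- cumsum(!in_ord) / (n - n_in)
  # both ECDFs terminate at 1 by construction
  stopifnot(abs(p_in[n] - 1) < 1e-12, abs(p_out[n] - 1) < 1e-12)
  sum(p_in - p_out)
}

#' Score a gene-set collection on every sample
#'
#' Applies \code{\link{ssgsea_sample}} to each set and sample. With
#' \code{normalize = TRUE} (default) the whole score matrix is shifted
#' and scaled by its global range so scores lie in [0, 1] — the
#' convention used when scores from many signatures are compared on one
#' scale (e.g. the 23 tumor-infiltrating immune cell types).
#'
#' @param x gene x sample expression matrix (any monotone scale).
#' @param sets named list of gene sets (see \code{\link{read_gmt}}).
#' @param alpha rank-weighting exponent.
#' @param normalize scale scores by the global range.
#' @return matrix sets x samples with attributes \code{normalized} and
#'   \code{alpha}.
#' @export
score_collection <- function(x, sets, alpha = 0.25, normalize = TRUE) {
  if (!length(sets)) stopf("empty gene-set collection")
  miss <- names(sets)[vapply(sets, function(s) !any(rownames(x) %in% s), logical(1))]
  if (length(miss))
    stopf("gene set(s) with no overlap in the matrix: %s", paste(miss, collapse = ", "))
  scores <- matrix(NA_real_, length(sets), ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    names(col) <- rownames(x)
    for (i in seq_along(sets))
      scores[i, j] <- ssgsea_sample(col, sets[[i]], alpha = alpha)
  }
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) == 0) {
      warnf("all enrichment scores identical; normalization skipped")
      normalize <- FALSE
    } else {
      scores <- (scores - rng[1]) / diff(rng)
    }
  }
  attr(scores, "normalized") <- normalize
  attr(scores, "alpha") <- alpha
  scores
}

#' Immune and stromal infiltration scores
#'
#' Per-sample ssGSEA scores on an immune and a stromal gene signature.
#' Scores are relative: they rank samples by infiltration and support
#' group comparisons, without the affine purity transform of the
#' original two-signature estimator.
#'
#' @param x gene x sample expression matrix.
#' @param immune_set,stromal_set character vectors of signature genes.
#' @param alpha rank-weighting exponent.
#' @return data.frame with columns \code{sample}, \code{immune_score},
#'   \code{stromal_score}.
#' @export
immune_stromal_scores <- function(x, immune_set, stromal_set, alpha = 0.25) {
  s <- score_collection(x, list(immune = immune_set, stromal = stromal_set),
                        alpha = alpha, normalize = FALSE)
  data.frame(sample = colnames(x), immune_score = s["immune", ],
             stromal_score = s["stromal", ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Over-representation test for a gene set
#'
#' One-sided hypergeometric tail probability of seeing at least the
#' observed overlap between a hit list and a gene set within a universe.
#'
#' @param hits character vector of hit genes (subset of universe).
#' @param set character vector, the gene set (subset of universe).
#' @param universe character vector of all testable genes.
#' @return list with \code{overlap}, \code{odds_ratio}, \code{p_value}.
#' @export
ora_test <- function(hits, set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  hits <- unique(intersect(hits, universe))
  set <- unique(intersect(set, universe))
  q <- length(intersect(hits, set))
  m <- length(set)
  n_u <- length(universe)
  k <- length(hits)
  p <- stats::phyper(q - 1, m, n_u - m, k, lower.tail = FALSE)
  a <- q; b <- k - q; cc <- m - q; d <- n_u - m - b
  or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  list(overlap = q, odds_ratio = or, p_value = min(p, 1))
}

#' Over-representation testing across a collection
#'
#' Runs \code{\link{ora_test}} for every set and applies
#' Benjamini-Hochberg correction across the collection.
#'
#' @param hits,universe as in \code{\link{ora_test}}.
#' @param sets named list of gene sets.
#' @return data.frame: set, overlap, set_size, odds_ratio, p_value, padj.
#' @export
ora_collection <- function(hits, sets, universe) {
  res <- lapply(sets, ora_test, hits = hits, universe = universe)
  out <- data.frame(set = names(sets),
                    overlap = vapply(res, `[[`, numeric(1), "overlap"),
                    set_size = vapply(sets, function(s) length(intersect(s, universe)), numeric(1)),
                    odds_ratio = vapply(res, `[[`, numeric(1), "odds_ratio"),
                    p_value = vapply(res, `[[`, numeric(1), "p_value"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$padj <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}
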