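# The per-sample m6A score (PCA on the prognostic phenotype signature),
# its survival stratification, tumor mutation burden, combined
# score x TMB strata, mutation/CNV frequency summaries, and the
# rank-based correlation / group-comparison utilities.

#' Fit the PCA score model on a gene signature
#'
#' Genes are z-scored across samples; the standardized samples x genes
#' matrix is decomposed by SVD and components 1 and 2 are retained. Each
#' component's sign is fixed so that the sum of its loadings is
#' non-negative (tie: first nonzero loading positive), making scores
#' reproducible across linear-algebra backends.
#'
#' @param x gene x sample expression matrix (log scale).
#' @param signature character vector of signature genes (>= 3 present in
#'   \code{x}). Zero-variance genes are dropped with a warning.
#' @return object of class \code{m6a_pca}: genes, center, scale,
#'   rotation (genes x 2), explained (variance fractions of PC1, PC2).
#' @export
fit_score_model <- function(x, signature) {
  genes <- intersect(unique(signature), rownames(x))
  if (ncol(x) < 3L) stopf("need at least 3 samples")
  xs <- x[genes, , drop = FALSE]
  sds <- apply(xs, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d zero-variance signature gene(s)", sum(sds == 0))
    genes <- genes[sds > 0]
    xs <- xs[genes, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (length(genes) < 3L) stopf("fewer than 3 signature genes present in the matrix")
  ctr <- rowMeans(xs)
  z <- (xs - ctr) / sds
  sv <- svd(t(z), nu = 0, nv = 2)          # samples x genes
  rot <- sv$v
  for (j in 1:2) {
    s <- sum(rot[, j])
    if (s < 0 || (s == 0 && rot[which(rot[, j] != 0)[1], j] < 0))
      rot[, j] <- -rot[, j]
  }
  rownames(rot) <- genes
  colnames(rot) <- c("PC1", "PC2")
  expl <- sv$d[1:2]^2 / sum(sv$d^2)
  model <- list(genes = genes, center = ctr, scale = sds, rotation = rot,
                explained = expl)
  class(model) <- "m6a_pca"
  model
}

#' @export
print.m6a_pca <- function(x, ...) {
  cat(sprintf("PCA score model: %d genes; PC1/PC2 explain %.1f%% / %.1f%% of variance\n",
              length(x$genes), 100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Per-sample m6A score
#'
#' score(s) = projection of sample s onto PC1 plus its projection onto
#' PC2, each projection the sum over signature genes of the z-scored
#' expression times the gene's loading. A sample sitting at the
#' training gene-wise means scores 0.
#'
#' @param model a fitted \code{\link{fit_score_model}} object.
#' @param x gene x sample matrix containing all model genes.
#' @return named numeric vector of scores.
#' @export
m6a_score <- function(model, x) {
  miss <- setdiff(model$genes, rownames(x))
  if (length(miss))
    stopf("matrix is missing model gene(s): %s", paste(miss, collapse = ", "))
  z <- (x[model$genes, , drop = FALSE] - model$center) / model$scale
  proj <- t(z) %*% model$rotation
  out <- proj[, "PC1"] + proj[, "PC2"]
  names(out) <- colnames(x)
  out
}

#' @export
predict.m6a_pca <- function(object, newdata, ...) m6a_score(object, newdata)

#' Stratify samples by score with a survival-driven cutpoint
#'
#' Delegates the cutpoint to \code{\link{max_sel_cutpoint}} and labels
#' samples high/low.
#'
#' @param scores named numeric vector.
#' @param time,event survival data aligned with \code{scores}.
#' @param minprop minimum group proportion (default 0.1).
#' @return list: group (factor high/low, named), cutpoint, statistic.
#' @export
stratify_score <- function(scores, time, event, minprop = 0.1) {
  cp <- max_sel_cutpoint(time, event, scores, minprop = minprop)
  group <- factor(ifelse(scores > cp$cutpoint, "high", "low"),
                  levels = c("low", "high"))
  names(group) <- names(scores)
  list(group = group, cutpoint = cp$cutpoint, statistic = cp$statistic)
}

#' Tumor mutation burden per sample
#'
#' Count of mutation records per sample, excluding silent variants by
#' default; no per-megabase normalization unless \code{per_mb} is given.
#'
#' @param mut mutation table from \code{\link{read_mutations}}.
#' @param samples optional vector of sample ids to report (samples with
#'   no records score 0, with a warning).
#' @param nonsilent_only exclude silent variants (default TRUE).
#' @param per_mb optional covered megabases to divide by.
#' @return named numeric vector of TMB values.
#' @export
tmb_per_sample <- function(mut, samples = NULL, nonsilent_only = TRUE, per_mb = NULL) {
  keep <- if (nonsilent_only) mut$variant_class != "silent" else rep(TRUE, nrow(mut))
  counts <- table(factor(mut$sample[keep],
                         levels = if (is.null(samples)) unique(mut$sample) else samples))
  if (!is.null(samples)) {
    absent <- setdiff(samples, unique(mut$sample))
    if (length(absent))
      warnf("%d sample(s) absent from the mutation table score TMB = 0", length(absent))
  }
  out <- as.numeric(counts)
  names(out) <- names(counts)
  if (!is.null(per_mb)) out <- out / per_mb
  out
}

#' Combined score x TMB survival strata
#'
#' Crosses the two high/low groupings into the four strata H/H, H/L,
#' L/H, L/L (score/TMB), runs the global log-rank across the non-empty
#' strata and all pairwise log-rank contrasts with BH adjustment.
#'
#' @param score_group,tmb_group factors with levels low/high on the same
#'   samples.
#' @param time,event survival data.
#' @return list: stratum (factor), global (logrank result), pairwise
#'   (data.frame contrast/chisq/p_value/padj).
#' @export
combine_strata <- function(score_group, tmb_group, time, event) {
  if (length(score_group) != length(tmb_group)) stopf("groupings differ in length")
  lab <- paste0(ifelse(score_group == "high", "H", "L"), "/",
                ifelse(tmb_group == "high", "H", "L"))
  stratum <- factor(lab, levels = c("H/H", "H/L", "L/H", "L/L"))
  empty <- levels(stratum)[table(stratum) == 0]
  if (length(empty)) {
    warnf("dropping empty stratum(s): %s", paste(empty, collapse = ", "))
    stratum <- droplevels(stratum)
  }
  global <- logrank_test(time, event, stratum)
  lv <- levels(stratum)
  pw <- do.call(rbind, lapply(utils::combn(lv, 2, simplify = FALSE), function(p) {
    sel <- stratum %in% p
    lt <- logrank_test(time[sel], event[sel], droplevels(stratum[sel]))
    data.frame(contrast = paste(p, collapse = " vs "), chisq = lt$chisq,
               p_value = lt$p_value, stringsAsFactors = FALSE)
  }))
  pw$padj <- stats::p.adjust(pw$p_value, method = "BH")
  list(stratum = stratum, global = global, pairwise = pw)
}

#' Mutation frequency per gene
#'
#' A sample counts once per gene regardless of how many hits it carries
#' (nonsilent records only).
#'
#' @param mut mutation table.
#' @param genes genes to report.
#' @param n_samples cohort size used as the denominator.
#' @return data.frame gene/count/percent, with attribute
#'   \code{altered_fraction}: overall fraction of samples carrying at
#'   least one nonsilent hit in any of \code{genes}.
#' @export
mutation_frequency <- function(mut, genes, n_samples) {
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  ns <- mut[mut$variant_class != "silent" & mut$gene %in% genes, , drop = FALSE]
  counts <- vapply(genes, function(g) length(unique(ns$sample[ns$gene == g])), numeric(1))
  out <- data.frame(gene = genes, count = counts,
                    percent = round(100 * counts / n_samples, 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "altered_fraction") <- length(unique(ns$sample)) / n_samples
  out
}

#' Copy-number gain/loss frequency per gene
#'
#' @param cnv integer call matrix (genes x samples, values -2..2).
#' @return data.frame gene/gain_freq/loss_freq.
#' @export
cnv_frequency <- function(cnv) {
  data.frame(gene = rownames(cnv),
             gain_freq = rowMeans(cnv > 0),
             loss_freq = rowMeans(cnv < 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman correlation between two sets of variables
#'
#' Tie-corrected rank correlation of every row of \code{a} against every
#' row of \code{b}; p-values from the t approximation, BH-adjusted
#' across the whole matrix. Constant rows give NA with a warning.
#'
#' @param a,b numeric matrices with variables in rows and the same
#'   samples in columns (vectors are treated as single rows).
#' @return list of matrices: rho, p_value, padj.
#' @export
correlate <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, 1, dimnames = list("a", names(a)))
  if (is.vector(b)) b <- matrix(b, 1, dimnames = list("b", names(b)))
  if (ncol(a) != ncol(b)) stopf("a and b must share samples")
  n <- ncol(a)
  const <- c(rownames(a)[apply(a, 1, stats::sd) == 0],
             rownames(b)[apply(b, 1, stats::sd) == 0])
  if (length(const))
    warnf("constant variable(s) give undefined correlation: %s",
          paste(const, collapse = ", "))
  ra <- t(apply(a, 1, rank)); rb <- t(apply(b, 1, rank))
  # Pearson on ranks = tie-corrected Spearman; cor's own zero-sd warning
  # is redundant with the named one above
  rho <- suppressWarnings(stats::cor(t(ra), t(rb)))
  rho[abs(rho) > 1] <- sign(rho[abs(rho) > 1])
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[rho == 1 | rho == -1] <- 0
  padj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), dimnames = dimnames(p))
  list(rho = rho, p_value = p, padj = padj)
}

#' Rank-based group comparison
#'
#' Wilcoxon rank-sum for two groups, Kruskal-Wallis for two or more,
#' both with tie correction.
#'
#' @param values numeric vector.
#' @param labels group labels.
#' @param test "wilcoxon" or "kruskal".
#' @return list(statistic, p_value, test).
#' @export
group_compare <- function(values, labels, test = c("wilcoxon", "kruskal")) {
  test <- match.arg(test)
  labels <- droplevels(factor(labels))
  if (any(table(labels) == 0L) || nlevels(labels) < 2L) stopf("need >= 2 non-empty groups")
  if (test == "wilcoxon") {
    if (nlevels(labels) != 2L) stopf("wilcoxon requires exactly 2 groups")
    ht <- stats::wilcox.test(values ~ labels, exact = FALSE, correct = FALSE)
  } else {
    ht <- stats::kruskal.test(values, labels)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
}
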