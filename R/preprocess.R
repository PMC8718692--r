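# Unit conversion, log transformation, cross-cohort normalization and the
# gene-space intersection that produces the analysis-ready meta-cohort.

#' Convert FPKM to TPM
#'
#' Per sample s: \code{tpm[g, s] = fpkm[g, s] / sum_g fpkm[g, s] * 1e6},
#' so every column sums to one million. The conversion is scale-invariant
#' per sample: multiplying a column by any c > 0 leaves its TPM unchanged.
#'
#' @param x gene x sample matrix of FPKM values (non-negative).
#' @return matrix of TPM values, \code{unit} attribute set to "tpm".
#' @export
fpkm_to_tpm <- function(x) {
  validate_expression(x, unit = "fpkm")
  cs <- colSums(x)
  if (any(cs == 0))
    stopf("all-zero sample column(s): %s",
          paste(colnames(x)[cs == 0], collapse = ", "))
  y <- sweep(x, 2, cs, "/") * 1e6
  expr_unit(y) <- "tpm"
  y
}

#' Log2-transform an expression matrix
#'
#' \code{y = log2(x + pseudocount)}.
#'
#' @param x non-negative matrix (fpkm or tpm).
#' @param pseudocount added before the log; default 1.
#' @return log2-scale matrix; unit becomes "log2tpm" (or stays a log unit).
#' @export
log2_transform <- function(x, pseudocount = 1) {
  if (any(x < 0)) stopf("log2_transform requires non-negative input")
  y <- log2(x + pseudocount)
  expr_unit(y) <- if (expr_unit(x) == "log2intensity") "log2intensity" else "log2tpm"
  y
}

#' Quantile-normalize samples to a common distribution
#'
#' Every sample's sorted value vector is replaced by the across-sample
#' mean of sorted vectors; tied values within a sample receive the mean
#' of the reference values over their rank span. Delegates to
#' \code{limma::normalizeQuantiles} (the engine behind limma's
#' between-array normalization).
#'
#' @param x gene x sample matrix, no missing values.
#' @return normalized matrix with the same dimnames and unit.
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stopf("quantile_normalize requires a complete matrix")
  if (ncol(x) == 1L) {
    warnf("single-sample matrix: quantile normalization is the identity")
    return(x)
  }
  y <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(y) <- dimnames(x)
  expr_unit(y) <- expr_unit(x)
  y
}

#' Assemble a normalized multi-cohort expression matrix
#'
#' Each cohort is brought to log2 scale (FPKM is first converted to TPM),
#' gene spaces are intersected, matrices are concatenated column-wise and
#' quantile normalization is applied once across the merged matrix (a
#' single reference distribution for all cohorts).
#'
#' @param cohorts list of gene x sample matrices, each carrying a
#'   \code{unit} attribute ("fpkm", "tpm", "log2tpm" or "log2intensity").
#' @param labels character vector of cohort labels, one per cohort.
#' @param normalize apply quantile normalization to the merged matrix
#'   (default TRUE).
#' @param pseudocount passed to \code{\link{log2_transform}}.
#' @return An object of class \code{meta_cohort}: list with
#'   \code{matrix} (log-scale, normalized), \code{cohort_of} (named
#'   character vector sample -> cohort) and \code{genes_common}.
#' @export
build_meta_cohort <- function(cohorts, labels, normalize = TRUE, pseudocount = 1) {
  if (!length(cohorts)) stopf("need at least one cohort")
  if (length(labels) != length(cohorts)) stopf("one label per cohort required")
  logged <- lapply(cohorts, function(x) {
    u <- expr_unit(x)
    if (u == "fpkm") x <- fpkm_to_tpm(x)
    if (expr_unit(x) == "tpm") x <- log2_transform(x, pseudocount)
    x
  })
  genes_common <- Reduce(intersect, lapply(logged, rownames))
  if (!length(genes_common)) stopf("empty gene intersection across cohorts")
  merged <- do.call(cbind, lapply(logged, function(x) x[genes_common, , drop = FALSE]))
  if (anyDuplicated(colnames(merged))) stopf("sample ids collide across cohorts")
  cohort_of <- rep(labels, vapply(logged, ncol, integer(1)))
  names(cohort_of) <- colnames(merged)
  expr_unit(merged) <- "log2tpm"
  if (normalize && ncol(merged) > 1L) merged <- quantile_normalize(merged)
  message(sprintf("build_meta_cohort: %d common genes across %d cohort(s), %d samples",
                  length(genes_common), length(cohorts), ncol(merged)))
  structure(list(matrix = merged, cohort_of = cohort_of, genes_common = genes_common),
            class = "meta_cohort")
}

#' @export
print.meta_cohort <- function(x, ...) {
  cat(sprintf("meta_cohort: %d genes x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", names(table(x$cohort_of)),
                            table(x$cohort_of)), collapse = ", ")))
  invisible(x)
}
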