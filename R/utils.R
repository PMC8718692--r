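# Internal helpers shared across modules.

PIPELINE_VERSION <- "m6ascore 0.1.0"

#' Evaluate an expression with a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's
#' `.Random.seed` afterwards, so package functions never clobber the
#' session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Validate an expression matrix
#'
#' Checks the invariants every stage assumes: a numeric matrix with unique,
#' non-empty gene and sample identifiers, all values finite, and (for
#' abundance units) non-negative.
#' @noRd
validate_expression <- function(x, unit = expr_unit(x)) {
  if (!is.matrix(x) || !is.numeric(x)) stopf("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(x))) stopf("duplicate sample ids")
  if (anyNA(x) || any(!is.finite(x))) stopf("expression matrix contains missing or non-finite values")
  if (unit %in% c("fpkm", "tpm") && any(x < 0))
    stopf("%s values must be non-negative", unit)
  invisible(x)
}

EXPR_UNITS <- c("fpkm", "tpm", "log2tpm", "log2intensity")

#' @noRd
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "log2tpm" else u
}

#' @noRd
`expr_unit<-` <- function(x, value) {
  value <- match.arg(value, EXPR_UNITS)
  attr(x, "unit") <- value
  x
}
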