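# The curated m6A regulator panel.

# 24 regulators: 10 writers (methyltransferase complex), 2 erasers
# (demethylases) and 12 readers (m6A-binding proteins).
.M6A_WRITERS <- c("CBLL1", "ELAVL1", "METTL3", "METTL14", "METTL16",
                  "KIAA1429", "RBM15", "RBM15B", "WTAP", "ZC3H13")
.M6A_ERASERS <- c("ALKBH5", "FTO")
.M6A_READERS <- c("YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2", "YTHDF3",
                  "FMR1", "HNRNPA2B1", "HNRNPC", "IGF2BP1", "IGF2BP2",
                  "IGF2BP3", "LRPPRC")

#' The m6A regulator registry
#'
#' Load the curated panel of 24 N6-methyladenosine (m6A) regulator genes
#' (10 writers, 2 erasers, 12 readers), or a user-supplied panel from a
#' two-column table.
#'
#' The symbol \code{WTA}, an occasional truncation of the writer
#' \code{WTAP} seen in published regulator lists, is normalised to
#' \code{WTAP} on load and the rewrite is reported via \code{message()}.
#'
#' @param path Optional path to a two-column TSV/CSV (\code{symbol},
#'   \code{role}). When \code{NULL} the built-in 24-gene panel is
#'   returned. User files may contain any number of genes; a panel that
#'   is not the canonical 24/10/2/12 partition is flagged with the
#'   attribute \code{canonical = FALSE}.
#' @return A data.frame with columns \code{gene} (unique, uppercase
#'   symbols) and \code{role} (factor: writer/eraser/reader), class
#'   \code{m6a_registry}.
#' @examples
#' reg <- load_registry()
#' table(reg$role)
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    reg <- data.frame(
      gene = c(.M6A_WRITERS, .M6A_ERASERS, .M6A_READERS),
      role = factor(rep(c("writer", "eraser", "reader"),
                        c(length(.M6A_WRITERS), length(.M6A_ERASERS),
                          length(.M6A_READERS))),
                    levels = c("writer", "eraser", "reader")),
      stringsAsFactors = FALSE
    )
    attr(reg, "canonical") <- TRUE
    class(reg) <- c("m6a_registry", "data.frame")
    return(reg)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, comment.char = "#",
                           strip.white = TRUE)
  if (ncol(tab) < 2) stopf("registry file needs two columns (symbol, role)")
  gene <- toupper(trimws(tab[[1]]))
  role <- tolower(trimws(tab[[2]]))
  if (any(!nzchar(gene))) stopf("registry file contains an empty gene symbol")
  if (any(gene == "WTA")) {
    message("registry: normalising symbol WTA -> WTAP")
    gene[gene == "WTA"] <- "WTAP"
  }
  if (anyDuplicated(gene))
    stopf("duplicate gene symbol in registry file: %s",
          paste(unique(gene[duplicated(gene)]), collapse = ", "))
  bad <- setdiff(unique(role), c("writer", "eraser", "reader"))
  if (length(bad)) stopf("unknown role token(s): %s", paste(bad, collapse = ", "))
  reg <- data.frame(gene = gene,
                    role = factor(role, levels = c("writer", "eraser", "reader")),
                    stringsAsFactors = FALSE)
  canon <- nrow(reg) == 24 &&
    all(table(reg$role)[c("writer", "eraser", "reader")] == c(10, 2, 12))
  if (!canon)
    message(sprintf("registry: non-canonical panel (%d genes: %s)",
                    nrow(reg), paste(table(reg$role), collapse = "/")))
  attr(reg, "canonical") <- canon
  class(reg) <- c("m6a_registry", "data.frame")
  reg
}

#' @export
print.m6a_registry <- function(x, ...) {
  cat(sprintf("m6A regulator registry: %d genes (%s)%s\n", nrow(x),
              paste(sprintf("%d %ss", table(x$role), levels(x$role)),
                    collapse = ", "),
              if (isTRUE(attr(x, "canonical"))) "" else " [non-canonical]"))
  print.data.frame(x, ...)
  invisible(x)
}
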