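# Readers and writers for the plain-text formats the pipeline touches:
# expression matrices (TSV/CSV), GMT gene-set collections, MAF-lite
# mutation tables, gene-level copy-number call matrices and clinical
# tables. All writers emit TSV with a header comment carrying the
# pipeline version; all readers skip '#' comment lines.

#' @noRd
guess_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene x sample expression matrix
#'
#' First column gene ids, header row sample ids. Duplicate gene rows are
#' collapsed to their per-sample maximum (the usual probe-to-gene
#' convention: deterministic and monotone). Missing values are rejected
#' by default, or imputed with the per-gene median.
#'
#' @param path TSV or CSV file (separator inferred from the extension).
#' @param unit Declared unit of the values: one of \code{"fpkm"},
#'   \code{"tpm"}, \code{"log2tpm"}, \code{"log2intensity"}.
#' @param na_action \code{"error"} (default) or \code{"impute_median"}.
#' @return Numeric matrix with gene rownames, sample colnames and a
#'   \code{unit} attribute.
#' @export
read_expression <- function(path, unit = c("fpkm", "tpm", "log2tpm", "log2intensity"),
                            na_action = c("error", "impute_median")) {
  unit <- match.arg(unit)
  na_action <- match.arg(na_action)
  tab <- utils::read.delim(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L) stopf("empty expression matrix in %s", path)
  genes <- as.character(tab[[1]])
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v) & toupper(trimws(v)) != "NA")
      if (length(bad))
        stopf("non-numeric cell at row %d, column '%s' in %s",
              bad[1], colnames(vals)[j], path)
      vals[[j]] <- suppress
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- genes
  if (anyNA(x)) {
    if (na_action == "error") {
      idx <- which(is.na(x), arr.ind = TRUE)[1, ]
      stopf("missing value at gene '%s', sample '%s' (use na_action = 'impute_median')",
            genes[idx[1]], colnames(x)[idx[2]])
    }
    for (i in which(rowSums(is.na(x)) > 0)) {
      med <- stats::median(x[i, ], na.rm = TRUE)
      if (is.na(med)) stopf("gene '%s' is entirely missing", genes[i])
      x[i, is.na(x[i, ])] <- med
    }
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    x <- collapse_max(x)
    message(sprintf("read_expression: collapsed %d duplicate gene row(s) by per-sample max", n_dup))
  }
  expr_unit(x) <- unit
  validate_expression(x)
}

#' @noRd
collapse_max <- function(x) {
  g <- factor(rownames(x), levels = unique(rownames(x)))
  out <- do.call(rbind, lapply(levels(g), function(gn) {
    rows <- x[g == gn, , drop = FALSE]
    if (nrow(rows) == 1L) rows[1, ] else apply(rows, 2, max)
  }))
  rownames(out) <- levels(g)
  colnames(out) <- colnames(x)
  out
}

#' Write an expression matrix as TSV
#'
#' @param x matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s expression matrix (unit: %s)", PIPELINE_VERSION, expr_unit(x)), con)
  utils::write.table(data.frame(gene = rownames(x), x, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, \code{name TAB description TAB gene...}.
#' The description column is discarded; duplicated genes within a set are
#' removed (reported via \code{message()}).
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- list()
  n_dedup <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stopf("GMT line %d has fewer than 3 fields", i)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      n_dedup <- n_dedup + sum(duplicated(genes))
      genes <- unique(genes)
    }
    if (!length(genes)) stopf("GMT line %d defines an empty set", i)
    if (f[1] %in% names(sets)) stopf("duplicate gene-set name '%s' (line %d)", f[1], i)
    sets[[f[1]]] <- genes
  }
  if (n_dedup > 0)
    message(sprintf("read_gmt: removed %d duplicated gene(s) within sets", n_dedup))
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# Canonical MAF Variant_Classification tokens -> the simplified classes
# the pipeline models.
.MAF_CLASS_MAP <- c(
  "Missense_Mutation" = "missense",
  "Nonsense_Mutation" = "nonsense",
  "Frame_Shift_Del"   = "frameshift",
  "Frame_Shift_Ins"   = "frameshift",
  "Splice_Site"       = "splice",
  "In_Frame_Del"      = "in_frame",
  "In_Frame_Ins"      = "in_frame",
  "Silent"            = "silent"
)
.VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                      "in_frame", "silent", "other")

#' Read a MAF-lite somatic mutation table
#'
#' Requires columns \code{Tumor_Sample_Barcode}, \code{Hugo_Symbol},
#' \code{Variant_Classification} (full MAF tokens or the simplified
#' classes \code{missense/nonsense/frameshift/splice/in_frame/silent/other};
#' unrecognised tokens map to \code{other}). Duplicate
#' (sample, gene, class) records are allowed: multiple hits.
#'
#' @param path TSV file.
#' @return data.frame with columns \code{sample}, \code{gene},
#'   \code{variant_class}.
#' @export
read_mutations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol", "Variant_Classification")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("mutation table is missing column(s): %s", paste(miss, collapse = ", "))
  sample <- as.character(tab$Tumor_Sample_Barcode)
  gene <- as.character(tab$Hugo_Symbol)
  if (any(!nzchar(sample)) || any(!nzchar(gene)))
    stopf("mutation table contains empty sample or gene ids")
  raw <- as.character(tab$Variant_Classification)
  cls <- ifelse(raw %in% names(.MAF_CLASS_MAP), .MAF_CLASS_MAP[raw],
                ifelse(tolower(raw) %in% .VARIANT_CLASSES, tolower(raw), "other"))
  data.frame(sample = sample, gene = gene,
             variant_class = factor(cls, levels = .VARIANT_CLASSES),
             stringsAsFactors = FALSE)
}

#' Read a gene x sample copy-number call matrix
#'
#' Integer calls in \{-2, -1, 0, 1, 2\} (deletion ... amplification).
#'
#' @param path TSV/CSV, first column gene ids.
#' @return Integer matrix.
#' @export
read_cnv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  x <- as.matrix(tab[, -1, drop = FALSE])
  rownames(x) <- as.character(tab[[1]])
  if (anyNA(x) || any(x != round(x)) || any(x < -2) || any(x > 2)) {
    idx <- which(is.na(x) | x != round(x) | x < -2 | x > 2, arr.ind = TRUE)[1, ]
    stopf("CNV call outside {-2..2} at gene '%s', sample '%s'",
          rownames(x)[idx[1]], colnames(x)[idx[2]])
  }
  storage.mode(x) <- "integer"
  x
}

#' Read a per-sample clinical table
#'
#' Expected columns (rename via \code{column_map}): \code{sample},
#' \code{time}, \code{event}, and optionally \code{stage}, \code{t_cat},
#' \code{n_cat}, \code{m_cat}, \code{age}, \code{sex},
#' \code{radiotherapy}. Rows with missing or non-positive \code{time} or
#' missing \code{event} are dropped; the count is stored in the
#' \code{n_excluded} attribute (the cohort-assembly rule: patients
#' without survival information are excluded).
#'
#' @param path TSV/CSV file.
#' @param column_map optional named character vector mapping the standard
#'   names to the file's column names, e.g.
#'   \code{c(sample = "barcode", time = "OS.time", event = "OS")}.
#' @param time_unit declared unit of \code{time} ("days" or "months");
#'   never inferred.
#' @return data.frame keyed by \code{sample} with attributes
#'   \code{n_excluded} and \code{time_unit}.
#' @export
read_clinical <- function(path, column_map = NULL, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  tab <- utils::read.delim(path, header = TRUE, sep = guess_sep(path),
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(column_map))
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% colnames(tab))
        stopf("clinical column '%s' (mapped to '%s') not found", column_map[[std]], std)
      colnames(tab)[colnames(tab) == column_map[[std]]] <- std
    }
  need <- c("sample", "time", "event")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("clinical table is missing column(s): %s", paste(miss, collapse = ", "))
  tab$time <- suppressWarnings(as.numeric(tab$time))
  tab$event <- suppressWarnings(as.integer(tab$event))
  keep <- !is.na(tab$time) & tab$time > 0 & !is.na(tab$event) & tab$event %in% c(0L, 1L)
  n_excluded <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  if (anyDuplicated(tab$sample)) stopf("duplicate sample ids in clinical table")
  for (col in c("stage", "t_cat", "n_cat", "m_cat", "sex", "radiotherapy"))
    if (col %in% colnames(tab)) tab[[col]] <- as.factor(tab[[col]])
  rownames(tab) <- NULL
  attr(tab, "n_excluded") <- n_excluded
  attr(tab, "time_unit") <- time_unit
  if (n_excluded > 0)
    message(sprintf("read_clinical: excluded %d row(s) without usable survival information", n_excluded))
  tab
}

#' Write a data.frame as versioned TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", PIPELINE_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
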