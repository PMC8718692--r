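# End-to-end orchestration: preprocess -> consensus clustering on the
# regulator panel -> immune/pathway enrichment -> pairwise DEGs and their
# intersection -> prognostic filter -> gene clusters -> PCA score ->
# score/TMB stratification -> survival reports. Every stage writes TSV
# intermediates and contributes a hashed entry to the run report, so a
# rerun with the same config and seed reproduces every output hash.

#' Pipeline run configuration
#'
#' @param k_range candidate cluster numbers for both consensus stages.
#' @param reps consensus resampling repetitions.
#' @param p_item consensus item-subsampling proportion.
#' @param alpha ssGSEA rank-weighting exponent.
#' @param p_cut raw p-value cut for phenotype DEGs.
#' @param cox_p univariate Cox p-value cut of the prognostic filter.
#' @param minprop minimum group proportion for cutpoint searches.
#' @param seed base RNG seed for all resampling.
#' @param outdir output directory (created if missing).
#' @return list of class \code{m6a_run_config}.
#' @export
run_config <- function(k_range = 2:6, reps = 1000, p_item = 0.8, alpha = 0.25,
                       p_cut = 0.001, cox_p = 0.05, minprop = 0.1,
                       seed = 1L, outdir = tempfile("m6a_run_")) {
  cfg <- as.list(environment())
  if (any(k_range < 2)) stopf("k_range must start at 2")
  if (reps < 1) stopf("reps must be >= 1")
  if (p_item <= 0 || p_item > 1) stopf("p_item must be in (0, 1]")
  if (p_cut <= 0 || p_cut > 1 || cox_p <= 0 || cox_p > 1) stopf("p cuts must be in (0, 1]")
  if (minprop <= 0 || minprop >= 0.5) stopf("minprop must be in (0, 0.5)")
  class(cfg) <- "m6a_run_config"
  cfg
}

#' @noRd
stage_entry <- function(report, name, params, outputs, files = character(0), warnings = character(0)) {
  hashes <- if (length(files)) tools::md5sum(files) else character(0)
  report$stages[[name]] <- list(params = params, outputs = outputs,
                                file_hashes = hashes, warnings = warnings)
  report
}

#' Run the full analysis pipeline
#'
#' Executes the whole workflow on an expression matrix (or list of
#' cohort matrices), a clinical table and optional mutation data. Stage
#' order: meta-cohort assembly, consensus clustering of samples on the
#' regulator panel (the m6A clusters), ssGSEA enrichment of the supplied
#' gene sets, pairwise cluster DEGs and their intersection, univariate
#' Cox prognostic filtering, a second consensus clustering on the
#' prognostic signature (the gene clusters), PCA score fitting and
#' stratification, TMB and combined strata, and survival summaries.
#'
#' @param cohorts a single gene x sample matrix or a named list of them
#'   (units taken from each matrix's \code{unit} attribute).
#' @param clinical clinical table with columns sample/time/event.
#' @param mutations optional mutation table; when absent the TMB stages
#'   are skipped with a warning.
#' @param gene_sets optional named list of gene sets for the enrichment
#'   stage.
#' @param registry regulator panel (default: the built-in 24).
#' @param config a \code{\link{run_config}}.
#' @return object of class \code{m6a_run}: per-stage report entries plus
#'   the key objects (labels, signature, score model, score table).
#' @export
run_m6a_pipeline <- function(cohorts, clinical, mutations = NULL,
                             gene_sets = NULL, registry = load_registry(),
                             config = run_config()) {
  if (!inherits(config, "m6a_run_config")) stopf("config must come from run_config()")
  if (is.matrix(cohorts)) cohorts <- list(cohort1 = cohorts)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(version = PIPELINE_VERSION, config = unclass(config),
                 stages = list())
  out <- function(...) file.path(config$outdir, ...)
  for (d in c("preprocess", "clusters", "enrichment", "degs", "survival", "score"))
    dir.create(out(d), showWarnings = FALSE)

  ## 1. preprocess ----------------------------------------------------
  meta <- build_meta_cohort(cohorts, names(cohorts))
  x <- meta$matrix
  common <- intersect(clinical$sample, colnames(x))
  if (length(common) < ncol(x))
    warnf("pipeline: %d sample(s) lack clinical rows and are kept only for expression stages",
          ncol(x) - length(common))
  clin <- clinical[match(common, clinical$sample), ]
  f_meta <- out("preprocess", "meta_matrix.tsv")
  write_expression(x, f_meta)
  report <- stage_entry(report, "preprocess",
                        params = list(cohorts = names(cohorts)),
                        outputs = list(n_genes = nrow(x), n_samples = ncol(x),
                                       n_common_genes = length(meta$genes_common)),
                        files = f_meta)

  ## 2. consensus clustering on the regulator panel --------------------
  panel <- intersect(registry$gene, rownames(x))
  if (length(panel) < 2L) stopf("fewer than 2 regulator genes present after intersection")
  cc <- consensus_cluster(x[panel, , drop = FALSE], k_range = config$k_range,
                          reps = config$reps, p_item = config$p_item,
                          seed = config$seed)
  m6a_cluster <- factor(LETTERS[cc$labels[[as.character(cc$chosen_k)]]])
  names(m6a_cluster) <- colnames(x)
  f_cl <- out("clusters", "m6a_clusters.tsv")
  write_tsv(data.frame(sample = names(m6a_cluster), m6a_cluster = m6a_cluster,
                       stringsAsFactors = FALSE), f_cl)
  f_diag <- out("clusters", "k_diagnostics.tsv")
  write_tsv(data.frame(k = cc$k_range, cdf_area = cc$cdf_area,
                       delta_area = cc$delta_area, pac = cc$pac), f_diag)
  report <- stage_entry(report, "consensus_cluster",
                        params = config[c("k_range", "reps", "p_item", "seed")],
                        outputs = list(chosen_k = cc$chosen_k,
                                       n_regulators = length(panel),
                                       sizes = as.list(table(m6a_cluster))),
                        files = c(f_cl, f_diag))

  ## 3. enrichment ------------------------------------------------------
  if (!is.null(gene_sets) && length(gene_sets)) {
    scores <- score_collection(x, gene_sets, alpha = config$alpha)
    f_enr <- out("enrichment", "ssgsea_scores.tsv")
    write_tsv(data.frame(set = rownames(scores), scores, check.names = FALSE), f_enr)
    report <- stage_entry(report, "enrichment",
                          params = list(alpha = config$alpha, n_sets = length(gene_sets)),
                          outputs = list(n_sets = nrow(scores)),
                          files = f_enr)
  }

  ## 4. DEGs and phenotype signature ------------------------------------
  degs <- list(); overlap <- character(0)
  if (cc$chosen_k < 3L) {
    warnf("pipeline: chosen k = %d < 3; the three-way DEG intersection and downstream signature stages are skipped",
          cc$chosen_k)
    sel <- logical(0)
  } else if (cc$chosen_k > 3L) {
    warnf("pipeline: chosen k = %d; DEG intersection is defined for 3 clusters - using the 3 largest",
          cc$chosen_k)
    keep_lv <- names(sort(table(m6a_cluster), decreasing = TRUE))[1:3]
    sel <- m6a_cluster %in% keep_lv
  } else sel <- rep(TRUE, ncol(x))
  if (any(sel)) {
    degs <- pairwise_cluster_degs(x[, sel, drop = FALSE],
                                  droplevels(m6a_cluster[sel]), p_cut = config$p_cut)
    overlap <- suppressWarnings(intersect_degs(degs))
  }
  f_deg <- out("degs", "overlap.txt")
  writeLines(overlap, f_deg)
  report <- stage_entry(report, "diffexp",
                        params = list(p_cut = config$p_cut),
                        outputs = c(lapply(degs, length), list(overlap = length(overlap))),
                        files = f_deg)

  ## 5. prognostic filter ------------------------------------------------
  xc <- x[, common, drop = FALSE]
  prog <- character(0)
  cox_tab <- NULL
  if (length(overlap)) {
    cox_tab <- do.call(rbind, lapply(overlap, function(g) {
      fit <- cox_univariate(clin$time, clin$event, xc[g, ])
      data.frame(gene = g, hr = fit$hr, beta = fit$beta, p_value = fit$p_value,
                 stringsAsFactors = FALSE)
    }))
    prog <- cox_tab$gene[cox_tab$p_value < config$cox_p]
  }
  f_prog <- out("degs", "prognostic.tsv")
  if (!is.null(cox_tab)) write_tsv(cox_tab, f_prog) else writeLines(character(0), f_prog)
  report <- stage_entry(report, "prognostic_filter",
                        params = list(cox_p = config$cox_p),
                        outputs = list(n_overlap = length(overlap),
                                       n_prognostic = length(prog)),
                        files = f_prog)

  ## 6. gene clusters on the prognostic signature ------------------------
  gene_cluster <- NULL
  if (length(prog) >= 2L) {
    gc <- consensus_cluster(x[prog, , drop = FALSE], k_range = config$k_range,
                            reps = config$reps, p_item = config$p_item,
                            seed = config$seed + 1L)
    gene_cluster <- factor(letters[gc$labels[[as.character(gc$chosen_k)]]])
    names(gene_cluster) <- colnames(x)
    f_gc <- out("clusters", "gene_clusters.tsv")
    write_tsv(data.frame(sample = names(gene_cluster), gene_cluster = gene_cluster,
                         stringsAsFactors = FALSE), f_gc)
    report <- stage_entry(report, "gene_cluster",
                          params = list(seed = config$seed + 1L),
                          outputs = list(chosen_k = gc$chosen_k,
                                         sizes = as.list(table(gene_cluster))),
                          files = f_gc)
  } else {
    warnf("pipeline: <2 prognostic genes; gene-cluster stage skipped")
  }

  ## 7. scoring -----------------------------------------------------------
  score_table <- NULL; model <- NULL
  if (length(prog) >= 3L) {
    model <- fit_score_model(x, prog)
    score <- m6a_score(model, xc)
    strat <- stratify_score(score, clin$time, clin$event, minprop = config$minprop)
    score_table <- data.frame(sample = common, m6a_score = score,
                              score_group = strat$group,
                              stringsAsFactors = FALSE)
    tmb_warn <- character(0)
    if (!is.null(mutations)) {
      tmb <- suppressWarnings(tmb_per_sample(mutations, samples = common))
      tmb_cp <- max_sel_cutpoint(clin$time, clin$event, tmb, minprop = config$minprop)
      score_table$tmb <- tmb
      score_table$tmb_group <- factor(ifelse(tmb > tmb_cp$cutpoint, "high", "low"),
                                      levels = c("low", "high"))
      strata <- combine_strata(score_table$score_group, score_table$tmb_group,
                               clin$time, clin$event)
      score_table$stratum <- as.character(strata$stratum)
    } else {
      tmb_warn <- "no mutation table supplied; TMB stages skipped"
      warnf("pipeline: %s", tmb_warn)
    }
    f_score <- out("score", "score_table.tsv")
    write_tsv(score_table, f_score)
    report <- stage_entry(report, "scoring",
                          params = list(minprop = config$minprop),
                          outputs = list(cutpoint = strat$cutpoint,
                                         n_high = sum(strat$group == "high"),
                                         n_low = sum(strat$group == "low"),
                                         explained = model$explained),
                          files = f_score, warnings = tmb_warn)
  } else {
    warnf("pipeline: <3 prognostic genes; scoring stage skipped")
  }

  ## 8. survival reports ---------------------------------------------------
  surv_out <- list()
  grp_sets <- list(m6a_cluster = m6a_cluster[common])
  if (!is.null(gene_cluster)) grp_sets$gene_cluster <- gene_cluster[common]
  if (!is.null(score_table)) grp_sets$score_group <- score_table$score_group
  if (!is.null(score_table$stratum)) grp_sets$stratum <- factor(score_table$stratum)
  for (nm in names(grp_sets)) {
    lt <- logrank_test(clin$time, clin$event, grp_sets[[nm]])
    surv_out[[nm]] <- lt
  }
  f_surv <- out("survival", "logrank.tsv")
  write_tsv(data.frame(grouping = names(surv_out),
                       chisq = vapply(surv_out, `[[`, numeric(1), "chisq"),
                       df = vapply(surv_out, `[[`, numeric(1), "df"),
                       p_value = vapply(surv_out, `[[`, numeric(1), "p_value")),
            f_surv)
  report <- stage_entry(report, "survival",
                        params = list(),
                        outputs = lapply(surv_out, `[[`, "p_value"),
                        files = f_surv)

  res <- list(report = report, meta = meta, consensus = cc,
              m6a_cluster = m6a_cluster, degs = degs, signature = overlap,
              prognostic = prog, gene_cluster = gene_cluster,
              score_model = model, score_table = score_table,
              survival = surv_out, outdir = config$outdir)
  class(res) <- "m6a_run"
  res
}

#' All output-file hashes of a run
#'
#' Concatenated md5 hashes of every file the run wrote, keyed by stage;
#' two runs with identical config and seed produce identical hash sets.
#'
#' @param run an \code{m6a_run}.
#' @return named character vector of md5 hashes.
#' @export
run_hashes <- function(run) {
  unlist(lapply(run$report$stages, function(s) unname(s$file_hashes)))
}

#' @export
print.m6a_run <- function(x, ...) {
  cat(sprintf("%s pipeline run: %d stages\n", PIPELINE_VERSION,
              length(x$report$stages)))
  cat(sprintf("  m6A clusters: k = %d (%s)\n", x$consensus$chosen_k,
              paste(table(x$m6a_cluster), collapse = "/")))
  cat(sprintf("  phenotype signature: %d DEGs, %d prognostic\n",
              length(x$signature), length(x$prognostic)))
  if (!is.null(x$score_table))
    cat(sprintf("  m6A score groups: %d high / %d low\n",
                sum(x$score_table$score_group == "high"),
                sum(x$score_table$score_group == "low")))
  for (nm in names(x$survival))
    cat(sprintf("  log-rank (%s): chi2 = %.2f, p = %.3g\n", nm,
                x$survival[[nm]]$chisq, x$survival[[nm]]$p_value))
  invisible(x)
}
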