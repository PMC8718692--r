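# Synthetic cohort generator: three latent molecular clusters expressed
# on the 24-gene regulator panel plus a phenotype signature,
# cluster-dependent exponential survival with administrative censoring,
# negative-binomial mutation counts linked to a per-sample latent score,
# copy-number calls, and block-structured immune-cell signatures. Ground
# truth is exposed for parameter-recovery testing.

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the study conditions the rest of the package is
#' validated under: three clusters of 100 samples; the 24-regulator
#' panel carrying the cluster structure at 2 SD effect; 80 signature
#' genes of which 50 are pan-cluster markers; exponential survival with
#' per-cluster rates 0.020 (cluster A, worst), 0.008 (B, best) and 0.012
#' (C) per month under Uniform(0, 120)-month administrative censoring;
#' negative-binomial mutation counts with mean 8 in the low-latent-score
#' half and 4 in the high half (dispersion 2); 23 disjoint immune-cell
#' signatures of 20 genes upshifted by 1 SD in cluster C.
#'
#' @param n_per_cluster samples per cluster (length 3).
#' @param cluster_effect cluster mean shift in noise-SD units.
#' @param noise_sd residual SD of expression.
#' @param n_signature total signature genes; \code{n_markers} of them are
#'   pan-cluster markers (differential in every pairwise contrast).
#' @param n_background additional null genes.
#' @param hazard per-cluster exponential event rates per month (A, B, C).
#' @param censor_max administrative censoring horizon in months;
#'   \code{censoring = FALSE} disables censoring entirely.
#' @param tmb_mean_low,tmb_mean_high,tmb_dispersion negative-binomial
#'   parameters of the nonsilent mutation count by latent-score half.
#' @param n_immune_sets,immune_set_size,immune_upshift immune signature
#'   block layout and the cluster-C shift in SD units.
#' @param cnv_gain_rate,cnv_loss_rate per-cell probabilities of a
#'   gain/loss call on the regulator panel.
#' @return list of class \code{m6a_sim_config}.
#' @export
m6a_sim_config <- function(n_per_cluster = c(100, 100, 100),
                           cluster_effect = 2.0, noise_sd = 1.0,
                           n_signature = 80, n_markers = 50,
                           n_background = 100,
                           hazard = c(A = 0.020, B = 0.008, C = 0.012),
                           censor_max = 120, censoring = TRUE,
                           tmb_mean_low = 8, tmb_mean_high = 4,
                           tmb_dispersion = 2,
                           n_immune_sets = 23, immune_set_size = 20,
                           immune_upshift = 1.0,
                           cnv_gain_rate = 0.15, cnv_loss_rate = 0.15) {
  cfg <- as.list(environment())
  bad <- character(0)
  if (length(cfg$n_per_cluster) != 3 || any(cfg$n_per_cluster < 1)) bad <- c(bad, "n_per_cluster")
  if (length(cfg$hazard) != 3 || any(cfg$hazard <= 0)) bad <- c(bad, "hazard")
  if (cfg$n_markers > cfg$n_signature) bad <- c(bad, "n_markers")
  if (cfg$noise_sd <= 0) bad <- c(bad, "noise_sd")
  if (!is.finite(cfg$cluster_effect)) bad <- c(bad, "cluster_effect")
  if (any(c(cfg$tmb_mean_low, cfg$tmb_mean_high, cfg$tmb_dispersion) <= 0)) bad <- c(bad, "tmb")
  if (cfg$cnv_gain_rate + cfg$cnv_loss_rate >= 1) bad <- c(bad, "cnv rates")
  if (length(bad)) stopf("invalid generator config field(s): %s", paste(bad, collapse = ", "))
  class(cfg) <- "m6a_sim_config"
  cfg
}

#' Generate a synthetic LUAD-like cohort
#'
#' Expression is a cluster-mean matrix plus Gaussian noise on a log2
#' scale. The regulator panel carries the cluster structure (three
#' blocks of 8 regulators, block j upshifted in cluster j). The latent
#' per-sample score is +1 in cluster B (best prognosis, highest score),
#' 0 in C and -1 in A, plus N(0, 0.3) noise; pan-cluster marker genes
#' increase with the latent, so a PCA score fitted on them rises toward
#' cluster B. Mutation counts follow the configured negative binomial
#' with the high-count mean in the low-latent half (high score implies
#' low TMB). All draws are deterministic under \code{seed}.
#'
#' @param config a \code{\link{m6a_sim_config}}.
#' @param seed integer RNG seed.
#' @return object of class \code{m6a_bundle}: list with
#'   \code{expression} (genes x samples, unit log2tpm), \code{clinical},
#'   \code{mutations}, \code{cnv}, \code{gene_sets} (immune signatures
#'   plus immune/stromal), \code{registry}, and \code{truth} (cluster,
#'   latent_score, markers, hazards, tmb_group).
#' @export
generate_m6a_data <- function(config = m6a_sim_config(), seed = 1L) {
  if (!inherits(config, "m6a_sim_config")) stopf("config must come from m6a_sim_config()")
  with_seed(seed, {
    n_cl <- config$n_per_cluster
    n <- sum(n_cl)
    cluster <- factor(rep(c("A", "B", "C"), n_cl), levels = c("A", "B", "C"))
    samples <- sprintf("S%04d", seq_len(n))
    names(cluster) <- samples
    latent_by_cluster <- c(A = -1, B = 1, C = 0)
    latent <- latent_by_cluster[as.character(cluster)] + stats::rnorm(n, 0, 0.3)
    names(latent) <- samples

    reg <- load_registry()
    regulators <- reg$gene
    markers <- sprintf("SIG%03d", seq_len(config$n_markers))
    nulls <- sprintf("SIG%03d", seq(config$n_markers + 1, config$n_signature))
    background <- sprintf("BG%03d", seq_len(config$n_background))
    imm_sets <- lapply(seq_len(config$n_immune_sets), function(j)
      sprintf("IMM%02d_%03d", j, seq_len(config$immune_set_size)))
    names(imm_sets) <- sprintf("immune_cell_%02d", seq_len(config$n_immune_sets))
    stromal <- sprintf("STR_%03d", seq_len(config$immune_set_size))
    genes <- c(regulators, markers, nulls, background, unlist(imm_sets), stromal)

    base <- stats::rnorm(length(genes), mean = 6, sd = 1.5)
    names(base) <- genes
    mu <- matrix(base, length(genes), n, dimnames = list(genes, samples))

    # regulator panel: three blocks of 8, block j elevated in cluster j
    block <- rep(1:3, each = 8)
    for (j in 1:3) {
      sel <- cluster == levels(cluster)[j]
      mu[regulators[block == j], sel] <- mu[regulators[block == j], sel] +
        config$cluster_effect * config$noise_sd
    }
    # pan-cluster markers track the latent score (distinct means in all
    # three clusters: -e, +e, 0)
    mu[markers, ] <- mu[markers, ] +
      config$cluster_effect * config$noise_sd *
      rep(latent_by_cluster[as.character(cluster)], each = length(markers))
    # immune blocks: per-set per-sample co-expression factor + cluster-C shift
    shiftC <- config$immune_upshift * config$noise_sd * (cluster == "C")
    for (j in seq_along(imm_sets)) {
      f <- stats::rnorm(n, 0, 0.6) + shiftC
      mu[imm_sets[[j]], ] <- mu[imm_sets[[j]], ] + rep(f, each = config$immune_set_size)
    }
    f_str <- stats::rnorm(n, 0, 0.6) + shiftC
    mu[stromal, ] <- mu[stromal, ] + rep(f_str, each = length(stromal))

    expr <- mu + matrix(stats::rnorm(length(mu), 0, config$noise_sd),
                        nrow(mu), ncol(mu))
    dimnames(expr) <- dimnames(mu)
    expr_unit(expr) <- "log2tpm"

    # survival: exponential per cluster, administrative censoring
    rate <- config$hazard[as.integer(cluster)]
    t_event <- stats::rexp(n, rate)
    if (config$censoring) {
      t_cens <- stats::runif(n, 0, config$censor_max)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    time <- pmax(time, 1e-3)
    stage_p <- cbind(`I` = 0.45 + 0.1 * latent, `II` = 0.25,
                     `III` = 0.2 - 0.05 * latent, `IV` = 0.1 - 0.05 * latent)
    stage_p[stage_p < 0.01] <- 0.01
    stage <- apply(stage_p, 1, function(p) sample(c("I", "II", "III", "IV"), 1, prob = p))
    clinical <- data.frame(
      sample = samples, time = time, event = event,
      stage = factor(stage, levels = c("I", "II", "III", "IV")),
      t_cat = factor(sample(c("T1", "T2", "T3", "T4"), n, TRUE, c(.3, .4, .2, .1))),
      n_cat = factor(sample(c("N0", "N1", "N2"), n, TRUE, c(.6, .25, .15))),
      m_cat = factor(sample(c("M0", "M1"), n, TRUE, c(.9, .1))),
      age = round(stats::rnorm(n, 65, 10), 1),
      sex = factor(sample(c("female", "male"), n, TRUE)),
      radiotherapy = factor(sample(c("yes", "no"), n, TRUE, c(.3, .7)),
                            levels = c("no", "yes")),
      stringsAsFactors = FALSE)
    attr(clinical, "time_unit") <- "months"

    # mutations: NB nonsilent count by latent-score half, plus silent extras
    tmb_group <- factor(ifelse(latent > stats::median(latent), "high", "low"),
                        levels = c("low", "high"))
    mu_tmb <- ifelse(tmb_group == "high", config$tmb_mean_high, config$tmb_mean_low)
    n_nonsil <- stats::rnbinom(n, size = config$tmb_dispersion, mu = mu_tmb)
    n_sil <- stats::rpois(n, 0.15 * pmax(n_nonsil, 1))
    mut_pool <- c(sprintf("MUT%03d", 1:200), regulators)
    nonsil_classes <- c("missense", "nonsense", "frameshift", "splice", "in_frame")
    recs <- lapply(seq_len(n), function(i) {
      k <- n_nonsil[i] + n_sil[i]
      if (k == 0) return(NULL)
      data.frame(sample = samples[i],
                 gene = sample(mut_pool, k, replace = TRUE),
                 variant_class = c(sample(nonsil_classes, n_nonsil[i], TRUE,
                                          c(.6, .1, .12, .08, .1)),
                                   rep("silent", n_sil[i])),
                 stringsAsFactors = FALSE)
    })
    mutations <- do.call(rbind, recs)
    mutations$variant_class <- factor(mutations$variant_class, levels = .VARIANT_CLASSES)

    # CNV calls on the regulator panel
    p0 <- 1 - config$cnv_gain_rate - config$cnv_loss_rate
    calls <- sample(c(-2L, -1L, 0L, 1L, 2L), length(regulators) * n, TRUE,
                    prob = c(config$cnv_loss_rate * 0.25, config$cnv_loss_rate * 0.75,
                             p0,
                             config$cnv_gain_rate * 0.75, config$cnv_gain_rate * 0.25))
    cnv <- matrix(calls, length(regulators), n, dimnames = list(regulators, samples))

    gene_sets <- c(imm_sets, list(immune_signature = unlist(imm_sets, use.names = FALSE),
                                  stromal_signature = stromal))

    bundle <- list(expression = expr, clinical = clinical, mutations = mutations,
                   cnv = cnv, gene_sets = gene_sets, registry = reg,
                   truth = list(cluster = cluster, latent_score = latent,
                                markers = markers, hazards = config$hazard,
                                tmb_group = tmb_group),
                   config = config, seed = seed)
    class(bundle) <- "m6a_bundle"
    bundle
  })
}

#' @export
print.m6a_bundle <- function(x, ...) {
  cat(sprintf("synthetic m6A cohort: %d genes x %d samples; clusters %s; seed %d\n",
              nrow(x$expression), ncol(x$expression),
              paste(table(x$truth$cluster), collapse = "/"), x$seed))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement by the contingency-table formula
#' (delegated to \code{mclust::adjustedRandIndex}).
#'
#' @param a,b two label vectors over the same items.
#' @return ARI in [-1, 1]; 1 = identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions differ in length")
  mclust::adjustedRandIndex(a, b)
}

#' Recovery metrics of pipeline outputs against generator truth
#'
#' @param bundle an \code{m6a_bundle}.
#' @param labels estimated cluster labels named by sample id.
#' @param degs optional estimated marker gene list (gives marker
#'   sensitivity and FDR against the planted markers).
#' @return list: ari, and when \code{degs} given, marker_sensitivity,
#'   marker_fdr.
#' @export
truth_report <- function(bundle, labels, degs = NULL) {
  if (is.null(names(labels)) || !setequal(names(labels), names(bundle$truth$cluster)))
    stopf("labels must be named by, and cover, the bundle's sample ids")
  labels <- labels[names(bundle$truth$cluster)]
  out <- list(ari = adjusted_rand_index(bundle$truth$cluster, labels))
  if (!is.null(degs)) {
    truth_markers <- bundle$truth$markers
    tp <- length(intersect(degs, truth_markers))
    out$marker_sensitivity <- tp / length(truth_markers)
    out$marker_fdr <- if (length(degs)) 1 - tp / length(degs) else 0
  }
  out
}
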