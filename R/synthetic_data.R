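#' Simulation configuration for multi-study bulk expression
#'
#' Defines the conditions of the synthetic multi-study experiment: several
#' small studies sharing a set of consensus differentially expressed genes
#' (homogeneous direction, per-study effect-size variation), a set of
#' discordant genes that are DE in exactly one study, study-level additive
#' offsets, and optional platform dropout of genes per study.
#'
#' Defaults mirror the designs of small dendritic-cell profiling studies:
#' five studies of 4 samples per phenotype on 10,000 genes, 100 consensus-up
#' and 100 consensus-down genes with per-study log2 effects drawn from
#' N(1.5, 0.25^2) of a fixed common sign, and 50 discordant genes.
#'
#' Per-gene residual variances follow the scaled inverse-chi-square law
#' `s0_sim * d0_sim / chisq(d0_sim)` of the hierarchical model assumed by
#' the empirical-Bayes moderation stage, with prior variance
#' `s0_sim = noise_sd^2` by default (so `noise_sd` is the typical residual
#' sd) and prior degrees of freedom `d0_sim = 4` (moderate gene-to-gene
#' variance heterogeneity, as seen in small array studies). Setting
#' `d0_sim = Inf` gives constant residual sd `noise_sd` for every gene.
#'
#' @param n_studies,n_genes,n_per_group positive integers.
#' @param n_consensus_up,n_consensus_down,n_discordant non-negative integers;
#'   their sum must not exceed `n_genes`.
#' @param effect_mean,effect_sd mean and sd of per-study true log2 effects
#'   for consensus genes.
#' @param noise_sd within-group residual sd when `d0_sim` is infinite.
#' @param study_offset_sd sd of the per-study, per-gene additive shift.
#' @param d0_sim,s0_sim prior degrees of freedom and prior variance of the
#'   per-gene variance distribution (`d0_sim = Inf` for constant variance).
#' @param platform_dropout fraction in [0, 1) of genes absent per study.
#' @param case_label,control_label phenotype labels used in the simulated
#'   annotation.
#' @param expression_scale `"log2"` (default) emits microarray-like log2
#'   values; `"intensity"` emits `2^x` to exercise the log-transform path.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_studies = 5, n_genes = 10000, n_per_group = 4,
                       n_consensus_up = 100, n_consensus_down = 100,
                       n_discordant = 50,
                       effect_mean = 1.5, effect_sd = 0.25,
                       noise_sd = 0.5, study_offset_sd = 0.25,
                       d0_sim = 4, s0_sim = noise_sd^2,
                       platform_dropout = 0,
                       case_label = "tolDC", control_label = "imDC",
                       expression_scale = c("log2", "intensity"),
                       seed = 1L) {
  expression_scale <- match.arg(expression_scale)
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x))
      stop(sprintf("invalid `%s`: must be an integer >= %d", nm, min), call. = FALSE)
  }
  chk_count(n_studies, "n_studies"); chk_count(n_genes, "n_genes")
  chk_count(n_per_group, "n_per_group", min = 2)
  chk_count(n_consensus_up, "n_consensus_up", 0)
  chk_count(n_consensus_down, "n_consensus_down", 0)
  chk_count(n_discordant, "n_discordant", 0)
  if (n_consensus_up + n_consensus_down + n_discordant > n_genes)
    stop("invalid `n_consensus_up`/`n_consensus_down`/`n_discordant`: ",
         "their sum exceeds `n_genes`", call. = FALSE)
  chk_real <- function(x, nm, min = -Inf) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min)
      stop(sprintf("invalid `%s`", nm), call. = FALSE)
  }
  chk_real(effect_mean, "effect_mean")
  chk_real(effect_sd, "effect_sd", 0)
  chk_real(noise_sd, "noise_sd", 0)
  if (noise_sd <= 0) stop("invalid `noise_sd`: must be positive", call. = FALSE)
  chk_real(study_offset_sd, "study_offset_sd", 0)
  if (!(length(d0_sim) == 1 && is.numeric(d0_sim) && d0_sim > 0))
    stop("invalid `d0_sim`: must be positive (possibly Inf)", call. = FALSE)
  chk_real(s0_sim, "s0_sim", 0)
  if (s0_sim <= 0) stop("invalid `s0_sim`: must be positive", call. = FALSE)
  if (length(platform_dropout) != 1 || !is.numeric(platform_dropout) ||
      is.na(platform_dropout) || platform_dropout < 0 || platform_dropout >= 1)
    stop("invalid `platform_dropout`: must be in [0, 1)", call. = FALSE)
  if (length(seed) != 1 || !is.numeric(seed) || is.na(seed) || seed != round(seed))
    stop("invalid `seed`: must be an integer", call. = FALSE)
  structure(list(
    n_studies = as.integer(n_studies), n_genes = as.integer(n_genes),
    n_per_group = as.integer(n_per_group),
    n_consensus_up = as.integer(n_consensus_up),
    n_consensus_down = as.integer(n_consensus_down),
    n_discordant = as.integer(n_discordant),
    effect_mean = effect_mean, effect_sd = effect_sd,
    noise_sd = noise_sd, study_offset_sd = study_offset_sd,
    d0_sim = d0_sim, s0_sim = s0_sim,
    platform_dropout = platform_dropout,
    case_label = case_label, control_label = control_label,
    expression_scale = expression_scale,
    seed = as.integer(seed)), class = "sim_config")
}

# Per-study seed derived from the master seed so that adding studies never
# changes the draws of earlier studies.
study_seed <- function(seed, s) {
  as.integer((abs(as.numeric(seed)) + 104729 * s) %% 2147483647)
}

#' Simulate a multi-study bulk expression experiment with known truth
#'
#' Generates `n_studies` gene-by-sample matrices with two phenotype groups
#' each. Consensus genes receive a per-study log2 effect drawn around
#' `effect_mean` with a fixed common sign; discordant genes are DE in exactly
#' one study; all remaining genes are null. Study-level additive offsets and
#' optional per-study gene dropout emulate platform differences. Per-study
#' draws are seeded hierarchically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `studies` (list of [expression_study()]) and `truth`,
#'   a list with `class` (named character: `consensus_up`, `consensus_down`,
#'   `discordant`, `null`), `effects` (genes x studies matrix of true log2
#'   effects), `included` (genes x studies logical inclusion mask) and
#'   `config`.
#' @export
simulate_bulk_studies <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("g%05d", seq_len(ng))
  perm <- sample.int(ng)
  up_idx <- perm[seq_len(config$n_consensus_up)]
  down_idx <- perm[config$n_consensus_up + seq_len(config$n_consensus_down)]
  disc_idx <- perm[config$n_consensus_up + config$n_consensus_down +
                     seq_len(config$n_discordant)]
  cls <- rep("null", ng)
  cls[up_idx] <- "consensus_up"
  cls[down_idx] <- "consensus_down"
  cls[disc_idx] <- "discordant"
  baseline <- rnorm(ng, mean = 7, sd = 1.5)
  disc_study <- if (length(disc_idx))
    sample.int(config$n_studies, length(disc_idx), replace = TRUE) else integer()
  disc_sign <- if (length(disc_idx))
    sample(c(-1, 1), length(disc_idx), replace = TRUE) else numeric()

  study_ids <- sprintf("study%d", seq_len(config$n_studies))
  effects <- matrix(0, ng, config$n_studies, dimnames = list(genes, study_ids))
  included <- matrix(TRUE, ng, config$n_studies, dimnames = list(genes, study_ids))
  studies <- vector("list", config$n_studies)
  npg <- config$n_per_group

  for (s in seq_len(config$n_studies)) {
    set.seed(study_seed(config$seed, s))
    eff <- numeric(ng)
    if (length(up_idx))
      eff[up_idx] <- rnorm(length(up_idx), config$effect_mean, config$effect_sd)
    if (length(down_idx))
      eff[down_idx] <- -rnorm(length(down_idx), config$effect_mean, config$effect_sd)
    here <- which(disc_study == s)
    if (length(here))
      eff[disc_idx[here]] <- disc_sign[here] *
        rnorm(length(here), config$effect_mean, config$effect_sd)
    effects[, s] <- eff

    sigma2 <- if (is.finite(config$d0_sim))
      config$s0_sim * config$d0_sim / rchisq(ng, df = config$d0_sim)
    else rep(config$noise_sd^2, ng)
    offset <- rnorm(ng, 0, config$study_offset_sd)

    n_tot <- 2L * npg
    eps <- matrix(rnorm(ng * n_tot, mean = 0, sd = sqrt(sigma2)), ng, n_tot)
    vals <- baseline + offset + eps
    vals[, npg + seq_len(npg)] <- vals[, npg + seq_len(npg)] + eff
    sample_ids <- c(sprintf("%s_%s_%d", study_ids[s], config$control_label, seq_len(npg)),
                    sprintf("%s_%s_%d", study_ids[s], config$case_label, seq_len(npg)))
    dimnames(vals) <- list(genes, sample_ids)
    pheno <- setNames(rep(c(config$control_label, config$case_label), each = npg),
                      sample_ids)
    if (config$platform_dropout > 0) {
      n_drop <- floor(config$platform_dropout * ng)
      drop <- sample.int(ng, n_drop)
      included[drop, s] <- FALSE
      vals <- vals[-drop, , drop = FALSE]
    }
    if (config$expression_scale == "intensity") vals <- 2^vals
    studies[[s]] <- expression_study(vals, pheno, study_ids[s])
  }
  # genes whose true effect is zero in every study are null by construction
  cls[rowSums(abs(effects)) == 0] <- "null"
  truth <- list(class = setNames(cls, genes), effects = effects,
                included = included, config = config)
  list(studies = studies, truth = truth)
}

#' Simulate single-cell counts with a signature spiked into one cluster
#'
#' Negative-binomial counts for `n_genes` genes by `n_cells` cells, with
#' cells partitioned into clusters according to `cluster_props`. The mean
#' expression of `signature_genes` is multiplied by `2^spike_lfc` in cluster
#' 1 only. Gene names follow the `g0001` convention of the bulk generator
#' truncated to four digits (use the returned `genes` to pick signatures).
#'
#' @param n_cells,n_genes positive integers.
#' @param cluster_props numeric vector of cluster proportions summing to 1.
#' @param signature_genes character vector of gene names (subset of the
#'   `sprintf("g%04d", 1:n_genes)` universe); must be non-empty.
#' @param spike_lfc log2 fold elevation of signature genes in cluster 1.
#' @param seed integer seed.
#' @param dispersion negative-binomial size parameter (default 2).
#' @return list with `counts` (genes x cells integer matrix), `clusters`
#'   (named character, `cluster1` ... ), `genes`, and `truth` (signature
#'   genes and spike_lfc).
#' @export
simulate_single_cell <- function(n_cells, n_genes, cluster_props,
                                 signature_genes, spike_lfc, seed,
                                 dispersion = 2) {
  stopifnot(n_cells >= 1, n_genes >= 1)
  if (abs(sum(cluster_props) - 1) > 1e-9)
    stop("`cluster_props` must sum to 1", call. = FALSE)
  if (any(cluster_props < 0))
    stop("`cluster_props` must be non-negative", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(n_genes))
  if (length(signature_genes) == 0)
    stop("`signature_genes` must be non-empty", call. = FALSE)
  bad <- setdiff(signature_genes, genes)
  if (length(bad))
    stop("signature genes outside the gene universe: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  k <- length(cluster_props)
  sizes <- diff(round(cumsum(c(0, cluster_props)) * n_cells))
  labels <- rep(sprintf("cluster%d", seq_len(k)), times = sizes)
  cells <- sprintf("cell%05d", seq_len(n_cells))
  # baseline per-gene mean counts, gamma-distributed as in typical droplet data
  mu <- rgamma(n_genes, shape = 0.6, rate = 1.2) + 0.05
  names(mu) <- genes
  mu_mat <- matrix(mu, n_genes, n_cells)
  in_c1 <- labels == "cluster1"
  sig_idx <- match(signature_genes, genes)
  mu_mat[sig_idx, in_c1] <- mu_mat[sig_idx, in_c1] * 2^spike_lfc
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu_mat, size = dispersion),
                   n_genes, n_cells, dimnames = list(genes, cells))
  list(counts = counts, clusters = setNames(labels, cells), genes = genes,
       truth = list(signature_genes = signature_genes, spike_lfc = spike_lfc))
}
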