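#' Directional concordance of a signature in an independent study
#'
#' For every signature gene present in the validation differential-expression
#' table, the validation z-score's sign is compared with the signature's
#' expected direction. The summary concordance (agreeing / present) is
#' referred to a permutation null: the concordance of `n_perm` random gene
#' sets of the same size and direction split drawn from the validation
#' universe.
#'
#' The concordance fraction with a permutation null is this package's
#' quantitative summary of the directional-heatmap validation commonly shown
#' in the field.
#'
#' @param signature a [gene_signature()].
#' @param validation_de a `de_result` table from [run_de()] on the held-out
#'   study (or any data.frame with `gene`, `t_mod`, `df_total`).
#' @param n_perm number of permutation draws.
#' @param seed integer seed.
#' @param min_overlap minimum fraction of signature genes that must be
#'   present in the validation table (default 0.5).
#' @return list of class `concordance_report`: `per_gene` data.frame
#'   (`gene`, `expected`, `z`, `agree`), `concordance`, `mean_directional_z`
#'   (mean of z times expected sign), `perm_p`, `n_present`, `n_missing`,
#'   `missing`.
#' @export
directional_concordance <- function(signature, validation_de, n_perm = 1000,
                                    seed = 1, min_overlap = 0.5) {
  stopifnot(inherits(signature, "gene_signature"))
  sig_genes <- c(signature$up, signature$down)
  if (!length(sig_genes)) stop("empty signature", call. = FALSE)
  expected <- setNames(rep(c(1, -1), c(length(signature$up), length(signature$down))),
                       sig_genes)
  z_all <- setNames(t_to_z(validation_de$t_mod, validation_de$df_total),
                    validation_de$gene)
  present <- intersect(sig_genes, names(z_all))
  missing <- setdiff(sig_genes, names(z_all))
  if (length(present) < min_overlap * length(sig_genes))
    stop("fewer than ", round(100 * min_overlap),
         "% of signature genes present in the validation table; missing: ",
         paste(head(missing, 20), collapse = ", "), call. = FALSE)
  e <- expected[present]
  zv <- z_all[present]
  agree <- zv * e > 0
  concordance <- mean(agree)
  set.seed(as.integer(seed))
  universe <- names(z_all)
  n <- length(present)
  perm <- vapply(seq_len(n_perm), function(b) {
    g <- sample(universe, n)
    mean(z_all[g] * e > 0)   # same direction split, random genes
  }, numeric(1))
  perm_p <- (1 + sum(perm >= concordance)) / (1 + n_perm)
  structure(list(
    per_gene = data.frame(gene = present, expected = unname(e),
                          z = unname(zv), agree = unname(agree),
                          stringsAsFactors = FALSE),
    concordance = concordance,
    mean_directional_z = mean(zv * e),
    perm_p = perm_p,
    n_present = n, n_missing = length(missing), missing = missing),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> %d/%d genes present; concordance %.3f (perm p %.4g)\n",
              x$n_present, x$n_present + x$n_missing, x$concordance, x$perm_p))
  invisible(x)
}

# counts-per-10k then log1p, the standard single-cell normalization used
# before module scoring.
lognormalize_counts <- function(counts, scale_factor = 1e4) {
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  log1p(sweep(counts, 2, cs, "/") * scale_factor)
}

looks_like_counts <- function(x) {
  mx <- max(x)
  mx > 20 && all(x >= 0) && all(x == round(x))
}

#' Per-cell module score of a gene set
#'
#' The mean log-normalized expression of the signature genes minus the mean
#' of expression-bin-matched control genes: genes are split into `n_bins`
#' equal-frequency bins of average expression and, for each signature gene,
#' `n_ctrl` control genes are drawn (with replacement, seeded) from its bin.
#' Raw count input is detected (non-negative integers with maximum > 20) and
#' log-normalized to counts-per-10k log1p first.
#'
#' @param expr genes x cells matrix (log-normalized, or raw counts).
#' @param genes signature gene list; genes absent from `expr` are dropped
#'   with a warning (an error if all are absent).
#' @param n_bins number of average-expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed integer seed for the control draws.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, genes, n_bins = 25, n_ctrl = 100, seed = 1) {
  stopifnot(is.matrix(expr) || inherits(expr, "Matrix"))
  expr <- as.matrix(expr)
  if (looks_like_counts(expr)) expr <- lognormalize_counts(expr)
  present <- intersect(genes, rownames(expr))
  if (!length(present)) stop("no signature genes present in the dataset",
                             call. = FALSE)
  if (length(present) < length(genes))
    warning(sprintf("%d signature gene(s) absent from the dataset; dropped",
                    length(genes) - length(present)))
  avg <- rowMeans(expr)
  ng <- nrow(expr)
  nb <- min(n_bins, ng)
  bin <- pmin(nb, pmax(1L, ceiling(nb * rank(avg, ties.method = "first") / ng)))
  names(bin) <- rownames(expr)
  by_bin <- split(rownames(expr), bin)
  set.seed(as.integer(seed))
  ctrl <- unlist(lapply(present, function(g) {
    pool <- by_bin[[as.character(bin[g])]]
    pool[sample.int(length(pool), n_ctrl, replace = TRUE)]
  }), use.names = FALSE)
  sig_mean <- colMeans(expr[present, , drop = FALSE])
  ctrl_mean <- colMeans(expr[ctrl, , drop = FALSE])
  sig_mean - ctrl_mean
}

#' Per-cluster summary of module scores
#'
#' @param scores named per-cell score vector from [module_score()].
#' @param clusters named cluster labels (cell -> label).
#' @return data.frame with `cluster`, `n`, `mean_score`.
#' @export
summarize_scores <- function(scores, clusters) {
  clusters <- clusters[names(scores)]
  agg <- tapply(scores, clusters, mean)
  data.frame(cluster = names(agg), n = as.integer(table(clusters)[names(agg)]),
             mean_score = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise group comparisons of per-cell scores
#'
#' All pairwise comparisons between groups using the Wilcoxon rank-sum test
#' or Welch's two-sample t-test, with BH adjustment across pairs. Groups
#' with fewer than 3 cells are excluded with a warning.
#'
#' @param scores named per-cell score vector.
#' @param groups named group labels (cell -> label).
#' @param test `"wilcoxon"` or `"t_test"`.
#' @return data.frame with `group1`, `group2`, `n1`, `n2`, `statistic`, `p`,
#'   `p_adj`.
#' @export
compare_scores <- function(scores, groups, test = c("wilcoxon", "t_test")) {
  test <- match.arg(test)
  groups <- groups[names(scores)]
  tab <- table(groups)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("group(s) with fewer than 3 cells excluded: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    scores <- scores[keep]; groups <- groups[keep]
    tab <- table(groups)
  }
  gs <- names(tab)
  if (length(gs) < 2) stop("need at least 2 groups with >= 3 cells", call. = FALSE)
  pairs <- combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- scores[groups == pairs[1, i]]
    b <- scores[groups == pairs[2, i]]
    if (test == "wilcoxon") {
      if (all(c(a, b) == c(a, b)[1])) {
        stat <- length(a) * length(b) / 2; p <- 1
      } else {
        ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
        stat <- unname(ht$statistic); p <- ht$p.value
      }
    } else {
      if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
        stat <- 0; p <- 1
      } else {
        ht <- t.test(a, b)
        stat <- unname(ht$statistic); p <- ht$p.value
      }
    }
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               n1 = length(a), n2 = length(b),
               statistic = stat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}
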