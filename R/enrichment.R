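# Exact two-sample rank-sum p-value under the permutation null, supporting
# ties via midranks. Uses dynamic programming over the doubled (integer)
# midranks: ways[k, s] = number of size-k subsets with rank sum s.
ranksum_exact_p <- function(scores, is_member,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  r2 <- as.integer(round(2 * rank(scores)))
  n <- sum(is_member)
  N <- length(scores)
  stopifnot(n >= 1, n < N)
  W2 <- sum(r2[is_member])
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(n)])
  ways <- matrix(0, n + 1, maxs + 1)
  ways[1, 1] <- 1
  for (r in r2) {
    kmax <- n
    for (k in kmax:1) {
      src <- ways[k, 1:(maxs + 1 - r)]
      ways[k + 1, (r + 1):(maxs + 1)] <- ways[k + 1, (r + 1):(maxs + 1)] + src
    }
  }
  dist <- ways[n + 1, ] / choose(N, n)
  pge <- sum(dist[(W2 + 1):(maxs + 1)])
  ple <- sum(dist[1:(W2 + 1)])
  switch(alternative,
         greater = min(1, pge),
         less = min(1, ple),
         two.sided = min(1, 2 * min(pge, ple)))
}

#' Wilcoxon rank-sum pathway enrichment on combined p-values
#'
#' Tests, for each pathway, whether its member genes carry more significant
#' combined p-values than non-members: a rank-sum test of member vs
#' non-member scores (`-log10 p_combined`, higher = more significant). When
#' both groups have at most 12 genes the exact permutation distribution is
#' used (midranks handle ties); otherwise the normal approximation with tie
#' and continuity correction. P-values are BH-adjusted across tested
#' pathways.
#'
#' @param scores named numeric vector, gene -> `-log10(p_combined)`.
#' @param pathways named list of gene sets (intersected with the score
#'   universe before testing).
#' @param min_size,max_size pathway size bounds (after intersection);
#'   pathways outside are skipped and recorded in the `"skipped"` attribute.
#' @param alternative `"greater"` (members more significant; default) or
#'   `"two.sided"`.
#' @param sig_threshold combined-p cutoff defining the DE fraction reported
#'   as `gene_ratio`.
#' @return data.frame with `pathway`, `n_in_universe`, `statistic` (rank-sum
#'   U of the members), `p`, `p_adj`, `gene_ratio`.
#' @export
wilcoxon_pathway_test <- function(scores, pathways, min_size = 10,
                                  max_size = 500,
                                  alternative = c("greater", "two.sided"),
                                  sig_threshold = 0.05) {
  alternative <- match.arg(alternative)
  stopifnot(!is.null(names(scores)), !anyDuplicated(names(scores)))
  universe <- names(scores)
  res <- list(); skipped <- character()
  for (nm in names(pathways)) {
    members <- intersect(pathways[[nm]], universe)
    n_in <- length(members)
    if (n_in < min_size || n_in > max_size) {
      skipped[nm] <- sprintf("size %d outside [%d, %d]", n_in, min_size, max_size)
      next
    }
    is_mem <- universe %in% members
    x <- scores[is_mem]; y <- scores[!is_mem]
    r <- rank(scores)
    U <- sum(r[is_mem]) - n_in * (n_in + 1) / 2
    if (n_in <= 12 && length(y) <= 12) {
      p <- ranksum_exact_p(scores, is_mem, alternative)
    } else if (all(scores == scores[1])) {
      p <- 1
    } else {
      wt <- suppressWarnings(
        wilcox.test(x, y, alternative = alternative,
                    exact = FALSE, correct = TRUE))
      p <- wt$p.value
    }
    res[[nm]] <- data.frame(pathway = nm, n_in_universe = n_in,
                            statistic = U, p = p,
                            gene_ratio = mean(scores[is_mem] > -log10(sig_threshold)),
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pathway = character(), n_in_universe = integer(),
               statistic = numeric(), p = numeric(), gene_ratio = numeric())
  rownames(out) <- NULL
  out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric()
  out <- out[, c("pathway", "n_in_universe", "statistic", "p", "p_adj", "gene_ratio")]
  attr(out, "skipped") <- skipped
  out
}

# Enrichment score of one gene set on an already-sorted score vector.
# `hit` is a logical vector along the sorted list. Returns the signed
# extremum of the weighted Kolmogorov-Smirnov-style running sum.
gsea_es <- function(abs_w, hit) {
  N <- length(hit)
  n <- sum(hit)
  step <- numeric(N)
  denom <- sum(abs_w[hit])
  if (denom == 0) stop("all hit scores are zero: undefined hit increments",
                       call. = FALSE)
  step[hit] <- abs_w[hit] / denom
  step[!hit] <- -1 / (N - n)
  cs <- cumsum(step)
  cs[which.max(abs(cs))]
}

#' Preranked gene-set enrichment
#'
#' Weighted Kolmogorov-Smirnov-style enrichment score on a ranked gene list:
#' hits increment the running sum by `|score|^weight / sum(|score|^weight)`
#' over the set, misses decrement by `1/(N - n)`; ES is the signed extremum.
#' The null distribution is obtained by permuting gene labels (equivalently,
#' resampling hit positions) `n_perm` times under `seed`; `p` is the
#' smoothed fraction of same-sign permutation scores at least as extreme,
#' and `NES = ES / mean(|same-sign permutation ES|)`.
#'
#' @param scores named numeric vector of ranking scores (signed; no
#'   duplicate names); sorted decreasingly internally.
#' @param set character vector of gene names; at least 3 must be present in
#'   `scores`.
#' @param weight exponent on `|score|` for hit increments (default 1;
#'   0 gives the unweighted KS statistic).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return list with `es`, `nes`, `p`, `n_hits`, `degenerate` (TRUE when the
#'   set covers the whole list, in which case `es = 1` by convention and no
#'   permutation test is performed).
#' @export
gsea_preranked <- function(scores, set, weight = 1, n_perm = 1000, seed = 1) {
  stopifnot(!is.null(names(scores)))
  if (anyDuplicated(names(scores)))
    stop("duplicate gene names in `scores`", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  hit <- names(s) %in% set
  n <- sum(hit)
  N <- length(s)
  if (n < 3)
    stop("fewer than 3 set genes present in the ranked list", call. = FALSE)
  if (n == N)
    return(list(es = 1, nes = NA_real_, p = NA_real_, n_hits = n,
                degenerate = TRUE))
  if (weight > 0 && all(s == 0))
    stop("all scores are zero with weight > 0: undefined hit increments",
         call. = FALSE)
  abs_w <- abs(s)^weight
  es <- gsea_es(abs_w, hit)
  set.seed(as.integer(seed))
  perm_es <- vapply(seq_len(n_perm), function(b) {
    h <- logical(N)
    h[sample.int(N, n)] <- TRUE
    gsea_es(abs_w, h)
  }, numeric(1))
  same <- sign(perm_es) == sign(es)
  n_same <- sum(same)
  p <- (1 + sum(same & abs(perm_es) >= abs(es))) / (1 + n_same)
  nes <- if (n_same > 0) es / mean(abs(perm_es[same])) else NA_real_
  list(es = es, nes = nes, p = p, n_hits = n, degenerate = FALSE)
}

#' Preranked GSEA over a pathway collection
#'
#' Runs [gsea_preranked()] for every pathway within size bounds and
#' BH-adjusts the permutation p-values.
#'
#' @inheritParams wilcoxon_pathway_test
#' @inheritParams gsea_preranked
#' @return data.frame with `pathway`, `n_in_universe`, `es`, `nes`, `p`,
#'   `p_adj`.
#' @export
gsea_collection <- function(scores, pathways, min_size = 10, max_size = 500,
                            weight = 1, n_perm = 1000, seed = 1) {
  res <- list(); skipped <- character()
  for (i in seq_along(pathways)) {
    nm <- names(pathways)[i]
    members <- intersect(pathways[[i]], names(scores))
    if (length(members) < max(3, min_size) || length(members) > max_size) {
      skipped[nm] <- "size outside bounds"
      next
    }
    g <- gsea_preranked(scores, members, weight = weight, n_perm = n_perm,
                        seed = study_seed(seed, i))
    res[[nm]] <- data.frame(pathway = nm, n_in_universe = g$n_hits,
                            es = g$es, nes = g$nes, p = g$p,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(pathway = character(), n_in_universe = integer(),
               es = numeric(), nes = numeric(), p = numeric())
  rownames(out) <- NULL
  out$p_adj <- if (nrow(out)) bh_adjust(out$p) else numeric()
  attr(out, "skipped") <- skipped
  out
}
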