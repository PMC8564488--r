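#' Convert moderated t-statistics to directional z-scores
#'
#' Maps each statistic to the standard-normal quantile carrying the same
#' two-sided tail probability, keeping the sign:
#' `z = sign(t) * qnorm(1 - p_two/2)` where `p_two` is the two-sided
#' Student-t tail at `|t|`. Computed in log-tail space so very large
#' statistics convert without underflow.
#'
#' @param t_mod numeric vector of moderated t-statistics (finite).
#' @param df_total degrees of freedom (scalar or vector; `Inf` for normal).
#' @return numeric vector of z-scores.
#' @export
t_to_z <- function(t_mod, df_total) {
  if (any(!is.finite(t_mod)))
    stop("non-finite moderated t-statistic", call. = FALSE)
  if (any(df_total <= 0)) stop("df_total must be positive", call. = FALSE)
  lp <- pt(abs(t_mod), df = df_total, lower.tail = FALSE, log.p = TRUE)
  sign(t_mod) * qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

#' Combine per-study directional z-scores across studies
#'
#' Pearson's method for signed effects: per gene, one-sided p-values are
#' combined separately in the upward direction (`p_i = pnorm(-z_i)`) and the
#' downward direction via `-2 * sum(log p_i) ~ chisq(2k)`; the overall
#' significance score is `min(1, 2 * min(p_up, p_down))`. The classical
#' single-product Fisher combination (on two-sided p-values) and Stouffer's
#' z-sum are available behind `method`.
#'
#' @param z genes x studies numeric matrix of directional z-scores, `NA`
#'   where a gene is absent from a study.
#' @param min_studies minimum number of studies a gene must appear in;
#'   genes below it are excluded (recorded in the `"excluded"` attribute).
#' @param method combination rule.
#' @return a `combined_gene_table` data.frame: `gene`, `n_studies`, `p_up`,
#'   `p_down`, `p_combined`, `direction`, `sum_z`, plus one `z_<study>`
#'   column per study. Combined p-values are floored at 1e-300.
#' @export
pearson_combine <- function(z, min_studies = ncol(z),
                            method = c("pearson", "fisher", "stouffer")) {
  method <- match.arg(method)
  stopifnot(is.matrix(z), !is.null(rownames(z)))
  k <- rowSums(!is.na(z))
  keep <- k >= min_studies
  excluded <- rownames(z)[!keep]
  zk <- z[keep, , drop = FALSE]
  kk <- k[keep]
  sum_z <- rowSums(zk, na.rm = TRUE)
  if (method == "pearson") {
    lup <- pnorm(zk, lower.tail = FALSE, log.p = TRUE)   # log P(Z > z): up-tail
    ldn <- pnorm(zk, lower.tail = TRUE, log.p = TRUE)
    x_up <- -2 * rowSums(lup, na.rm = TRUE)
    x_dn <- -2 * rowSums(ldn, na.rm = TRUE)
    p_up <- pchisq(x_up, df = 2 * kk, lower.tail = FALSE)
    p_down <- pchisq(x_dn, df = 2 * kk, lower.tail = FALSE)
    p_comb <- pmin(1, 2 * pmin(p_up, p_down))
  } else if (method == "fisher") {
    # classical Fisher on two-sided p's; direction from the z sum
    l2 <- pnorm(abs(zk), lower.tail = FALSE, log.p = TRUE) + log(2)
    x <- -2 * rowSums(l2, na.rm = TRUE)
    p_comb <- pchisq(x, df = 2 * kk, lower.tail = FALSE)
    p_up <- ifelse(sum_z >= 0, p_comb / 2, 1 - p_comb / 2)
    p_down <- ifelse(sum_z >= 0, 1 - p_comb / 2, p_comb / 2)
  } else {
    zc <- sum_z / sqrt(kk)
    p_up <- pnorm(zc, lower.tail = FALSE)
    p_down <- pnorm(zc, lower.tail = TRUE)
    p_comb <- pmin(1, 2 * pmin(p_up, p_down))
  }
  p_comb <- pmax(p_comb, 1e-300)
  direction <- ifelse(p_up < p_down, "up",
                      ifelse(p_down < p_up, "down",
                             ifelse(sum_z < 0, "down", "up")))
  out <- data.frame(gene = rownames(zk), n_studies = kk,
                    p_up = p_up, p_down = p_down, p_combined = p_comb,
                    direction = direction, sum_z = sum_z,
                    row.names = NULL, stringsAsFactors = FALSE)
  zdf <- as.data.frame(zk, row.names = NULL)
  names(zdf) <- paste0("z_", colnames(zk))
  out <- cbind(out, zdf)
  attr(out, "excluded") <- excluded
  attr(out, "method") <- method
  class(out) <- c("combined_gene_table", "data.frame")
  out
}

#' Build the combined gene table from per-study DE results
#'
#' Converts each study's moderated t-statistics to z-scores with [t_to_z()]
#' and combines them with [pearson_combine()].
#'
#' @param de_list list of `de_result` tables from [run_de()]; names (or the
#'   `study_id` attributes) become study IDs.
#' @param min_studies minimum studies per gene (default: all studies).
#' @param method combination rule, see [pearson_combine()].
#' @return a `combined_gene_table`.
#' @export
combine_studies <- function(de_list, min_studies = length(de_list),
                            method = c("pearson", "fisher", "stouffer")) {
  method <- match.arg(method)
  stopifnot(length(de_list) >= 1)
  ids <- names(de_list)
  if (is.null(ids))
    ids <- vapply(de_list, function(d) attr(d, "study_id") %||% "", "")
  ids[ids == ""] <- sprintf("study%d", which(ids == ""))
  genes <- sort(unique(unlist(lapply(de_list, `[[`, "gene"))))
  z <- matrix(NA_real_, length(genes), length(de_list),
              dimnames = list(genes, ids))
  for (i in seq_along(de_list)) {
    d <- de_list[[i]]
    z[match(d$gene, genes), i] <- t_to_z(d$t_mod, d$df_total)
  }
  pearson_combine(z, min_studies = min_studies, method = method)
}

#' Derive a gene signature from a combined gene table
#'
#' Genes with `p_combined < threshold` are partitioned by direction; each
#' list is sorted by ascending combined p (ties broken by gene name for
#' determinism).
#'
#' @param table a `combined_gene_table`.
#' @param threshold combined p-value cutoff (default 1e-5, the overall
#'   significance score used to call consensus genes).
#' @param name signature name.
#' @param source_studies study IDs recorded in the signature (default: the
#'   z-score columns of `table`).
#' @return a [gene_signature()]; may be empty (a message is emitted).
#' @export
derive_signature <- function(table, threshold = 1e-5, name = "signature",
                             source_studies = NULL) {
  stopifnot(nrow(table) > 0)
  if (is.null(source_studies))
    source_studies <- sub("^z_", "", grep("^z_", names(table), value = TRUE))
  hit <- table$p_combined < threshold
  sel <- table[hit, , drop = FALSE]
  sel <- sel[order(sel$p_combined, sel$gene), , drop = FALSE]
  sig <- gene_signature(name,
                        up = sel$gene[sel$direction == "up"],
                        down = sel$gene[sel$direction == "down"],
                        threshold = threshold,
                        source_studies = source_studies)
  if (!length(sig$up) && !length(sig$down))
    message(sprintf("signature '%s' is empty at threshold %g", name, threshold))
  sig
}

#' Export the z-score matrix of the top combined genes
#'
#' Rows are the `top_n` genes by ascending combined p-value, columns the
#' per-study z-scores (NA where a gene was absent) — the matrix behind the
#' standard consensus heatmap.
#'
#' @param table a `combined_gene_table`.
#' @param top_n number of genes (must not exceed `nrow(table)`).
#' @return numeric matrix, genes x studies.
#' @export
export_zscore_heatmap_matrix <- function(table, top_n) {
  stopifnot(top_n >= 1, top_n <= nrow(table))
  o <- order(table$p_combined, table$gene)
  sel <- table[o[seq_len(top_n)], , drop = FALSE]
  zc <- grep("^z_", names(table), value = TRUE)
  m <- as.matrix(sel[, zc, drop = FALSE])
  dimnames(m) <- list(sel$gene, sub("^z_", "", zc))
  m
}
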