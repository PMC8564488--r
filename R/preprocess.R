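#' Remove genes with nil expression
#'
#' Drops genes whose values equal the study's floor value in every sample
#' (0 on the count scale; the minimum constant row on the log scale). Gene
#' order is otherwise preserved.
#'
#' @param study an [expression_study()].
#' @return the filtered study.
#' @export
filter_unexpressed <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$values
  if (!length(x)) stop("empty expression matrix", call. = FALSE)
  floor_val <- min(x)
  nil <- rowSums(x != floor_val) == 0
  if (all(nil))
    stop("all genes are at the floor value; empty study after filtering",
         call. = FALSE)
  study$values <- x[!nil, , drop = FALSE]
  study
}

# Core quantile normalization on a matrix: every column's empirical
# distribution is forced to the row-means of the column-sorted matrix; tied
# values within a column receive the mean of the reference quantiles spanned
# by their rank range (the "ties = average" dialect).
quantile_normalize_matrix <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    grp <- cumsum(!duplicated(x[o, j]))
    vals <- stats::ave(ref, grp, FUN = mean)
    out[o, j] <- vals
  }
  out
}

#' Quantile-normalize an expression study
#'
#' After normalization every sample shares the same empirical distribution:
#' the vector of row-means of the column-sorted matrix.
#'
#' @param study an [expression_study()] with at least two samples.
#' @return the normalized study (`normalized_by = "quantile"`).
#' @export
quantile_normalize <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (ncol(study$values) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  study$values <- quantile_normalize_matrix(study$values)
  study$normalized_by <- "quantile"
  study
}

#' TMM scaling factors
#'
#' Per-sample scaling factors from a doubly trimmed, precision-weighted mean
#' of per-gene log2 ratios against a reference sample, rescaled so the
#' factors' geometric mean is 1. Unlike composition-only normalization
#' factors, the returned factors absorb library size: a sample with every
#' count doubled gets (before rescaling) a factor twice as large.
#'
#' The reference sample is the one whose 75th-percentile count fraction is
#' closest to the mean of that quantity across samples. Log-ratios are
#' trimmed 30% on each side by M (log-ratio) and 5% on each side by A
#' (average log abundance); weights are inverse delta-method variances of M
#' computed on count fractions, so the factors are exactly scale-equivariant.
#'
#' @param study an [expression_study()] on the count scale (non-negative).
#' @param trim_m,trim_a two-sided trim fractions for M and A.
#' @return named numeric vector of per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(study, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$values
  if (any(x < 0)) stop("TMM requires non-negative counts", call. = FALSE)
  libsize <- colSums(x)
  zero_samp <- colnames(x)[libsize == 0]
  if (length(zero_samp))
    stop("sample(s) with all-zero counts: ",
         paste(zero_samp, collapse = ", "), call. = FALSE)
  q75_frac <- apply(x, 2, function(col) quantile(col, 0.75) / sum(col))
  ref <- which.min(abs(q75_frac - mean(q75_frac)))
  xr <- x[, ref]
  pr <- xr / libsize[ref]
  f <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    if (j == ref) { f[j] <- 1; next }
    xs <- x[, j]
    ok <- xs > 0 & xr > 0
    M <- log2(xs[ok] / xr[ok])
    A <- 0.5 * (log2(xs[ok]) + log2(xr[ok]))
    ps <- xs[ok] / libsize[j]
    w <- 1 / (1 / ps + 1 / pr[ok])
    n <- length(M)
    if (n == 0) stop("no genes shared with the reference sample", call. = FALSE)
    loM <- floor(n * trim_m) + 1; hiM <- n - floor(n * trim_m)
    loA <- floor(n * trim_a) + 1; hiA <- n - floor(n * trim_a)
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    f[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(x))
}

#' Apply TMM scaling and move to the log2 scale
#'
#' Divides each sample's counts by its TMM factor and log2(x+1)-transforms.
#'
#' @inheritParams tmm_factors
#' @return an [expression_study()] with `normalized_by = "tmm"`.
#' @export
tmm_normalize <- function(study) {
  f <- tmm_factors(study)
  study$values <- log2(sweep(study$values, 2, f, "/") + 1)
  study$normalized_by <- "tmm"
  study
}

#' Log2-transform a matrix that looks like raw intensities or counts
#'
#' If the matrix maximum exceeds `threshold`, values are replaced by
#' `log2(x + 1)` (and a message is emitted); otherwise the study is returned
#' unchanged. Array log-intensities and log-counts rarely exceed ~20 while
#' raw counts and intensities almost always do, hence the default of 50.
#'
#' @param study an [expression_study()].
#' @param threshold scale-detection cutoff.
#' @return the (possibly transformed) study.
#' @export
log_transform_if_needed <- function(study, threshold = 50) {
  stopifnot(inherits(study, "expression_study"))
  mx <- max(study$values)
  if (mx <= threshold) return(study)
  if (any(study$values < 0))
    stop("negative values with maximum > threshold: ambiguous scale",
         call. = FALSE)
  study$values <- log2(study$values + 1)
  message(sprintf("study %s: values log2(x+1)-transformed (max was %.3g)",
                  study$study_id, mx))
  study
}

#' Principal-component QC of samples
#'
#' Centers each gene across samples and decomposes; returns per-sample
#' scores on the leading components and the variance-explained fractions.
#'
#' @param study an [expression_study()].
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components) and `var_explained`.
#' @export
pca_qc <- function(study, n_components = 2) {
  stopifnot(inherits(study, "expression_study"))
  x <- t(study$values)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (all(pc$sdev < .Machine$double.eps^0.5))
    stop("constant expression matrix: no variance to decompose", call. = FALSE)
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Sample correlation matrix and average-linkage dendrogram
#'
#' Pearson correlation between samples and hierarchical clustering on the
#' 1 - correlation distance (average linkage), the standard QC view of
#' whether samples group by phenotype.
#'
#' @param study an [expression_study()] with at least 3 samples.
#' @return list with `correlation` (symmetric, unit diagonal) and `hclust`.
#' @export
sample_correlation_clustering <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  x <- study$values
  if (ncol(x) < 3) stop("need at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  C <- cor(x)
  diag(C) <- 1
  hc <- hclust(as.dist(1 - C), method = "average")
  list(correlation = C, hclust = hc)
}
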