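#' Construct an expression study
#'
#' Container for one study's gene-by-sample expression matrix together with
#' the phenotype of every sample. Values are expected on the log2 scale after
#' preprocessing; raw count matrices are accepted and can be converted with
#' [log_transform_if_needed()] or scaled with [tmm_factors()].
#'
#' Duplicate gene symbols (e.g. several probes mapped to one gene) are
#' collapsed to the row with the highest mean expression before the object is
#' built; the number of collapsed rows is reported via a message.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param phenotype character vector of phenotype labels, either named by
#'   sample ID or in column order of `values`.
#' @param study_id single string identifying the study.
#' @param normalized_by one of `"none"`, `"quantile"`, `"tmm"`.
#' @return An object of class `expression_study`: a list with elements
#'   `study_id`, `values`, `phenotype` (named by sample) and `normalized_by`.
#' @export
expression_study <- function(values, phenotype, study_id,
                             normalized_by = c("none", "quantile", "tmm")) {
  normalized_by <- match.arg(normalized_by)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)))
    stop("`values` must have gene symbols as rownames", call. = FALSE)
  if (is.null(colnames(values)))
    stop("`values` must have sample IDs as colnames", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs in `values`", call. = FALSE)
  values <- collapse_duplicate_genes(values)
  if (is.null(names(phenotype))) {
    if (length(phenotype) != ncol(values))
      stop("`phenotype` length does not match number of samples", call. = FALSE)
    names(phenotype) <- colnames(values)
  }
  missing_pheno <- setdiff(colnames(values), names(phenotype))
  if (length(missing_pheno))
    stop("phenotype missing for sample(s): ",
         paste(missing_pheno, collapse = ", "), call. = FALSE)
  phenotype <- phenotype[colnames(values)]
  structure(
    list(study_id = as.character(study_id)[1],
         values = values,
         phenotype = setNames(as.character(phenotype), names(phenotype)),
         normalized_by = normalized_by),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s: %d genes x %d samples (%s)\n",
              x$study_id, nrow(x$values), ncol(x$values), x$normalized_by))
  tab <- table(x$phenotype)
  cat("  phenotypes:",
      paste(sprintf("%s x %s", tab, names(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$values)

#' Collapse duplicate gene symbols
#'
#' Keeps, for each gene symbol, the row with the highest mean expression.
#' Row order of the retained rows is preserved.
#'
#' @param values numeric matrix with (possibly duplicated) rownames.
#' @return matrix with unique rownames.
#' @export
collapse_duplicate_genes <- function(values) {
  g <- rownames(values)
  if (!anyDuplicated(g)) return(values)
  m <- rowMeans(values)
  keep <- logical(nrow(values))
  for (idx in split(seq_len(nrow(values)), g)) {
    keep[idx[which.max(m[idx])]] <- TRUE
  }
  n_drop <- sum(!keep)
  message(sprintf("collapsed %d duplicate gene row(s), keeping highest-mean row", n_drop))
  values[keep, , drop = FALSE]
}

#' Define a two-group contrast
#'
#' @param case_label phenotype label of the case group (e.g. `"tolDC"`).
#' @param control_label phenotype label of the control group (e.g. `"imDC"`).
#' @return object of class `contrast`.
#' @export
contrast <- function(case_label, control_label) {
  stopifnot(is.character(case_label), is.character(control_label))
  if (case_label == control_label)
    stop("case and control labels must differ", call. = FALSE)
  structure(list(case_label = case_label, control_label = control_label),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("<contrast> %s vs %s\n", x$case_label, x$control_label))
  invisible(x)
}

#' Construct a gene signature
#'
#' A named pair of up- and down-regulated gene lists derived at a combined
#' p-value threshold, with provenance.
#'
#' @param name signature name.
#' @param up,down character vectors of gene symbols; must be disjoint.
#' @param threshold combined p-value threshold used for derivation.
#' @param source_studies character vector of contributing study IDs.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, up, down, threshold, source_studies = character()) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)))
    stop("up and down gene lists overlap", call. = FALSE)
  structure(list(name = as.character(name)[1], up = up, down = down,
                 threshold = as.numeric(threshold)[1],
                 source_studies = as.character(source_studies)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up, %d down (p < %g; %d studies)\n",
              x$name, length(x$up), length(x$down), x$threshold,
              length(x$source_studies)))
  invisible(x)
}
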