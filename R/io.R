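# Format doubles so that read-back reproduces them bit-for-bit.
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a gene-by-sample matrix as tab-delimited text
#'
#' Header row `gene<TAB>sample1...`; numeric values are written with 17
#' significant digits so a read/write round trip is exact.
#'
#' @param x numeric matrix with gene rownames and sample colnames, or an
#'   [expression_study()].
#' @param path output file.
#' @export
write_expression_tsv <- function(x, path) {
  if (inherits(x, "expression_study")) x <- x$values
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c("gene", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], fmt_num(x[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a gene-by-sample tab-delimited matrix
#'
#' Expects a header row of sample IDs (first field is the gene-column name)
#' and one gene per row. Duplicate sample IDs, ragged rows and non-numeric
#' cells are rejected with the offending line number. Duplicate gene symbols
#' are retained here; [expression_study()] collapses them.
#'
#' @param path input file.
#' @return numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (length(header) < 2)
    stop("malformed header (line 1): need gene column plus >= 1 sample",
         call. = FALSE)
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample IDs in header (line 1)", call. = FALSE)
  nfield <- length(header)
  n <- length(lines) - 1L
  m <- matrix(NA_real_, n, length(samples))
  genes <- character(n)
  for (i in seq_len(n)) {
    row <- parts[[i + 1L]]
    if (length(row) != nfield)
      stop(sprintf("ragged row at line %d: %d fields, expected %d",
                   i + 1L, length(row), nfield), call. = FALSE)
    genes[i] <- row[1]
    v <- suppressWarnings(as.numeric(row[-1]))
    bad <- is.na(v) & !(row[-1] %in% c("NA", "NaN"))
    if (any(bad))
      stop(sprintf("non-numeric cell at line %d (sample %s)",
                   i + 1L, samples[which(bad)[1]]), call. = FALSE)
    m[i, ] <- v
  }
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a sample annotation table
#' @param phenotype named character vector (sample -> label).
#' @param path output file.
#' @param study_id optional study ID written as a third column.
#' @export
write_annotation_tsv <- function(phenotype, path, study_id = NULL) {
  lines <- paste(names(phenotype), phenotype, sep = "\t")
  header <- "sample_id\tphenotype"
  if (!is.null(study_id)) {
    lines <- paste(lines, study_id, sep = "\t")
    header <- paste0(header, "\tstudy_id")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a sample annotation table
#' @param path file with columns `sample_id`, `phenotype` (optionally
#'   `study_id`).
#' @return named character vector of phenotypes.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "phenotype")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample IDs in annotation file", call. = FALSE)
  setNames(as.character(d$phenotype), d$sample_id)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then gene symbols. Lines with fewer
#' than 3 fields are rejected with their line number.
#'
#' @param path GMT file.
#' @return named list of character gene vectors; descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); desc <- character()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i),
           call. = FALSE)
    sets[[p[1]]] <- p[-(1:2)]
    desc[p[1]] <- p[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character gene vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a gene signature as JSON
#' @param signature a [gene_signature()].
#' @param path output file.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  jsonlite::write_json(
    list(name = signature$name,
         up = signature$up, down = signature$down,
         threshold = signature$threshold,
         source_studies = signature$source_studies),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a gene signature from JSON
#' @param path JSON file written by [write_signature()].
#' @return a [gene_signature()].
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gene_signature(x$name, x$up %||% character(), x$down %||% character(),
                 x$threshold, x$source_studies %||% character())
}

#' Write a per-study DE table as TSV
#' @param de a `de_result` from [run_de()].
#' @param path output file.
#' @export
write_de_tsv <- function(de, path) {
  cols <- c("gene", "log2_fc", "t_mod", "df_total", "p", "p_adj")
  header <- paste(cols, collapse = "\t")
  body <- vapply(seq_len(nrow(de)), function(i)
    paste(c(de$gene[i], fmt_num(c(de$log2_fc[i], de$t_mod[i], de$df_total[i],
                                  de$p[i], de$p_adj[i]))), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-cell matrix-market directory
#'
#' Expects `matrix.mtx` (genes x cells), `genes.tsv` and `barcodes.tsv`
#' (first column used from each).
#'
#' @param dir directory with the three files.
#' @return dense genes x cells numeric matrix.
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  m <- as.matrix(m)
  dimnames(m) <- list(genes, cells)
  m
}

#' Write the outputs of a bulk simulation to a directory
#'
#' One matrix TSV and one annotation TSV per study plus a truth TSV
#' (gene, class, per-study effects).
#'
#' @param sim result of [simulate_bulk_studies()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in sim$studies) {
    write_expression_tsv(st, file.path(dir, paste0(st$study_id, "_matrix.tsv")))
    write_annotation_tsv(st$phenotype,
                         file.path(dir, paste0(st$study_id, "_pheno.tsv")),
                         study_id = st$study_id)
  }
  tr <- sim$truth
  eff <- tr$effects
  header <- paste(c("gene", "class", paste0("effect_", colnames(eff))),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(eff)), function(i)
    paste(c(rownames(eff)[i], tr$class[[rownames(eff)[i]]], fmt_num(eff[i, ])),
          collapse = "\t"), "")
  writeLines(c(header, body), file.path(dir, "truth.tsv"))
  invisible(dir)
}
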