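#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; fields mirror the arguments of [run_pipeline()]'s
#'   config list.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    contrast = list(case = "tolDC", control = "imDC"),
    normalization = "quantile",
    combine_method = "pearson",
    threshold = 1e-5,
    min_studies = NULL,
    signature_name = "consensus",
    simulate = NULL,     # sim_config fields; alternative to `studies`
    studies = NULL,      # list of list(matrix=, pheno=)
    validation = NULL,   # list of list(matrix=, pheno=) for concordance
    gmt = NULL,          # path to a GMT file for enrichment
    enrichment_method = "wilcoxon"
  )
}

load_study_from_paths <- function(paths, id) {
  m <- read_expression_tsv(paths$matrix)
  pheno <- read_annotation_tsv(paths$pheno)
  expression_study(m, pheno, id)
}

preprocess_study <- function(study, normalization) {
  study <- log_transform_if_needed(study)
  study <- filter_unexpressed(study)
  if (normalization == "quantile") quantile_normalize(study)
  else if (normalization == "tmm") tmm_normalize(study)
  else study
}

#' Run the full consensus-signature pipeline
#'
#' Executes preprocess -> per-study differential expression -> cross-study
#' combination -> signature derivation, and optionally pathway enrichment
#' and held-out validation, writing every stage's output plus a manifest
#' into `outdir`. All randomness flows from `config$seed`. Any stage
#' failure aborts with the stage name after writing a partial manifest.
#'
#' Config fields (all optional except when noted): `seed`; `contrast`
#' (list with `case`, `control`); `normalization` (`"quantile"`, `"tmm"`,
#' `"none"`); `combine_method` (`"pearson"`, `"fisher"`, `"stouffer"`);
#' `threshold`; `min_studies`; `signature_name`; either `simulate` (fields
#' for [sim_config()]) or `studies` (list of `list(matrix=, pheno=)` file
#' paths); `validation` (like `studies`); `gmt` (gene-set file for
#' enrichment); `enrichment_method` (`"wilcoxon"` or `"gsea"`).
#'
#' @param config named list (see above) or path to a YAML file.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the derived `signature`, the
#'   `combined` gene table, per-study `de` results, optional `enrichment`
#'   and `validation` results, and the `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  if (!(is.numeric(cfg$threshold) && cfg$threshold > 0 && cfg$threshold < 1))
    stop("config threshold must lie in (0, 1)", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "consensig",
                   version = as.character(packageVersion("consensig")),
                   seed = cfg$seed,
                   parameters = cfg[c("normalization", "combine_method",
                                      "threshold", "signature_name",
                                      "enrichment_method")],
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- input stage -----------------------------------------------------
  truth <- NULL
  studies <- stage("input", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim <- simulate_bulk_studies(do.call(sim_config, sim_args))
      truth <- sim$truth
      sim$studies
    } else if (!is.null(cfg$studies)) {
      checks <- vapply(unlist(lapply(cfg$studies, unlist)), function(p)
        file.exists(p), TRUE)
      if (!all(checks))
        stop("missing input file(s): ",
             paste(names(checks)[!checks], collapse = ", "))
      manifest$inputs <- lapply(cfg$studies, function(s)
        list(matrix = unname(tools::md5sum(s$matrix)),
             pheno = unname(tools::md5sum(s$pheno))))
      lapply(seq_along(cfg$studies), function(i)
        load_study_from_paths(cfg$studies[[i]],
                              names(cfg$studies)[i] %||% sprintf("study%d", i)))
    } else stop("config must provide `simulate` or `studies`")
  })
  manifest$stages$input <- list(status = "ok", n_studies = length(studies))

  ctr <- contrast(cfg$contrast$case, cfg$contrast$control)

  # --- preprocess ------------------------------------------------------
  studies <- stage("preprocess", lapply(studies, preprocess_study,
                                        normalization = cfg$normalization))
  manifest$stages$preprocess <- list(
    status = "ok", normalization = cfg$normalization,
    genes = vapply(studies, function(s) nrow(s$values), 0L),
    samples = vapply(studies, function(s) ncol(s$values), 0L))

  # --- per-study DE ----------------------------------------------------
  de_list <- stage("diffexpr", {
    out <- lapply(studies, run_de, ctr = ctr)
    names(out) <- vapply(studies, `[[`, "", "study_id")
    out
  })
  for (id in names(de_list))
    write_de_tsv(de_list[[id]], file.path(outdir, paste0("de_", id, ".tsv")))
  manifest$stages$diffexpr <- list(
    status = "ok",
    d0 = vapply(de_list, function(d) attr(d, "d0"), 0),
    n_de_padj05 = vapply(de_list, function(d) sum(d$p_adj < 0.05), 0L))

  # --- combine ---------------------------------------------------------
  combined <- stage("combine", combine_studies(
    de_list, min_studies = cfg$min_studies %||% length(de_list),
    method = cfg$combine_method))
  write_combined_tsv(combined, file.path(outdir, "combined.tsv"))
  manifest$stages$combine <- list(status = "ok", n_genes = nrow(combined),
                                  method = cfg$combine_method)

  # --- signature -------------------------------------------------------
  signature <- stage("signature", derive_signature(
    combined, threshold = cfg$threshold, name = cfg$signature_name,
    source_studies = names(de_list)))
  write_signature(signature, file.path(outdir, "signature.json"))
  manifest$stages$signature <- list(status = "ok",
                                    n_up = length(signature$up),
                                    n_down = length(signature$down))

  # --- enrichment (optional) -------------------------------------------
  enrichment <- NULL
  if (!is.null(cfg$gmt)) {
    enrichment <- stage("enrichment", {
      sets <- read_gmt(cfg$gmt)
      scores <- setNames(-log10(combined$p_combined), combined$gene)
      if (cfg$enrichment_method == "gsea") {
        zc <- grep("^z_", names(combined), value = TRUE)
        ranked <- setNames(rowMeans(as.matrix(combined[, zc, drop = FALSE]),
                                    na.rm = TRUE), combined$gene)
        gsea_collection(ranked, sets, seed = cfg$seed)
      } else {
        wilcoxon_pathway_test(scores, sets)
      }
    })
    utils::write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrichment <- list(status = "ok",
                                       n_pathways = nrow(enrichment))
  }

  # --- validation (optional) -------------------------------------------
  validation <- NULL
  if (!is.null(cfg$validation)) {
    validation <- stage("validation", {
      lapply(seq_along(cfg$validation), function(i) {
        vs <- load_study_from_paths(cfg$validation[[i]],
                                    names(cfg$validation)[i] %||%
                                      sprintf("validation%d", i))
        vs <- preprocess_study(vs, cfg$normalization)
        vde <- run_de(vs, ctr)
        directional_concordance(signature, vde, seed = cfg$seed)
      })
    })
    rep <- lapply(validation, function(r)
      list(concordance = r$concordance, perm_p = r$perm_p,
           n_present = r$n_present))
    jsonlite::write_json(rep, file.path(outdir, "concordance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$stages$validation <- list(status = "ok",
                                       concordance = vapply(validation,
                                                            `[[`, 0, "concordance"))
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(signature = signature, combined = combined, de = de_list,
                 enrichment = enrichment, validation = validation,
                 truth = truth, manifest = manifest))
}

#' Write a combined gene table as TSV
#' @param combined a `combined_gene_table`.
#' @param path output file.
#' @export
write_combined_tsv <- function(combined, path) {
  zc <- grep("^z_", names(combined), value = TRUE)
  cols <- c("gene", "n_studies", "p_up", "p_down", "p_combined", "direction",
            zc)
  header <- paste(cols, collapse = "\t")
  body <- vapply(seq_len(nrow(combined)), function(i) {
    nums <- unlist(combined[i, c("p_up", "p_down", "p_combined")])
    zs <- unlist(combined[i, zc])
    paste(c(combined$gene[i], combined$n_studies[i], fmt_num(nums),
            combined$direction[i], fmt_num(zs)), collapse = "\t")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}
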