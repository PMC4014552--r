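#' Run the full miRNA-gene survival-module pipeline
#'
#' Executes the integrated analysis on sample-matched miRNA and mRNA
#' expression with clinical follow-up, a pathway collection and a
#' miRNA-target map:
#' \enumerate{
#'   \item remove samples below the minimum survival time;
#'   \item mean-split log-rank screen of miRNAs and genes
#'     (`alpha_survival`);
#'   \item hypergeometric enrichment of the survival genes and of each
#'     survival miRNA's reliably supported targets across pathways, and
#'     selection of survival pathways (`alpha_enrich`, `fdr_threshold`,
#'     `min_mirna_regulators`);
#'   \item random walk with restart on each selected pathway per
#'     regulating miRNA, and extraction of top-fraction core genes;
#'   \item assembly of the bipartite core miRNA-gene module.
#' }
#'
#' @param mirna_expr,mrna_expr expression matrices (features x samples).
#' @param clinical clinical data frame.
#' @param pathways named list of [pathway_graph()] objects.
#' @param targets miRNA-target map data frame.
#' @param config a [run_config()].
#' @param samples optional sample ids restricting the analysis (e.g. a
#'   training set).
#' @return List of class `pipeline_result` with the stage outputs:
#'   `screen_mirna`, `screen_gene`, `survival_mirnas`, `survival_genes`,
#'   `gene_enrichment`, `mirna_enrichment`, `selection`, `walk`
#'   (provenance and per-miRNA cores) and `module`.
#' @export
run_pipeline <- function(mirna_expr, mrna_expr, clinical, pathways,
                         targets, config = run_config(), samples = NULL) {
  clinical <- filter_min_survival(validate_clinical(clinical),
                                  config$min_survival_days)
  if (!is.null(samples)) {
    clinical <- clinical[clinical$sample_id %in% samples, , drop = FALSE]
  }
  log_stage(config, "filter", c(samples = nrow(clinical),
                                min_days = config$min_survival_days))

  screen_mirna <- screen_features(mirna_expr, clinical,
                                  config$alpha_survival)
  screen_gene <- screen_features(mrna_expr, clinical,
                                 config$alpha_survival)
  survival_mirnas <- screen_mirna$feature_id[screen_mirna$selected]
  survival_genes <- screen_gene$feature_id[screen_gene$selected]
  log_stage(config, "screen",
            c(mirnas = length(survival_mirnas),
              genes = length(survival_genes),
              alpha = config$alpha_survival))

  targets <- filter_target_map(targets, config$support_min)
  m <- if (is.null(config$genome_size)) nrow(mrna_expr) else
    config$genome_size
  gene_enrichment <- enrich_pathways(survival_genes, pathways, m)
  mirna_enrichment <- list()
  for (mirna in survival_mirnas) {
    tg <- targets$gene_id[targets$mirna_id == mirna]
    mirna_enrichment[[mirna]] <- enrich_pathways(tg, pathways, m)
  }
  selection <- select_survival_pathways(
    gene_enrichment, mirna_enrichment,
    alpha_enrich = config$alpha_enrich,
    fdr_threshold = config$fdr_threshold,
    min_regulators = config$min_mirna_regulators
  )
  log_stage(config, "enrich",
            c(pathways = length(selection$pathway_ids), m = m,
              alpha = config$alpha_enrich, fdr = config$fdr_threshold))

  walk <- run_pbrw(selection, pathways, survival_genes, targets, config)
  module <- assemble_module(walk$provenance)
  log_stage(config, "module",
            c(mirnas = length(module$mirnas), genes = length(module$genes),
              edges = nrow(module$edges)))

  structure(list(
    screen_mirna = screen_mirna, screen_gene = screen_gene,
    survival_mirnas = survival_mirnas, survival_genes = survival_genes,
    gene_enrichment = gene_enrichment, mirna_enrichment = mirna_enrichment,
    selection = selection, walk = walk, module = module, config = config
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  survival miRNAs: %d, survival genes: %d\n",
              length(x$survival_mirnas), length(x$survival_genes)))
  cat(sprintf("  selected pathways: %d\n", length(x$selection$pathway_ids)))
  cat(sprintf("  module: %d miRNAs x %d genes (%d edges)\n",
              length(x$module$mirnas), length(x$module$genes),
              nrow(x$module$edges)))
  invisible(x)
}

#' Write the module and sub-module tables of a pipeline result
#'
#' Writes the module edge list (TSV) and, when sub-modules are requested,
#' a sub-module membership TSV. Deterministic: the same pipeline result
#' produces byte-identical files.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @param submodules number of sub-modules to cut (`0` to skip).
#' @return Character vector of files written, invisibly.
#' @export
write_pipeline_result <- function(result, dir, submodules = 0L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edge_path <- file.path(dir, "module_edges.tsv")
  edges <- result$module$edges
  edges$gene_class <- result$module$gene_class[edges$gene_id]
  write.table(edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- edge_path
  if (submodules > 0) {
    subs <- detect_submodules(result$module, submodules)
    rows <- do.call(rbind, lapply(subs, function(s) {
      data.frame(
        sub_module = s$label,
        node_id = c(s$mirnas, s$genes),
        node_type = c(rep("mirna", length(s$mirnas)),
                      rep("gene", length(s$genes))),
        stringsAsFactors = FALSE
      )
    }))
    sub_path <- file.path(dir, "submodules.tsv")
    write.table(rows, sub_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, sub_path)
  }
  invisible(files)
}
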