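#' Hypergeometric enrichment p-value
#'
#' Upper tail probability `P(X >= r)` for `X ~ Hypergeometric` with a
#' population of `m` genes of which `t` belong to the pathway, when `n`
#' query genes are drawn: the chance of seeing at least the observed
#' overlap by accident.
#'
#' @param m gene universe size.
#' @param t pathway gene count (`t <= m`).
#' @param n query gene-set size (`n <= m`).
#' @param r_overlap observed overlap (`0 <= r_overlap <= min(n, t)`).
#' @return Exact tail probability.
#' @examples
#' hypergeometric_pvalue(20, 5, 5, 3)
#' @export
hypergeometric_pvalue <- function(m, t, n, r_overlap) {
  if (t > m || n > m) stop("t and n must not exceed m")
  if (r_overlap < 0 || r_overlap > min(n, t)) {
    stop("r_overlap must lie in [0, min(n, t)]")
  }
  if (r_overlap == 0) return(1)
  phyper(r_overlap - 1, t, m - t, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment, order-preserving with the
#' input vector.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, elementwise at least as large as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Hypergeometric enrichment of a gene set across pathways
#'
#' Tests each pathway's gene nodes for over-representation of the query
#' genes. Only gene-type nodes count towards the pathway size `t` and the
#' overlap `r_overlap`. FDR values are Benjamini-Hochberg adjusted within
#' the tested family.
#'
#' @param query_genes character vector of query gene ids (an empty query
#'   yields `p = 1` everywhere).
#' @param pathways named list of [pathway_graph()] objects.
#' @param genome_size universe size `m`; must be at least the largest
#'   pathway gene count.
#' @return Data frame with columns `pathway_id`, `m`, `t`, `n`,
#'   `r_overlap`, `p_value`, `fdr`.
#' @export
enrich_pathways <- function(query_genes, pathways, genome_size) {
  query_genes <- unique(as.character(query_genes))
  n <- length(query_genes)
  rows <- lapply(pathways, function(g) {
    pg <- gene_nodes(g)
    t <- length(pg)
    if (t > genome_size) stop("genome_size smaller than pathway ",
                              g$pathway_id)
    r <- length(intersect(query_genes, pg))
    data.frame(pathway_id = g$pathway_id, m = genome_size, t = t, n = n,
               r_overlap = r,
               p_value = hypergeometric_pvalue(genome_size, t, min(n, genome_size), r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Select survival pathways from gene- and miRNA-level enrichment
#'
#' A pathway is selected when (i) its enrichment by the survival genes is
#' significant (`p < alpha_enrich`) and survives FDR control
#' (`fdr < fdr_threshold`), and (ii) at least `min_regulators` survival
#' miRNAs have their filtered target sets significantly enriched in it
#' (`p < alpha_enrich`). Those miRNAs are reported as the pathway's
#' regulators.
#'
#' @param gene_level enrichment table from [enrich_pathways()] on the
#'   survival genes.
#' @param mirna_level named list (one element per survival miRNA) of
#'   enrichment tables on that miRNA's filtered target genes.
#' @param alpha_enrich enrichment significance level (strict `<`).
#' @param fdr_threshold FDR cutoff for the gene-level family.
#' @param min_regulators minimum number of regulating miRNAs.
#' @return List with `pathway_ids` (character), `regulators` (named list
#'   mapping pathway id to its regulating miRNA ids) and `table` (the
#'   gene-level rows of the selected pathways).
#' @export
select_survival_pathways <- function(gene_level, mirna_level,
                                     alpha_enrich = 0.01,
                                     fdr_threshold = 0.15,
                                     min_regulators = 1L) {
  gene_pass <- gene_level$pathway_id[
    gene_level$p_value < alpha_enrich & gene_level$fdr < fdr_threshold
  ]
  regulators <- list()
  for (mirna in names(mirna_level)) {
    tab <- mirna_level[[mirna]]
    hits <- tab$pathway_id[tab$p_value < alpha_enrich]
    for (pid in hits) regulators[[pid]] <- c(regulators[[pid]], mirna)
  }
  n_reg <- vapply(gene_pass, function(pid) {
    length(regulators[[pid]])
  }, integer(1))
  selected <- gene_pass[n_reg >= min_regulators]
  list(
    pathway_ids = selected,
    regulators = regulators[selected],
    table = gene_level[gene_level$pathway_id %in% selected, , drop = FALSE]
  )
}
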