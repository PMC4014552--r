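#' Column-normalized transition matrix of a pathway graph
#'
#' Builds the adjacency matrix of a pathway (node order fixed by
#' lexicographic node id) and normalizes each column to sum to one, so
#' that column `j` holds the transition probabilities out of node `j`. By
#' default edges are treated as undirected; in directed mode only the
#' stored edge orientation is used. Dangling nodes (no outgoing edge)
#' receive a self-loop before normalization so the matrix stays
#' column-stochastic.
#'
#' @param graph a [pathway_graph()].
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return Column-stochastic matrix with node ids as dimnames.
#' @export
column_normalize <- function(graph, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  ids <- sort(graph$nodes$node_id, method = "radix")
  n <- length(ids)
  if (n == 0) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0) {
    from <- match(graph$edges$from, ids)
    to <- match(graph$edges$to, ids)
    A[cbind(to, from)] <- 1
    if (mode == "undirected") A[cbind(from, to)] <- 1
  }
  dangling <- which(colSums(A) == 0)
  if (length(dangling)) A[cbind(dangling, dangling)] <- 1
  sweep(A, 2, colSums(A), "/")
}

#' Restart vector over pathway seed nodes
#'
#' Seeds are the survival genes and the focal miRNA's target genes that
#' are present among the pathway's gene nodes; each seed receives equal
#' probability summing to one.
#'
#' @param graph a [pathway_graph()].
#' @param survival_genes character vector of survival-associated genes.
#' @param mirna_targets character vector of the focal miRNA's target
#'   genes.
#' @return Named probability vector over all pathway nodes (lexicographic
#'   order, matching [column_normalize()]).
#' @export
build_seed_vector <- function(graph, survival_genes,
                              mirna_targets = character(0)) {
  ids <- sort(graph$nodes$node_id, method = "radix")
  seeds <- intersect(union(survival_genes, mirna_targets), gene_nodes(graph))
  if (length(seeds) == 0) {
    stop("no seed gene intersects pathway ", graph$pathway_id)
  }
  p0 <- setNames(numeric(length(ids)), ids)
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p_0` from `p_0` until the L1
#' difference between successive iterates falls below `eps`. For a
#' column-stochastic `W` and restart probability `r > 0` the fixed point
#' is unique, so the result does not depend on the starting iterate.
#'
#' @param W column-stochastic transition matrix.
#' @param p0 restart (seed) probability vector, summing to one.
#' @param restart_prob restart probability `r` in (0, 1).
#' @param eps L1 convergence threshold.
#' @param max_iterations iteration cap; exceeding it is an error that
#'   reports the last residual.
#' @return List with `steady` (named steady-state probabilities, summing
#'   to one) and `iterations`.
#' @export
random_walk_restart <- function(W, p0, restart_prob = 0.7, eps = 1e-6,
                                max_iterations = 10000L) {
  stopifnot(restart_prob > 0, restart_prob < 1, eps > 0)
  if (abs(sum(p0) - 1) > 1e-9) stop("p0 must sum to 1")
  if (max(abs(colSums(W) - 1)) > 1e-9) stop("W must be column-stochastic")
  p <- p0
  for (it in seq_len(max_iterations)) {
    p_next <- as.vector((1 - restart_prob) * (W %*% p)) + restart_prob * p0
    delta <- sum(abs(p_next - p))
    p <- p_next
    if (delta < eps) {
      return(list(steady = setNames(p, rownames(W)), iterations = it))
    }
  }
  stop(sprintf("no convergence after %d iterations (last L1 residual %.3g)",
               max_iterations, delta))
}

#' Top-scoring core genes of a walked pathway
#'
#' Keeps the `ceiling(top_fraction * G)` highest-scoring gene nodes, where
#' `G` is the number of gene-type nodes. Non-gene nodes participate in the
#' walk but are never returned and do not count towards `G`. Ties at the
#' cutoff are broken by lexicographic node id.
#'
#' @param steady named steady-state probability vector.
#' @param graph the walked [pathway_graph()].
#' @param top_fraction fraction of gene nodes to keep (default 0.03).
#' @return Character vector of core gene ids.
#' @export
top_core_genes <- function(steady, graph, top_fraction = 0.03) {
  genes <- gene_nodes(graph)
  if (length(genes) == 0) stop("pathway has no gene nodes")
  stopifnot(top_fraction > 0, top_fraction <= 1)
  k <- ceiling(top_fraction * length(genes))
  scores <- steady[genes]
  ord <- order(-scores, genes, method = "radix")
  genes[ord][seq_len(k)]
}

#' Pathway-based random walk over all selected pathways
#'
#' For each survival miRNA, runs the restart walk on every selected
#' pathway that the miRNA regulates, seeded by the survival genes together
#' with the miRNA's filtered target genes present in that pathway, and
#' extracts the pathway's top-fraction core genes. The per-miRNA core set
#' is the union over its regulated pathways.
#'
#' @param selection output of [select_survival_pathways()].
#' @param pathways named list of [pathway_graph()] objects.
#' @param survival_genes survival-associated gene ids from the screen.
#' @param target_map target map data frame (filtered at
#'   `config$support_min`; re-filtering is idempotent).
#' @param config a [run_config()].
#' @return List with `provenance` (data frame `mirna_id`, `gene_id`,
#'   `pathway_id`, `score`, `rank`) and `core` (named list mapping each
#'   miRNA to its core gene set; miRNAs regulating no selected pathway map
#'   to an empty set).
#' @export
run_pbrw <- function(selection, pathways, survival_genes, target_map,
                     config = run_config()) {
  target_map <- filter_target_map(target_map, config$support_min)
  mirnas <- sort(unique(as.character(unlist(selection$regulators,
                                            use.names = FALSE))),
                 method = "radix")
  walked <- list()  # per pathway: W (walk cache is per pathway+seed set)
  prov <- list()
  core <- setNames(vector("list", length(mirnas)), mirnas)
  for (mirna in mirnas) {
    pids <- names(selection$regulators)[
      vapply(selection$regulators, function(x) mirna %in% x, logical(1))
    ]
    core_genes <- character(0)
    for (pid in pids) {
      graph <- pathways[[pid]]
      targets <- target_map$gene_id[target_map$mirna_id == mirna]
      p0 <- tryCatch(
        build_seed_vector(graph, intersect(survival_genes, gene_nodes(graph)),
                          targets),
        error = function(e) NULL
      )
      if (is.null(p0)) {
        warning("skipping pathway ", pid, " for ", mirna,
                ": no seed in graph")
        next
      }
      if (is.null(walked[[pid]])) {
        walked[[pid]] <- column_normalize(graph, config$walk_mode)
      }
      res <- random_walk_restart(walked[[pid]], p0,
                                 restart_prob = config$restart_prob,
                                 eps = config$convergence_eps,
                                 max_iterations = config$max_iterations)
      top <- top_core_genes(res$steady, graph, config$top_fraction)
      prov[[length(prov) + 1L]] <- data.frame(
        mirna_id = mirna, gene_id = top, pathway_id = pid,
        score = unname(res$steady[top]), rank = seq_along(top),
        stringsAsFactors = FALSE
      )
      core_genes <- union(core_genes, top)
    }
    core[[mirna]] <- core_genes
    if (length(pids) == 0) {
      message("miRNA ", mirna, " regulates no selected pathway")
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(mirna_id = character(), gene_id = character(),
               pathway_id = character(), score = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  rownames(provenance) <- NULL
  list(provenance = provenance, core = core)
}
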