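#' Construct an expression matrix
#'
#' A plain numeric matrix of log-scale expression values with unique
#' feature rownames and unique sample colnames. Used for both miRNA and
#' mRNA profiles.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param feature_ids,sample_ids optional dimnames; taken from `values`
#'   when omitted.
#' @return A validated numeric matrix.
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("feature and sample ids are required")
  }
  rownames(values) <- as.character(feature_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression(values)
  values
}

validate_expression <- function(x) {
  if (anyNA(x)) stop("expression matrix contains missing values")
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids")
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Tab-separated text: first column the feature id, header row the sample
#' ids. Duplicate feature rows are collapsed by their mean; duplicate
#' sample ids or non-numeric cells are errors.
#'
#' @param path path to the file.
#' @return Expression matrix (features x samples).
#' @seealso [write_expression()]
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a feature column and samples")
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  features <- df[[1]]
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                 features[bad[1, 1]], samples[bad[1, 2]]))
  }
  if (anyDuplicated(features)) {
    vals <- rowsum(vals, group = features, reorder = FALSE) /
      as.vector(table(factor(features, levels = unique(features))))
    features <- unique(features)
  }
  rownames(vals) <- features
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' Comma-separated text with named columns `sample_id`, `survival_days`,
#' `event` (1 = deceased, 0 = alive/censored), `grade` (II/III/IV) and
#' optionally `age` and `gender`.
#'
#' @param path path to the CSV file.
#' @return `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' Validate (and type) a clinical table
#'
#' @param df data frame with the clinical columns.
#' @return The validated data frame.
#' @export
validate_clinical <- function(df) {
  need <- c("sample_id", "survival_days", "event", "grade")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  df$survival_days <- as.integer(df$survival_days)
  if (anyNA(df$survival_days) || any(df$survival_days < 0)) {
    stop("survival_days must be non-negative integers")
  }
  df$event <- as.integer(df$event)
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L))) {
    stop("event must be 0 (alive/censored) or 1 (deceased)")
  }
  df$grade <- as.character(df$grade)
  bad <- setdiff(unique(df$grade), c("II", "III", "IV"))
  if (length(bad)) stop("unknown grade: ", paste(bad, collapse = ", "))
  df
}

#' Write a clinical table to CSV
#' @param df clinical data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(df, path) {
  validate_clinical(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep samples with a minimum survival time
#'
#' Samples observed for fewer than `min_days` days are removed (very short
#' survivors are likely to have died of causes other than the disease).
#' The boundary is kept: a sample with exactly `min_days` days survives the
#' filter.
#'
#' @param clinical clinical data frame.
#' @param min_days minimum survival in days (default 30).
#' @return Filtered clinical data frame.
#' @export
filter_min_survival <- function(clinical, min_days = 30L) {
  stopifnot(min_days >= 0)
  clinical[clinical$survival_days >= min_days, , drop = FALSE]
}

#' Construct a pathway graph
#'
#' Typed nodes (`gene` or `other`, e.g. compounds) plus directed edges.
#' Every edge endpoint must be a declared node.
#'
#' @param pathway_id,name identifiers.
#' @param nodes data frame with columns `node_id`, `node_type`.
#' @param edges data frame with columns `from`, `to`.
#' @return Object of class `pathway_graph`.
#' @export
pathway_graph <- function(pathway_id, name = pathway_id, nodes, edges) {
  nodes <- data.frame(node_id = as.character(nodes$node_id),
                      node_type = as.character(nodes$node_type),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node id in ", pathway_id)
  if (!all(nodes$node_type %in% c("gene", "other"))) {
    stop("node_type must be 'gene' or 'other'")
  }
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      stringsAsFactors = FALSE)
  loose <- setdiff(unique(c(edges$from, edges$to)), nodes$node_id)
  if (length(loose)) {
    stop("edge endpoints not declared as nodes in ", pathway_id, ": ",
         paste(head(loose, 5), collapse = ", "))
  }
  structure(list(pathway_id = as.character(pathway_id),
                 name = as.character(name),
                 nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph %s (%s): %d nodes (%d genes), %d edges\n",
              x$pathway_id, x$name, nrow(x$nodes),
              sum(x$nodes$node_type == "gene"), nrow(x$edges)))
  invisible(x)
}

#' Gene-type node ids of a pathway graph
#' @param graph a `pathway_graph`.
#' @return Character vector of gene node ids.
#' @export
gene_nodes <- function(graph) {
  graph$nodes$node_id[graph$nodes$node_type == "gene"]
}

#' Read a pathway collection
#'
#' Two tab-separated files: a node file with columns
#' `pathway_id`, `node_id`, `node_type` and an edge file with columns
#' `pathway_id`, `from`, `to`. Optionally a `name` column in the node file.
#'
#' @param nodes_path,edges_path file paths.
#' @return Named list of `pathway_graph` objects.
#' @export
read_pathways <- function(nodes_path, edges_path) {
  nd <- read.delim(nodes_path, stringsAsFactors = FALSE)
  ed <- read.delim(edges_path, stringsAsFactors = FALSE)
  ids <- unique(nd$pathway_id)
  out <- lapply(ids, function(pid) {
    nsub <- nd[nd$pathway_id == pid, , drop = FALSE]
    esub <- ed[ed$pathway_id == pid, , drop = FALSE]
    nm <- if ("name" %in% colnames(nsub)) nsub$name[1] else pid
    pathway_graph(pid, nm,
                  nodes = nsub[, c("node_id", "node_type")],
                  edges = esub[, c("from", "to")])
  })
  names(out) <- ids
  out
}

#' Write a pathway collection
#' @param pathways named list of `pathway_graph` objects.
#' @param nodes_path,edges_path output paths.
#' @return `nodes_path`, invisibly.
#' @export
write_pathways <- function(pathways, nodes_path, edges_path) {
  nd <- do.call(rbind, lapply(pathways, function(g) {
    data.frame(pathway_id = g$pathway_id, name = g$name, g$nodes,
               stringsAsFactors = FALSE)
  }))
  ed <- do.call(rbind, lapply(pathways, function(g) {
    if (nrow(g$edges) == 0) return(NULL)
    data.frame(pathway_id = g$pathway_id, g$edges, stringsAsFactors = FALSE)
  }))
  write.table(nd, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ed, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nodes_path)
}

#' Read a miRNA-target table
#'
#' Tab-separated with columns `mirna_id`, `gene_id`, `support_count`
#' (number of prediction sources asserting the pair, 1-11).
#'
#' @param path file path.
#' @return Validated data frame.
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_target_map(df)
}

validate_target_map <- function(df) {
  need <- c("mirna_id", "gene_id", "support_count")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("target map lacks columns: ",
                         paste(miss, collapse = ", "))
  df$mirna_id <- as.character(df$mirna_id)
  df$gene_id <- as.character(df$gene_id)
  df$support_count <- as.integer(df$support_count)
  if (anyNA(df$support_count) ||
      any(df$support_count < 1L | df$support_count > 11L)) {
    stop("support_count must be within 1..11")
  }
  if (anyDuplicated(df[, c("mirna_id", "gene_id")])) {
    stop("duplicate (mirna_id, gene_id) pair in target map")
  }
  df
}

#' Write a miRNA-target table
#' @param df target map data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(df, path) {
  validate_target_map(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep reliably supported miRNA-target pairs
#'
#' Retains pairs asserted by at least `support_min` of the 11 prediction
#' sources (boundary inclusive).
#'
#' @param targets target map data frame.
#' @param support_min minimum support count (default 6).
#' @return Filtered target map.
#' @export
filter_target_map <- function(targets, support_min = 6L) {
  stopifnot(support_min >= 1)
  targets[targets$support_count >= support_min, , drop = FALSE]
}
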