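#' Assemble the bipartite core miRNA-gene module
#'
#' Merges the per-miRNA core-gene relationships into one bipartite module.
#' Each gene is labelled by its source pathway, or `"multi"` when it was
#' recovered from more than one pathway.
#'
#' @param per_mirna_core provenance data frame with columns `mirna_id`,
#'   `gene_id`, `pathway_id` (as produced by [run_pbrw()]).
#' @return Object of class `core_module`: a list with `mirnas`, `genes`,
#'   `edges` (data frame `mirna_id`, `gene_id`, `pathways`) and
#'   `gene_class` (named character vector).
#' @export
assemble_module <- function(per_mirna_core) {
  if (is.null(per_mirna_core) || nrow(per_mirna_core) == 0) {
    return(structure(list(mirnas = character(0), genes = character(0),
                          edges = data.frame(mirna_id = character(),
                                             gene_id = character(),
                                             pathways = character(),
                                             stringsAsFactors = FALSE),
                          gene_class = character(0)),
                     class = "core_module"))
  }
  stopifnot(all(c("mirna_id", "gene_id", "pathway_id") %in%
                  colnames(per_mirna_core)))
  key <- paste(per_mirna_core$mirna_id, per_mirna_core$gene_id, sep = "\r")
  paths_by_edge <- split(per_mirna_core$pathway_id, key)
  uniq <- !duplicated(key)
  edges <- data.frame(
    mirna_id = per_mirna_core$mirna_id[uniq],
    gene_id = per_mirna_core$gene_id[uniq],
    stringsAsFactors = FALSE
  )
  edges$pathways <- vapply(paste(edges$mirna_id, edges$gene_id, sep = "\r"),
                           function(k) {
                             paste(sort(unique(paths_by_edge[[k]]),
                                        method = "radix"), collapse = ";")
                           }, character(1), USE.NAMES = FALSE)
  ord <- order(edges$mirna_id, edges$gene_id, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  gene_paths <- split(per_mirna_core$pathway_id, per_mirna_core$gene_id)
  gene_class <- vapply(gene_paths, function(p) {
    u <- unique(p)
    if (length(u) == 1) u else "multi"
  }, character(1))
  structure(list(
    mirnas = sort(unique(edges$mirna_id), method = "radix"),
    genes = sort(unique(edges$gene_id), method = "radix"),
    edges = edges,
    gene_class = gene_class[sort(names(gene_class), method = "radix")]
  ), class = "core_module")
}

#' @export
print.core_module <- function(x, ...) {
  cat(sprintf("core_module: %d miRNAs, %d genes, %d edges\n",
              length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Bipartite degree distributions of a core module
#'
#' @param module a `core_module`.
#' @return List with `mirna_degree` (genes per miRNA) and `gene_degree`
#'   (miRNAs per gene), both named integer vectors.
#' @export
degree_distribution <- function(module) {
  list(
    mirna_degree = vapply(split(module$edges$gene_id, factor(module$edges$mirna_id, levels = module$mirnas)),
                          function(x) length(unique(x)), integer(1)),
    gene_degree = vapply(split(module$edges$mirna_id, factor(module$edges$gene_id, levels = module$genes)),
                         function(x) length(unique(x)), integer(1))
  )
}

#' Expand a printed gene-symbol range
#'
#' Signature tables print runs of numbered family members as ranges such
#' as `"FZD1-FZD10"`. A range token has the same alphanumeric prefix on
#' both sides of the dash and integer suffixes `a <= b`; it expands to
#' `prefix a, ..., prefix b` inclusive. Any other token (including miRNA
#' names like `"miR-129-5p"`) is returned as itself.
#'
#' @param token a single symbol or range token.
#' @return Character vector of expanded symbols.
#' @examples
#' expand_symbol_range("FZD1-FZD10")
#' expand_symbol_range("EGFR")
#' @export
expand_symbol_range <- function(token) {
  token <- trimws(token)
  if (nchar(token) == 0) return(character(0))
  parts <- strsplit(token, "-", fixed = TRUE)[[1]]
  part_re <- "^([A-Za-z][A-Za-z0-9]*?)([0-9]+)$"
  if (length(parts) == 2 && all(grepl(part_re, parts))) {
    pre <- sub(part_re, "\\1", parts)
    suf <- as.integer(sub(part_re, "\\2", parts))
    if (pre[1] != pre[2]) {
      stop("mismatched prefixes in range token '", token, "'")
    }
    if (suf[1] > suf[2]) {
      stop("descending range in token '", token, "'")
    }
    return(paste0(pre[1], seq(suf[1], suf[2])))
  }
  token
}

#' Parse a printed sub-module signature table
#'
#' Rows carry semicolon-separated miRNA and gene signature cells; gene
#' tokens may be ranges (see [expand_symbol_range()]). Signatures are
#' expanded and de-duplicated.
#'
#' @param rows data frame with columns `sub_module`, `mirna_signature`,
#'   `gene_signature`.
#' @return Named list of sub-modules, each a list with `label`, `mirnas`,
#'   `genes`.
#' @export
parse_submodule_table <- function(rows) {
  stopifnot(all(c("sub_module", "mirna_signature", "gene_signature") %in%
                  colnames(rows)))
  expand_cell <- function(cell) {
    tokens <- trimws(strsplit(paste0(cell, ""), ";", fixed = TRUE)[[1]])
    tokens <- tokens[nchar(tokens) > 0]
    unique(unlist(lapply(tokens, expand_symbol_range), use.names = FALSE))
  }
  out <- lapply(seq_len(nrow(rows)), function(i) {
    list(label = as.character(rows$sub_module[i]),
         mirnas = expand_cell(rows$mirna_signature[i]),
         genes = expand_cell(rows$gene_signature[i]))
  })
  names(out) <- as.character(rows$sub_module)
  out
}

#' Read a sub-module signature table from TSV
#'
#' @param path tab-separated file with columns `sub_module`,
#'   `mirna_signature`, `gene_signature`. The packaged reference table of
#'   four glioma sub-module signatures is available via
#'   `system.file("extdata", "submodule_signatures.tsv",
#'   package = "mirmodwalk")`.
#' @return See [parse_submodule_table()].
#' @export
read_submodule_table <- function(path) {
  parse_submodule_table(read.delim(path, stringsAsFactors = FALSE))
}

# uncentered correlation distance: 1 - sum(xy) / sqrt(sum(x^2) sum(y^2));
# rows with zero norm are at distance 1 from everything
uncentered_cor_dist <- function(X) {
  norms <- sqrt(rowSums(X^2))
  cross <- X %*% t(X)
  denom <- outer(norms, norms)
  D <- 1 - ifelse(denom > 0, cross / denom, 0)
  D[denom == 0] <- 1
  diag(D) <- 0
  stats::as.dist(D)
}

#' Cut a core module into sub-modules
#'
#' Genes are clustered hierarchically on their rows of the bipartite
#' incidence matrix (genes x miRNAs, 1 where an edge exists) using the
#' uncentered correlation distance and complete linkage, and the tree is
#' cut into `k` gene clusters. Each miRNA is assigned to the cluster
#' holding the largest share of its neighbor genes (ties go to the
#' lexicographically first cluster label).
#'
#' @param module a `core_module`.
#' @param k number of sub-modules (1 <= k <= number of genes).
#' @return Named list of sub-modules `S1..Sk`, each a list with `label`,
#'   `mirnas`, `genes`. Gene sets partition the module's genes; the union
#'   of miRNA sets equals the module's miRNAs.
#' @export
detect_submodules <- function(module, k = 4L) {
  if (length(module$genes) == 0) stop("empty module")
  if (k > length(module$genes)) stop("k exceeds number of genes")
  inc <- matrix(0, length(module$genes), length(module$mirnas),
                dimnames = list(module$genes, module$mirnas))
  inc[cbind(module$edges$gene_id, module$edges$mirna_id)] <- 1
  if (k == 1L) {
    cl <- setNames(rep(1L, length(module$genes)), module$genes)
  } else {
    hc <- hclust(uncentered_cor_dist(inc), method = "complete")
    cl <- cutree(hc, k = k)
  }
  labels <- paste0("S", seq_len(k))
  gene_sets <- lapply(seq_len(k), function(i) {
    sort(names(cl)[cl == i], method = "radix")
  })
  mirna_cluster <- vapply(module$mirnas, function(m) {
    nb <- module$edges$gene_id[module$edges$mirna_id == m]
    share <- vapply(seq_len(k), function(i) {
      length(intersect(nb, gene_sets[[i]]))
    }, integer(1))
    which.max(share)  # first maximum = lexicographically first label
  }, integer(1))
  out <- lapply(seq_len(k), function(i) {
    list(label = labels[i],
         mirnas = sort(names(mirna_cluster)[mirna_cluster == i],
                       method = "radix"),
         genes = gene_sets[[i]])
  })
  names(out) <- labels
  out
}
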