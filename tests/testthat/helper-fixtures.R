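# Small in-code fixtures shared across test files.

# tiny pathway graph from an edge list; every mentioned node is a gene
# unless listed in `others`
toy_graph <- function(id, edges, extra_nodes = character(0),
                      others = character(0)) {
  ids <- unique(c(edges$from, edges$to, extra_nodes, others))
  pathway_graph(
    id, id,
    nodes = data.frame(node_id = ids,
                       node_type = ifelse(ids %in% others, "other", "gene")),
    edges = edges
  )
}

edge_df <- function(from, to) {
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

# random connected pathway graph for property tests
random_graph <- function(id, n, seed, p_extra = 0.08) {
  set.seed(seed)
  ids <- sprintf("%s_n%02d", id, seq_len(n))
  from <- to <- character(0)
  if (n > 1) {
    for (i in 2:n) {
      j <- sample.int(i - 1L, 1L)
      from <- c(from, ids[j]); to <- c(to, ids[i])
    }
    extra <- which(upper.tri(matrix(0, n, n)) &
                     matrix(runif(n * n) < p_extra, n, n), arr.ind = TRUE)
    from <- c(from, ids[extra[, 1]]); to <- c(to, ids[extra[, 2]])
  }
  toy_graph(id, edge_df(from, to))
}

# small clinical table with the given survival days / events
toy_clinical <- function(days, events,
                         grade = rep("IV", length(days)),
                         ids = sprintf("S%02d", seq_along(days))) {
  data.frame(sample_id = ids, survival_days = as.integer(days),
             event = as.integer(events), grade = grade,
             stringsAsFactors = FALSE)
}

# a small planted truth + matching small cohort for fast evaluation tests
small_truth <- function() {
  planted_truth(planted_mirnas = sprintf("mir-%04d", 1:3),
                planted_genes = sprintf("g%05d", 1:12),
                planted_seed_genes = sprintf("g%05d", 1:3))
}

small_cohort <- function(seed, n_samples = 80, n_genes = 40, n_mirnas = 10,
                         truth = small_truth()) {
  generate_cohort(n_samples = n_samples, n_genes = n_genes,
                  n_mirnas = n_mirnas, truth = truth, seed = seed)
}

# direct linear-solve oracle for the restart walk:
# p* = r (I - (1-r) W)^{-1} p0
rwr_solve <- function(W, p0, r) {
  n <- nrow(W)
  as.vector(r * solve(diag(n) - (1 - r) * W, p0))
}
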