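#' Ground truth of the planted miRNA-gene module
#'
#' Describes the co-expressed miRNA-gene module planted into synthetic
#' cohorts. The module is driven by one latent activity per sample: planted
#' genes load on it positively, planted miRNAs negatively (miRNAs repress
#' the module), with correlation `module_cor` and unit marginal variance.
#' The hazard of death depends on the planted seed genes and miRNAs through
#' the risk score described in [generate_cohort()].
#'
#' @param planted_mirnas ids of the planted miRNAs.
#' @param planted_genes ids of all planted module genes.
#' @param planted_seed_genes subset of `planted_genes` acting as hazard
#'   drivers.
#' @param effect_size log-hazard shift per unit risk score.
#' @param censor_rate expected fraction of censored (alive) samples;
#'   default matches a glioma cohort in which 57.5% of patients were alive
#'   at last follow-up.
#' @param module_cor correlation of each planted feature with the latent
#'   module activity (squared loading).
#' @return Object of class `planted_truth`.
#' @export
planted_truth <- function(planted_mirnas = sprintf("mir-%04d", 1:3),
                          planted_genes = sprintf("g%05d", 1:12),
                          planted_seed_genes = sprintf("g%05d", 1:3),
                          effect_size = 1.5,
                          censor_rate = 0.575,
                          module_cor = 0.7) {
  stopifnot(
    length(planted_mirnas) >= 1, length(planted_genes) >= 1,
    length(planted_seed_genes) >= 1,
    all(planted_seed_genes %in% planted_genes),
    is.finite(effect_size),
    censor_rate >= 0, censor_rate < 1,
    module_cor >= 0, module_cor < 1
  )
  structure(list(planted_mirnas = as.character(planted_mirnas),
                 planted_genes = as.character(planted_genes),
                 planted_seed_genes = as.character(planted_seed_genes),
                 effect_size = effect_size,
                 censor_rate = censor_rate,
                 module_cor = module_cor),
            class = "planted_truth")
}

#' Default synthetic feature ids
#'
#' @param n_genes,n_mirnas universe sizes.
#' @return List with `genes` and `mirnas` id vectors; the planted defaults
#'   of [planted_truth()] occupy the first positions.
#' @export
synthetic_feature_ids <- function(n_genes, n_mirnas) {
  list(genes = sprintf("g%05d", seq_len(n_genes)),
       mirnas = sprintf("mir-%04d", seq_len(n_mirnas)))
}

#' Generate a synthetic survival cohort
#'
#' Emulates a sample-matched miRNA/mRNA glioma cohort. Background features
#' are i.i.d. standard normal; planted module features share a latent
#' activity (genes positively, miRNAs negatively) so the module is
#' co-expressed and miRNA-repressed. Each sample's risk score is the mean
#' expression of the planted seed genes minus the mean expression of the
#' planted miRNAs; survival times are exponential with hazard
#' `h0 * exp(effect_size * risk)`, censoring is uniform over the
#' unobserved death time for a `censor_rate` fraction of samples, and WHO
#' grades II/III/IV are assigned by risk tertiles with the proportions
#' 63:33:64 observed in a 160-patient glioma cohort.
#'
#' @param n_samples number of samples (at least 10).
#' @param n_genes,n_mirnas feature universe sizes (must contain the
#'   planted ids of `truth`).
#' @param truth a [planted_truth()].
#' @param seed integer seed; identical seeds give identical cohorts.
#' @param baseline_hazard baseline daily hazard `h0` (default gives a
#'   600-day median survival at risk 0).
#' @return List with elements `mirna` and `mrna` (expression matrices),
#'   `clinical` (data frame), and `risk` (true per-sample risk score, for
#'   diagnostics).
#' @export
generate_cohort <- function(n_samples = 160L, n_genes = 5000L,
                            n_mirnas = 150L, truth = planted_truth(),
                            seed = 1L,
                            baseline_hazard = log(2) / 600) {
  if (n_samples < 10) stop("n_samples must be at least 10")
  ids <- synthetic_feature_ids(n_genes, n_mirnas)
  if (!all(truth$planted_genes %in% ids$genes) ||
      !all(truth$planted_mirnas %in% ids$mirnas)) {
    stop("planted ids must lie within the feature universe")
  }
  set.seed(as.integer(seed))
  samples <- sprintf("S%03d", seq_len(n_samples))

  mrna <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                 dimnames = list(ids$genes, samples))
  mirna <- matrix(rnorm(n_mirnas * n_samples), n_mirnas, n_samples,
                  dimnames = list(ids$mirnas, samples))

  rho <- truth$module_cor
  z <- rnorm(n_samples)
  for (g in truth$planted_genes) {
    mrna[g, ] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
  }
  for (m in truth$planted_mirnas) {
    mirna[m, ] <- -sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
  }

  risk <- colMeans(mrna[truth$planted_seed_genes, , drop = FALSE]) -
    colMeans(mirna[truth$planted_mirnas, , drop = FALSE])

  hazard <- baseline_hazard * exp(truth$effect_size * risk)
  t_death <- rexp(n_samples, hazard)
  censored <- runif(n_samples) < truth$censor_rate
  obs <- ifelse(censored, runif(n_samples, 0, t_death), t_death)
  days <- pmax(1L, as.integer(ceiling(obs)))

  cuts <- quantile(risk, probs = cumsum(c(63, 33) / 160))
  grade <- cut(risk, breaks = c(-Inf, cuts, Inf),
               labels = c("II", "III", "IV"))

  clinical <- data.frame(
    sample_id = samples,
    survival_days = days,
    event = as.integer(!censored),
    grade = as.character(grade),
    age = pmin(80L, pmax(18L, as.integer(round(rnorm(n_samples, 41, 12.5))))),
    gender = sample(c("M", "F"), n_samples, replace = TRUE,
                    prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE
  )
  list(mirna = mirna, mrna = mrna, clinical = validate_clinical(clinical),
       risk = setNames(risk, samples))
}

# random connected undirected skeleton over `ids`: spanning tree plus
# extra edges up to the requested average degree
random_connected_edges <- function(ids, avg_degree = 3) {
  n <- length(ids)
  if (n == 1) return(data.frame(from = character(), to = character(),
                                stringsAsFactors = FALSE))
  ord <- sample(ids)
  from <- character(0); to <- character(0)
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    from <- c(from, ord[j]); to <- c(to, ord[i])
  }
  n_extra <- max(0L, round(avg_degree * n / 2) - (n - 1L))
  have <- paste(pmin(from, to), pmax(from, to))
  tries <- 0L
  while (n_extra > 0 && tries < 50L * n) {
    pair <- sample(ids, 2L)
    key <- paste(min(pair), max(pair))
    tries <- tries + 1L
    if (!key %in% have) {
      from <- c(from, pair[1]); to <- c(to, pair[2])
      have <- c(have, key)
      n_extra <- n_extra - 1L
    }
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Generate a synthetic pathway collection
#'
#' Builds `n_pathways` connected random graphs of `genes_per_pathway` gene
#' nodes plus a few non-gene (compound) nodes. The first
#' `length(planted_seed_genes)` pathways are "planted": pathway `j`
#' contains seed gene `j` together with an equal share of the remaining
#' planted genes, each wired directly to the pathway's seed gene (graph
#' distance 1) and to each other, so a walk restarted at the seeds can
#' reach the whole planted membership. Non-planted pathways contain no
#' planted genes.
#'
#' @param n_pathways number of pathways (at least the number of planted
#'   seed genes).
#' @param genes_per_pathway gene nodes per pathway (at least 10).
#' @param truth a [planted_truth()].
#' @param seed integer seed.
#' @param gene_pool gene id universe to draw background genes from;
#'   defaults to the 5000-gene universe of [generate_cohort()].
#' @param n_other_nodes non-gene nodes attached per pathway.
#' @param avg_degree target average node degree of the random skeleton.
#' @return Named list of `pathway_graph` objects.
#' @export
generate_pathways <- function(n_pathways = 10L, genes_per_pathway = 120L,
                              truth = planted_truth(), seed = 1L,
                              gene_pool = NULL, n_other_nodes = 5L,
                              avg_degree = 3) {
  if (genes_per_pathway < 10) stop("genes_per_pathway must be >= 10")
  n_planted <- length(truth$planted_seed_genes)
  if (n_pathways < n_planted) {
    stop("need at least one pathway per planted seed gene")
  }
  if (is.null(gene_pool)) gene_pool <- synthetic_feature_ids(5000L, 1L)$genes
  background <- setdiff(gene_pool, truth$planted_genes)
  others <- setdiff(truth$planted_genes, truth$planted_seed_genes)
  share <- split(others, rep(seq_len(n_planted), length.out = length(others)))

  set.seed(as.integer(seed))
  out <- vector("list", n_pathways)
  for (j in seq_len(n_pathways)) {
    pid <- sprintf("path%02d", j)
    if (j <= n_planted) {
      planted_here <- c(truth$planted_seed_genes[j],
                        if (j <= length(share)) share[[j]] else character(0))
      bg <- sample(background, genes_per_pathway - length(planted_here))
      genes <- c(planted_here, bg)
    } else {
      planted_here <- character(0)
      genes <- sample(background, genes_per_pathway)
    }
    cpds <- sprintf("%s_cpd%02d", pid, seq_len(n_other_nodes))
    nodes <- data.frame(
      node_id = c(genes, cpds),
      node_type = c(rep("gene", length(genes)), rep("other", length(cpds))),
      stringsAsFactors = FALSE
    )
    edges <- random_connected_edges(nodes$node_id, avg_degree)
    if (length(planted_here) > 1) {
      anchor <- truth$planted_seed_genes[j]
      extra_from <- character(0); extra_to <- character(0)
      rest <- setdiff(planted_here, anchor)
      for (g in rest) { extra_from <- c(extra_from, anchor); extra_to <- c(extra_to, g) }
      if (length(rest) > 1) {
        pairs <- utils::combn(rest, 2)
        extra_from <- c(extra_from, pairs[1, ]); extra_to <- c(extra_to, pairs[2, ])
      }
      key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
      ekey <- paste(pmin(extra_from, extra_to), pmax(extra_from, extra_to))
      keep <- !ekey %in% key & !duplicated(ekey)
      edges <- rbind(edges, data.frame(from = extra_from[keep],
                                       to = extra_to[keep],
                                       stringsAsFactors = FALSE))
    }
    out[[j]] <- pathway_graph(pid, sprintf("synthetic pathway %02d", j),
                              nodes, edges)
  }
  names(out) <- vapply(out, `[[`, character(1), "pathway_id")
  out
}

#' Generate a synthetic miRNA-target map
#'
#' Planted (miRNA, gene) pairs — every planted miRNA paired with every
#' planted gene — receive support counts drawn uniformly from 6..11; decoy
#' pairs receive 1..5. Filtering at a minimum support of 6 therefore
#' recovers exactly the planted pairs.
#'
#' @param truth a [planted_truth()].
#' @param n_decoys number of decoy pairs.
#' @param seed integer seed.
#' @param mirna_pool,gene_pool id universes for decoy pairs; default to the
#'   universes of [generate_cohort()].
#' @return Target map data frame.
#' @export
generate_target_map <- function(truth = planted_truth(), n_decoys = 300L,
                                seed = 1L, mirna_pool = NULL,
                                gene_pool = NULL) {
  ids <- synthetic_feature_ids(5000L, 150L)
  if (is.null(mirna_pool)) mirna_pool <- ids$mirnas
  if (is.null(gene_pool)) gene_pool <- ids$genes
  set.seed(as.integer(seed))
  planted <- expand.grid(mirna_id = truth$planted_mirnas,
                         gene_id = truth$planted_genes,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  planted$support_count <- sample(6:11, nrow(planted), replace = TRUE)
  decoy <- data.frame(
    mirna_id = sample(mirna_pool, 3L * n_decoys, replace = TRUE),
    gene_id = sample(gene_pool, 3L * n_decoys, replace = TRUE),
    stringsAsFactors = FALSE
  )
  key <- paste(decoy$mirna_id, decoy$gene_id)
  pkey <- paste(planted$mirna_id, planted$gene_id)
  decoy <- decoy[!duplicated(key) & !key %in% pkey, , drop = FALSE]
  decoy <- head(decoy, n_decoys)
  decoy$support_count <- sample(1:5, nrow(decoy), replace = TRUE)
  out <- rbind(planted, decoy)
  rownames(out) <- NULL
  validate_target_map(out)
}

#' Write a complete synthetic study to disk
#'
#' Generates a cohort, pathway collection and target map under one master
#' seed and writes all pipeline input files (plus the planted truth, for
#' reference) into `dir`. Running it twice with the same seed produces
#' byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param truth a [planted_truth()].
#' @param n_samples,n_genes,n_mirnas cohort dimensions.
#' @param n_pathways,genes_per_pathway pathway collection dimensions.
#' @param n_decoys decoy target pairs.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_study <- function(dir, truth = planted_truth(), n_samples = 160L,
                           n_genes = 5000L, n_mirnas = 150L,
                           n_pathways = 10L, genes_per_pathway = 120L,
                           n_decoys = 300L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n_samples, n_genes, n_mirnas, truth,
                            seed = stage_seed(seed, "cohort"))
  pw <- generate_pathways(n_pathways, genes_per_pathway, truth,
                          seed = stage_seed(seed, "pathways"),
                          gene_pool = rownames(cohort$mrna))
  tm <- generate_target_map(truth, n_decoys,
                            seed = stage_seed(seed, "targets"),
                            mirna_pool = rownames(cohort$mirna),
                            gene_pool = rownames(cohort$mrna))
  files <- c(
    mirna = file.path(dir, "mirna_expression.tsv"),
    mrna = file.path(dir, "mrna_expression.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    nodes = file.path(dir, "pathway_nodes.tsv"),
    edges = file.path(dir, "pathway_edges.tsv"),
    targets = file.path(dir, "target_map.tsv"),
    truth = file.path(dir, "planted_truth.tsv")
  )
  write_expression(cohort$mirna, files["mirna"])
  write_expression(cohort$mrna, files["mrna"])
  write_clinical(cohort$clinical, files["clinical"])
  write_pathways(pw, files["nodes"], files["edges"])
  write_target_map(tm, files["targets"])
  tr <- data.frame(
    field = c(rep("planted_mirna", length(truth$planted_mirnas)),
              rep("planted_gene", length(truth$planted_genes)),
              rep("planted_seed_gene", length(truth$planted_seed_genes)),
              "effect_size", "censor_rate", "module_cor"),
    value = c(truth$planted_mirnas, truth$planted_genes,
              truth$planted_seed_genes, truth$effect_size,
              truth$censor_rate, truth$module_cor),
    stringsAsFactors = FALSE
  )
  write.table(tr, files["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(files)
}
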