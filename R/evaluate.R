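# z-score with population (1/n) moments, row-wise
row_zscore <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  keep <- s > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s)")
    x <- x[keep, , drop = FALSE]
    mu <- mu[keep]; s <- s[keep]
  }
  (x - mu) / s
}

col_zscore <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}

#' Merge and normalize signature expression
#'
#' Restricts the sample-matched miRNA and mRNA profiles to a signature's
#' features, stacks them into one matrix over the shared samples, z-scores
#' each feature row (mean 0, sd 1) and then z-scores each sample column.
#' Constant rows are dropped with a warning.
#'
#' @param mirna_expr,mrna_expr expression matrices sharing sample ids.
#' @param signature list with character elements `mirnas` and `genes`
#'   (either may be empty).
#' @return Normalized merged matrix (signature features x shared samples).
#' @export
merge_and_normalize <- function(mirna_expr, mrna_expr, signature) {
  shared <- intersect(colnames(mirna_expr), colnames(mrna_expr))
  if (length(shared) == 0) stop("no shared samples")
  mirnas <- intersect(signature$mirnas, rownames(mirna_expr))
  genes <- intersect(signature$genes, rownames(mrna_expr))
  missing <- c(setdiff(signature$mirnas, mirnas),
               setdiff(signature$genes, genes))
  if (length(missing)) {
    stop("signature features absent from expression: ",
         paste(head(missing, 5), collapse = ", "))
  }
  x <- rbind(mirna_expr[mirnas, shared, drop = FALSE],
             mrna_expr[genes, shared, drop = FALSE])
  if (nrow(x) == 0) stop("empty signature")
  col_zscore(row_zscore(x))
}

# label the two sample groups high/low risk: higher death rate wins,
# ties by shorter median survival, then by lexicographically smallest
# member sample id
label_risk_groups <- function(groups, clinical) {
  cl <- clinical[match(names(groups), clinical$sample_id), ]
  stats_by <- lapply(split(seq_along(groups), groups), function(idx) {
    list(death = mean(cl$event[idx]),
         med = median(cl$survival_days[idx]),
         first = min(names(groups)[idx]))
  })
  ids <- names(stats_by)
  o <- order(-vapply(stats_by, `[[`, numeric(1), "death"),
             vapply(stats_by, `[[`, numeric(1), "med"),
             vapply(stats_by, `[[`, character(1), "first"))
  high <- ids[o[1]]
  setNames(ifelse(groups == high, "high", "low"), names(groups))
}

#' K-means risk grouping of samples
#'
#' Clusters the columns (samples) of a normalized signature matrix with
#' K-means (k = 2, multiple restarts, best within-cluster sum of
#' squares). The cluster with the higher observed death rate is labelled
#' high-risk (ties: shorter median survival, then lexicographically
#' smallest sample id).
#'
#' @param mat merged normalized matrix from [merge_and_normalize()].
#' @param clinical clinical data frame covering the matrix's samples.
#' @param k number of clusters (default 2).
#' @param seed integer seed; results are deterministic given the seed.
#' @param nstart number of random restarts.
#' @return Named character vector (`"high"`/`"low"`) per sample.
#' @export
kmeans_risk_groups <- function(mat, clinical, k = 2L, seed = 1L,
                               nstart = 10L) {
  if (ncol(mat) < 2 * k) stop("need at least ", 2 * k, " samples")
  if (nrow(unique(t(mat))) < k) {
    stop("degenerate input: fewer than ", k, " distinct samples")
  }
  set.seed(as.integer(seed))
  km <- kmeans(t(mat), centers = k, nstart = nstart)
  groups <- setNames(km$cluster, colnames(mat))
  label_risk_groups(groups, clinical)
}

#' Leave-one-out nearest-centroid risk classification
#'
#' For each sample in turn, the remaining samples are clustered into two
#' groups by K-means; the two group centroids are computed and the
#' held-out sample is assigned the risk label (death-rate labelling of
#' the two training groups) of the nearer centroid in Euclidean distance.
#' A distance tie assigns the sample to the high-risk group.
#'
#' @param mat merged normalized matrix (features x samples).
#' @param clinical clinical data frame covering the samples.
#' @param seed integer seed.
#' @param nstart K-means restarts per left-out sample.
#' @return Named character vector (`"high"`/`"low"`) per sample, with a
#'   `details` attribute holding the per-sample centroid distances.
#' @export
nearest_centroid_classify <- function(mat, clinical, seed = 1L,
                                      nstart = 10L) {
  n <- ncol(mat)
  if (n < 5) stop("need at least 5 samples")
  labels <- character(n)
  d_high <- numeric(n); d_low <- numeric(n)
  for (i in seq_len(n)) {
    rest <- mat[, -i, drop = FALSE]
    set.seed(stage_seed(seed, "kmeans") + i)
    km <- kmeans(t(rest), centers = 2L, nstart = nstart)
    grp <- label_risk_groups(setNames(km$cluster, colnames(rest)), clinical)
    cent_high <- rowMeans(rest[, grp == "high", drop = FALSE])
    cent_low <- rowMeans(rest[, grp == "low", drop = FALSE])
    dh <- sqrt(sum((mat[, i] - cent_high)^2))
    dl <- sqrt(sum((mat[, i] - cent_low)^2))
    labels[i] <- if (dh <= dl) "high" else "low"
    d_high[i] <- dh; d_low[i] <- dl
  }
  out <- setNames(labels, colnames(mat))
  attr(out, "details") <- data.frame(sample_id = colnames(mat),
                                     d_high = d_high, d_low = d_low,
                                     assigned = labels,
                                     stringsAsFactors = FALSE)
  out
}

#' Evaluate an expression signature as a survival predictor
#'
#' Forms two risk groups from the signature's merged, normalized
#' expression — by K-means clustering or leave-one-out nearest-centroid
#' classification — and compares their survival by the log-rank test.
#' Arbitrary sample subsets (e.g. a high-grade subgroup) can be evaluated
#' via `samples`.
#'
#' @param mirna_expr,mrna_expr expression matrices.
#' @param clinical clinical data frame.
#' @param signature list with `mirnas` and `genes`.
#' @param method `"kmeans"` or `"nearest_centroid"`.
#' @param seed integer seed.
#' @param samples optional sample ids to restrict to (at least 10).
#' @return List with `method`, `risk_labels`, `statistic`, `p_value`,
#'   `group_sizes`.
#' @export
evaluate_signature <- function(mirna_expr, mrna_expr, clinical, signature,
                               method = c("kmeans", "nearest_centroid"),
                               seed = 1L, samples = NULL) {
  method <- match.arg(method)
  clinical <- validate_clinical(clinical)
  shared <- Reduce(intersect, list(colnames(mirna_expr),
                                   colnames(mrna_expr),
                                   clinical$sample_id))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 10) stop("need at least 10 samples")
  mat <- merge_and_normalize(mirna_expr[, shared, drop = FALSE],
                             mrna_expr[, shared, drop = FALSE], signature)
  cl <- clinical[match(colnames(mat), clinical$sample_id), ]
  labels <- switch(method,
    kmeans = kmeans_risk_groups(mat, cl, seed = seed),
    nearest_centroid = nearest_centroid_classify(mat, cl, seed = seed)
  )
  lr <- logrank_test(cl$survival_days, cl$event, labels[cl$sample_id])
  list(method = method, risk_labels = labels, statistic = lr$statistic,
       p_value = lr$p_value, group_sizes = lr$group_sizes)
}

#' Optimize a top-n gene signature
#'
#' Given genes ranked by survival significance (most significant first),
#' evaluates each top-n subset as a gene-only signature and returns the
#' `n` minimizing the log-rank p-value (ties favor the smaller `n`),
#' together with the whole p-versus-n curve.
#'
#' @param ranked_genes character vector of gene ids, best first.
#' @param mirna_expr,mrna_expr,clinical expression and clinical inputs.
#' @param n_range candidate sizes (default 2..25); truncated with a
#'   warning when it exceeds the number of ranked genes.
#' @param method risk-grouping method, see [evaluate_signature()].
#' @param seed integer seed.
#' @param samples optional sample subset.
#' @return List with `best_n` and `curve` (data frame `n`, `p_value`).
#' @export
optimize_topn <- function(ranked_genes, mirna_expr, mrna_expr, clinical,
                          n_range = 2:25, method = "kmeans", seed = 1L,
                          samples = NULL) {
  n_range <- sort(unique(as.integer(n_range)))
  if (max(n_range) > length(ranked_genes)) {
    warning("n_range truncated to the ", length(ranked_genes),
            " available genes")
    n_range <- n_range[n_range <= length(ranked_genes)]
  }
  if (length(n_range) == 0) stop("no feasible n")
  pvals <- vapply(n_range, function(n) {
    sig <- list(mirnas = character(0), genes = ranked_genes[seq_len(n)])
    evaluate_signature(mirna_expr, mrna_expr, clinical, sig,
                       method = method, seed = stage_seed(seed, "topn") + n,
                       samples = samples)$p_value
  }, numeric(1))
  list(best_n = n_range[which.min(pvals)],
       curve = data.frame(n = n_range, p_value = pvals))
}

#' Recurrence ratio of a result set
#'
#' Fraction of an original result set (e.g. the module's genes) that is
#' recovered when the pipeline is rerun on perturbed or reshuffled
#' samples: `|original ∩ rerun| / |original|`.
#'
#' @param original non-empty character vector.
#' @param rerun character vector from the rerun.
#' @return Ratio in \[0, 1\].
#' @export
recurrence_ratio <- function(original, rerun) {
  original <- unique(original)
  if (length(original) == 0) stop("original set is empty")
  length(intersect(original, rerun)) / length(original)
}

#' Repeated shuffle-and-split sample partitions
#'
#' Shuffles the samples and splits them into disjoint training and
#' testing sets, `n_repeats` times. Reproducible for a given seed.
#'
#' @param sample_ids character vector (at least 4 samples).
#' @param n_repeats number of repeats (default 500).
#' @param train_fraction fraction assigned to training (default 0.5).
#' @param seed integer seed.
#' @return List of `n_repeats` lists with `train` and `test`.
#' @export
shuffle_and_split <- function(sample_ids, n_repeats = 500L,
                              train_fraction = 0.5, seed = 1L) {
  if (length(sample_ids) < 4) stop("need at least 4 samples")
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(stage_seed(seed, "split"))
  n_train <- round(train_fraction * length(sample_ids))
  lapply(seq_len(n_repeats), function(i) {
    perm <- sample(sample_ids)
    list(train = perm[seq_len(n_train)],
         test = perm[(n_train + 1):length(sample_ids)])
  })
}

#' Swap samples between a training and testing partition
#'
#' Perturbs an existing train/test partition by exchanging `n_swap`
#' samples between the two sets, for robustness reruns of the pipeline.
#'
#' @param train,test disjoint sample id vectors.
#' @param n_swap number of samples exchanged.
#' @param seed integer seed.
#' @return List with perturbed `train` and `test`.
#' @export
perturb_partition <- function(train, test, n_swap = 5L, seed = 1L) {
  stopifnot(n_swap >= 0, n_swap <= min(length(train), length(test)),
            length(intersect(train, test)) == 0)
  set.seed(stage_seed(seed, "split") + n_swap)
  out_tr <- sample(train, n_swap)
  out_te <- sample(test, n_swap)
  list(train = c(setdiff(train, out_tr), out_te),
       test = c(setdiff(test, out_te), out_tr))
}
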