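test_that("row normalization gives zero-mean unit-sd rows and drops constants", {
  x <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("f1", c("S1", "S2", "S3")))
  z <- mirmodwalk:::row_zscore(x)
  expect_equal(unname(z[1, ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)

  set.seed(12)
  m <- matrix(rnorm(80), 8, 10)
  zm <- mirmodwalk:::row_zscore(m)
  expect_equal(unname(rowMeans(zm)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(sqrt(rowMeans(zm^2))), rep(1, 8), tolerance = 1e-12)

  # an already row-standardized matrix passes through unchanged
  expect_equal(mirmodwalk:::row_zscore(zm), zm, tolerance = 1e-9)

  m2 <- rbind(m, 0)
  expect_warning(z2 <- mirmodwalk:::row_zscore(m2), "constant")
  expect_identical(nrow(z2), 8L)
})

test_that("merged signature matrices stack miRNA and gene rows over shared samples", {
  co <- small_cohort(seed = 71, n_samples = 30)
  sig <- list(mirnas = rownames(co$mirna)[1:2], genes = rownames(co$mrna)[1:3])
  mat <- merge_and_normalize(co$mirna, co$mrna, sig)
  expect_identical(dim(mat), c(5L, 30L))
  expect_setequal(rownames(mat), c(sig$mirnas, sig$genes))
  expect_equal(unname(colMeans(mat)), rep(0, 30), tolerance = 1e-12)

  expect_error(merge_and_normalize(co$mirna, co$mrna,
                                   list(mirnas = "nope", genes = sig$genes)),
               "absent")
  m2 <- co$mirna; colnames(m2) <- paste0("X", colnames(m2))
  expect_error(merge_and_normalize(m2, co$mrna, sig), "no shared samples")
})

test_that("k-means risk groups label the deadlier cluster high and are deterministic", {
  set.seed(41)
  n <- 30
  mat <- cbind(matrix(rnorm(5 * n, -3), 5, n), matrix(rnorm(5 * n, 3), 5, n))
  colnames(mat) <- sprintf("S%02d", 1:(2 * n))
  cl <- toy_clinical(rep(c(500L, 400L), each = n),
                     c(rbinom(n, 1, 0.9), rbinom(n, 1, 0.1)),
                     ids = colnames(mat))
  lab <- kmeans_risk_groups(mat, cl, seed = 3)
  expect_identical(unname(lab[1:n]), rep("high", n))
  expect_identical(unname(lab[(n + 1):(2 * n)]), rep("low", n))
  expect_identical(lab, kmeans_risk_groups(mat, cl, seed = 3))

  const <- matrix(1, 3, 10, dimnames = list(NULL, sprintf("S%02d", 1:10)))
  expect_error(kmeans_risk_groups(const, toy_clinical(rep(10, 10), rep(1, 10),
                                                      ids = colnames(const))),
               "degenerate")
})

test_that("k-means risk groups recover the planted cohort stratification", {
  hits <- vapply(1:20, function(i) {
    co <- small_cohort(seed = 500 + i, n_samples = 60)
    sig <- list(mirnas = small_truth()$planted_mirnas,
                genes = small_truth()$planted_genes)
    mat <- merge_and_normalize(co$mirna, co$mrna, sig)
    lab <- kmeans_risk_groups(mat, co$clinical, seed = i)
    truth_split <- ifelse(co$risk > median(co$risk), "high", "low")
    mean(lab[names(truth_split)] == truth_split)
  }, numeric(1))
  expect_gte(mean(pmax(hits, 1 - hits)), 0.9)
})

test_that("nearest-centroid assignments equal the direct distance comparison", {
  set.seed(43)
  mat <- cbind(matrix(rnorm(4 * 10, -4), 4, 10),
               matrix(rnorm(4 * 10, 4), 4, 10))
  colnames(mat) <- sprintf("S%02d", 1:20)
  cl <- toy_clinical(rep(c(100L, 900L), each = 10),
                     rep(c(1L, 0L), each = 10), ids = colnames(mat))
  lab <- nearest_centroid_classify(mat, cl, seed = 7)
  det <- attr(lab, "details")
  expect_identical(det$assigned,
                   ifelse(det$d_high <= det$d_low, "high", "low"))

  # well-separated blobs: leave-one-out equals direct k-means labels
  km <- kmeans_risk_groups(mat, cl, seed = 7)
  expect_identical(unname(lab[names(km)]), unname(km))
  expect_error(nearest_centroid_classify(mat[, 1:4], cl[1:4, ]), "at least 5")
})

test_that("signature evaluation is deterministic and calibrated under the null", {
  co <- small_cohort(seed = 81, n_samples = 60)
  sig <- list(mirnas = rownames(co$mirna)[1:2],
              genes = small_truth()$planted_genes[1:5])
  a <- evaluate_signature(co$mirna, co$mrna, co$clinical, sig, "kmeans",
                          seed = 2)
  b <- evaluate_signature(co$mirna, co$mrna, co$clinical, sig, "kmeans",
                          seed = 2)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$risk_labels, b$risk_labels)
  expect_identical(sum(a$group_sizes), 60L)

  expect_error(
    evaluate_signature(co$mirna, co$mrna, co$clinical, sig,
                       samples = co$clinical$sample_id[1:5]),
    "at least 10"
  )

  # null signatures (no planted features) give uniform p-values
  null_truth <- planted_truth(planted_mirnas = "mir-0001",
                              planted_genes = "g00001",
                              planted_seed_genes = "g00001",
                              effect_size = 0)
  pvals <- vapply(1:200, function(i) {
    co <- generate_cohort(n_samples = 40, n_genes = 8, n_mirnas = 3,
                          truth = null_truth, seed = 6000 + i)
    sig <- list(mirnas = character(0), genes = rownames(co$mrna)[2:6])
    evaluate_signature(co$mirna, co$mrna, co$clinical, sig, "kmeans",
                       seed = i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted signatures predict survival with high power", {
  pvals <- vapply(1:50, function(i) {
    co <- small_cohort(seed = 7000 + i, n_samples = 60)
    sig <- list(mirnas = small_truth()$planted_mirnas,
                genes = small_truth()$planted_genes)
    evaluate_signature(co$mirna, co$mrna, co$clinical, sig, "kmeans",
                       seed = i)$p_value
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.9)
})

test_that("top-n optimization scans the requested range and warns on truncation", {
  co <- small_cohort(seed = 91, n_samples = 60)
  ranked <- rownames(co$mrna)[1:30]
  res <- optimize_topn(ranked, co$mirna, co$mrna, co$clinical,
                       n_range = 2:25, seed = 4)
  expect_identical(nrow(res$curve), 24L)
  expect_identical(res$curve$n, 2:25)
  expect_true(res$best_n %in% 2:25)
  expect_equal(min(res$curve$p_value),
               res$curve$p_value[res$curve$n == res$best_n])

  expect_warning(
    short <- optimize_topn(ranked[1:5], co$mirna, co$mrna, co$clinical,
                           n_range = 2:25, seed = 4),
    "truncated"
  )
  expect_identical(short$curve$n, 2:5)
})

test_that("recurrence ratio is the intersection share of the original set", {
  expect_equal(recurrence_ratio(letters[1:5], letters[1:5]), 1)
  expect_equal(recurrence_ratio(letters[1:5], LETTERS[1:5]), 0)
  expect_error(recurrence_ratio(character(0), "a"), "empty")

  set.seed(19)
  for (i in 1:10) {
    orig <- sample(letters, 10)
    rerun <- sample(letters, sample.int(20, 1))
    expect_equal(recurrence_ratio(orig, rerun),
                 length(intersect(orig, rerun)) / 10)
  }
  # monotone in the intersection
  r <- vapply(0:10, function(k) {
    recurrence_ratio(letters[1:10], letters[seq_len(k)])
  }, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("shuffle-and-split partitions are disjoint, exhaustive and reproducible", {
  ids <- sprintf("S%03d", 1:160)
  sp <- shuffle_and_split(ids, n_repeats = 20, seed = 5)
  expect_length(sp, 20L)
  for (s in sp) {
    expect_length(s$train, 80L)
    expect_length(s$test, 80L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), ids)
  }
  expect_identical(sp, shuffle_and_split(ids, n_repeats = 20, seed = 5))
  expect_false(identical(sp, shuffle_and_split(ids, n_repeats = 20,
                                               seed = 6)))

  pert <- perturb_partition(ids[1:80], ids[81:160], n_swap = 10, seed = 3)
  expect_length(pert$train, 80L)
  expect_length(intersect(pert$train, pert$test), 0L)
  expect_length(intersect(pert$train, ids[81:160]), 10L)
})
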