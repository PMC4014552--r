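test_that("column normalization yields a stochastic matrix with the stated conventions", {
  # single node: self-loop rule
  g1 <- toy_graph("p", edge_df(character(0), character(0)),
                  extra_nodes = "a")
  expect_equal(column_normalize(g1), matrix(1, 1, 1,
                                            dimnames = list("a", "a")))

  # 2-node cycle: off-diagonal ones
  g2 <- toy_graph("p", edge_df(c("A", "B"), c("B", "A")))
  W <- column_normalize(g2)
  expect_equal(unname(W), matrix(c(0, 1, 1, 0), 2))

  # directed mode keeps only stored orientation; B dangles -> self-loop
  g3 <- toy_graph("p", edge_df("A", "B"))
  Wd <- column_normalize(g3, mode = "directed")
  expect_equal(Wd["B", "A"], 1)
  expect_equal(Wd["B", "B"], 1)
  expect_equal(Wd["A", "B"], 0)

  # node order is lexicographic
  g4 <- toy_graph("p", edge_df("zz", "aa"))
  expect_identical(rownames(column_normalize(g4)), c("aa", "zz"))

  # random 50-node graph: columns sum to one
  g5 <- random_graph("r", 50, seed = 123)
  expect_true(max(abs(colSums(column_normalize(g5)) - 1)) < 1e-12)
  expect_error(column_normalize(toy_graph("p", edge_df(character(0),
                                                       character(0)))),
               "empty")
})

test_that("seed vector spreads equal mass over seeds present in the graph", {
  g <- toy_graph("p", edge_df(c("a", "b", "c"), c("b", "c", "d")))
  p1 <- build_seed_vector(g, "a")
  expect_equal(p1[["a"]], 1)
  expect_equal(sum(p1), 1)

  p4 <- build_seed_vector(g, c("a", "b"), c("c", "d"))
  expect_equal(unname(p4[c("a", "b", "c", "d")]), rep(0.25, 4))

  set.seed(5)
  for (i in 1:10) {
    surv <- sample(c(letters[1:4], "x", "y"), 3)
    tg <- sample(c(letters[1:4], "z"), 2)
    expected <- intersect(union(surv, tg), c("a", "b", "c", "d"))
    if (length(expected) == 0) {
      expect_error(build_seed_vector(g, surv, tg), "no seed")
    } else {
      p <- build_seed_vector(g, surv, tg)
      expect_setequal(names(p)[p > 0], expected)
      expect_equal(sum(p), 1)
    }
  }
  expect_error(build_seed_vector(g, "nope"), "no seed")
})

test_that("restart walk reaches the closed-form fixed point", {
  # single self-loop node: fixed point immediately
  g1 <- toy_graph("p", edge_df(character(0), character(0)),
                  extra_nodes = "a")
  W1 <- column_normalize(g1)
  res1 <- random_walk_restart(W1, c(a = 1))
  expect_equal(unname(res1$steady), 1)
  expect_lte(res1$iterations, 1)

  # 2-node swap graph against the direct linear solve
  g2 <- toy_graph("p", edge_df(c("A", "B"), c("B", "A")))
  W2 <- column_normalize(g2)
  p0 <- build_seed_vector(g2, "A")
  res2 <- random_walk_restart(W2, p0, restart_prob = 0.7, eps = 1e-10)
  expect_equal(unname(res2$steady), rwr_solve(W2, p0, 0.7),
               tolerance = 1e-8)

  # random 30-node graph
  g3 <- random_graph("r", 30, seed = 55)
  W3 <- column_normalize(g3)
  p03 <- build_seed_vector(g3, gene_nodes(g3)[c(1, 7, 20)])
  res3 <- random_walk_restart(W3, p03, restart_prob = 0.7, eps = 1e-6)
  expect_lt(max(abs(res3$steady - rwr_solve(W3, p03, 0.7))), 1e-5)
  expect_equal(sum(res3$steady), 1, tolerance = 1e-9)
})

test_that("restart walk conserves probability and approaches p0 as r -> 1", {
  g <- random_graph("r", 40, seed = 77)
  W <- column_normalize(g)
  p0 <- build_seed_vector(g, gene_nodes(g)[1:4])
  res <- random_walk_restart(W, p0)
  expect_equal(sum(res$steady), 1, tolerance = 1e-9)
  expect_true(all(res$steady >= 0))

  near <- random_walk_restart(W, p0, restart_prob = 0.999)
  expect_lt(sum(abs(near$steady - p0)), 0.01)

  expect_error(random_walk_restart(W, p0, eps = 1e-15, max_iterations = 1),
               "no convergence")
  expect_error(random_walk_restart(W, p0 * 2), "sum to 1")
})

test_that("top-core extraction follows the ceiling rule and breaks ties lexicographically", {
  g <- random_graph("r", 20, seed = 31)
  ids <- sort(g$nodes$node_id)
  steady <- setNames(seq_along(ids) / sum(seq_along(ids)), ids)
  expect_identical(top_core_genes(steady, g, 0.03), ids[length(ids)])
  expect_setequal(top_core_genes(steady, g, 1.0), ids)

  for (G in c(1, 10, 33, 34, 100)) {
    gg <- toy_graph("p", edge_df(character(0), character(0)),
                    extra_nodes = sprintf("n%03d", seq_len(G)))
    s <- setNames(rep(0.5, G), sort(gene_nodes(gg)))
    expect_length(top_core_genes(s, gg, 0.03), ceiling(0.03 * G))
  }

  # 3-way tie at the boundary: k = 2, three nodes share the top score
  gt <- toy_graph("p", edge_df(character(0), character(0)),
                  extra_nodes = sprintf("n%02d", 1:34))
  s <- setNames(rep(0, 34), sort(gene_nodes(gt)))
  s[c("n07", "n03", "n11")] <- 0.9
  expect_identical(top_core_genes(s, gt, 0.03), c("n03", "n07"))

  # non-gene nodes never appear and do not count toward the denominator
  gm <- toy_graph("p", edge_df(c("a", "b"), c("b", "cpd")),
                  others = "cpd")
  sm <- setNames(c(0.1, 0.2, 0.7), c("a", "b", "cpd"))
  expect_identical(top_core_genes(sm, gm, 0.5), "b")
})

test_that("per-miRNA walks union their pathway cores with provenance", {
  g1 <- random_graph("pw1", 20, seed = 41)
  g2 <- random_graph("pw2", 20, seed = 42)
  pws <- list(pw1 = g1, pw2 = g2)
  surv <- c(gene_nodes(g1)[1:2], gene_nodes(g2)[1:2])
  tm <- data.frame(mirna_id = "mirX",
                   gene_id = c(gene_nodes(g1)[3], gene_nodes(g2)[3]),
                   support_count = 8L, stringsAsFactors = FALSE)
  cfg <- run_config(top_fraction = 0.2)

  sel1 <- list(pathway_ids = "pw1", regulators = list(pw1 = "mirX"))
  one <- run_pbrw(sel1, pws, surv, tm, cfg)
  W <- column_normalize(g1)
  p0 <- build_seed_vector(g1, surv, tm$gene_id)
  direct <- top_core_genes(random_walk_restart(W, p0,
                                               cfg$restart_prob,
                                               cfg$convergence_eps)$steady,
                           g1, 0.2)
  expect_setequal(one$core$mirX, direct)

  sel2 <- list(pathway_ids = c("pw1", "pw2"),
               regulators = list(pw1 = "mirX", pw2 = "mirX"))
  both <- run_pbrw(sel2, pws, surv, tm, cfg)
  expect_setequal(both$core$mirX,
                  union(both$provenance$gene_id[both$provenance$pathway_id == "pw1"],
                        both$provenance$gene_id[both$provenance$pathway_id == "pw2"]))
  expect_false(any(duplicated(both$core$mirX)))
  expect_true(all(c("mirna_id", "gene_id", "pathway_id", "score", "rank")
                  %in% colnames(both$provenance)))

  # a miRNA regulating no selected pathway yields an empty core set
  sel3 <- list(pathway_ids = character(0), regulators = setNames(list(), character(0)))
  expect_length(run_pbrw(sel3, pws, surv, tm, cfg)$core, 0)
})
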