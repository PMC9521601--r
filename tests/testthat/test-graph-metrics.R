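test_that("modularity closed forms hold on constructed graphs", {
  # any partition with everything in one community scores 0
  g <- random_graph(4, 4, 0.5, seed = 1)
  expect_equal(modularity(g, trivial_partition(g)), 0)

  # m disjoint edges, each its own community: Q = 1 - 1/m
  for (m_edges in c(2, 3, 4)) {
    g2 <- pair_graph(m_edges, m_edges, seq_len(m_edges), seq_len(m_edges))
    part <- singleton_partition(g2)
    for (i in seq_len(m_edges))
      part[c(paste0("T:T", i), paste0("C:C", i))] <- paste0("e", i)
    expect_equal(modularity(g2, part), 1 - 1 / m_edges)
  }

  # two disjoint 6-cycles, one community each: Q = 1/2
  g3 <- pair_graph(6, 6,
                   c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                   c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6))
  part3 <- singleton_partition(g3)
  part3[c(paste0("T:T", 1:3), paste0("C:C", 1:3))] <- "left"
  part3[c(paste0("T:T", 4:6), paste0("C:C", 4:6))] <- "right"
  expect_equal(modularity(g3, part3), 0.5)

  expect_error(modularity(pair_graph(2, 2, integer(0), integer(0)),
                          NULL), "edgeless")
})

test_that("modularity equals the direct double-sum on random graphs", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_graph(sample(2:5, 1), sample(2:5, 1), runif(1, 0.2, 0.8))
    if (n_edges(g) == 0) next
    part <- stats::setNames(
      paste0("c", sample(1:3, nrow(g$nodes), replace = TRUE)),
      g$nodes$node)
    expect_equal(modularity(g, part), oracle_modularity(g, part),
                 tolerance = 1e-12)
  }
})

test_that("modularity is invariant under community relabeling", {
  g <- random_graph(4, 4, 0.4, seed = 7)
  part <- stats::setNames(paste0("c", rep(1:2, 4)), g$nodes$node)
  relabeled <- stats::setNames(
    c(c1 = "zebra", c2 = "apple")[part], names(part))
  expect_equal(modularity(g, part), modularity(g, relabeled))
})

test_that("greedy maximization recovers obvious structure", {
  # two disjoint 6-cycles: the two components, Q = 0.5
  g <- pair_graph(6, 6,
                  c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4),
                  c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6))
  res <- max_modularity(g)
  expect_equal(res$q, 0.5)
  expect_length(unique(res$partition[c(paste0("T:T", 1:3),
                                       paste0("C:C", 1:3))]), 1)
  expect_length(unique(res$partition), 2)

  # single edge: optimum is 0 (both endpoints together)
  g1 <- pair_graph(2, 2, 1, 1)
  res1 <- max_modularity(g1)
  expect_equal(res1$q, 0)
  expect_equal(res1$partition[["T:T1"]], res1$partition[["C:C1"]])
  expect_equal(modularity(g1, singleton_partition(g1)), -0.5)

  # edgeless graph: sentinel with singleton partition
  g0 <- pair_graph(2, 2, integer(0), integer(0))
  expect_equal(max_modularity(g0)$q, 1)
  expect_equal(max_modularity(g0, edgeless_q = 0.5)$q, 0.5)
})

test_that("greedy result is bounded by the exhaustive optimum", {
  set.seed(202)
  hits <- 0
  for (rep in 1:20) {
    g <- random_graph(sample(2:4, 1), sample(2:4, 1), runif(1, 0.15, 0.4))
    if (n_edges(g) == 0) next
    q_greedy <- max_modularity(g)$q
    q_star <- oracle_max_modularity(g)
    expect_lte(q_greedy, q_star + 1e-12)
    expect_gte(q_greedy, 0)              # single community is reachable
    if (abs(q_greedy - q_star) < 1e-12) hits <- hits + 1
  }
  expect_gt(hits, 10)
})

test_that("greedy agrees with igraph fast-greedy on random instances", {
  set.seed(303)
  for (rep in 1:10) {
    g <- random_graph(6, 6, 0.25)
    if (n_edges(g) == 0) next
    q_pkg <- max_modularity(g)$q
    gi <- as_igraph(g)
    gi_sub <- igraph::delete_vertices(gi, igraph::degree(gi) == 0)
    q_ig <- max(igraph::cluster_fast_greedy(gi_sub)$modularity)
    # both are greedy heuristics with different tie-breaking; they must
    # agree to within heuristic slack and usually exactly
    expect_equal(q_pkg, q_ig, tolerance = 0.1)
  }
})

test_that("degree centrality counts direct connections", {
  g <- pair_graph(1, 3, c(1, 1, 1), c(1, 2, 3))   # star: teacher hub
  deg <- degree_centrality(g)
  expect_equal(deg[["T:T1"]], 3)
  expect_equal(unname(deg[paste0("C:C", 1:3)]), rep(1L, 3))
  expect_equal(unname(degree_centrality(pair_graph(2, 2, integer(0),
                                                   integer(0)))),
               rep(0L, 4))
  # handshake: degrees sum to twice the edge count
  for (seed in 1:5) {
    gr <- random_graph(5, 6, 0.3, seed = seed)
    expect_equal(sum(degree_centrality(gr)), 2 * n_edges(gr))
  }
})

test_that("relevance aggregation reproduces the published percentages", {
  summ <- aggregate_relevance(study_graphs())
  expect_equal(summ$total_edges, 24)
  t_rel <- stats::setNames(summ$teacher$node_relevance,
                           summ$teacher$channel)
  c_rel <- stats::setNames(summ$child$node_relevance, summ$child$channel)
  expect_equal(t_rel[["FP2-AF8"]], 21)    # 5/24 -> 20.8 -> 21
  expect_equal(t_rel[["AF3-F5"]], 13)     # 3/24 = 12.5 -> 13 (half-up)
  expect_equal(c_rel[["CP4-CP6"]], 29)    # 7/24 -> 29.2 -> 29
  # per-side node counts sum to the total edge count (bipartiteness)
  expect_equal(sum(summ$teacher$node_count), 24)
  expect_equal(sum(summ$child$node_count), 24)
  # percentages sum to ~100 (rounding slack: 1 per nonzero channel)
  expect_lte(abs(sum(t_rel) - 100), sum(t_rel > 0))
  expect_lte(abs(sum(c_rel) - 100), sum(c_rel > 0))
})

test_that("relevance handles degenerate collections", {
  g <- pair_graph(2, 2, 1, 2)
  summ <- aggregate_relevance(list(g))
  expect_equal(summ$teacher$node_relevance[summ$teacher$channel == "T1"],
               100)
  expect_equal(summ$child$node_relevance[summ$child$channel == "C2"], 100)
  expect_error(aggregate_relevance(list()), "empty")
  expect_error(aggregate_relevance(list(g, pair_graph(3, 2, 1, 1))),
               "montage")
})

test_that("eigenvector centrality matches closed forms", {
  # complete bipartite K22 (a 4-cycle): all nodes equivalent, all scores 1
  g <- pair_graph(2, 2, c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_equal(unname(eigenvector_centrality(g)), rep(1, 4),
               tolerance = 1e-8)
  # star with 3 leaves: hub 1, leaves 1/sqrt(3)
  star <- pair_graph(1, 3, c(1, 1, 1), c(1, 2, 3))
  ec <- eigenvector_centrality(star)
  expect_equal(ec[["T:T1"]], 1)
  expect_equal(unname(ec[paste0("C:C", 1:3)]), rep(1 / sqrt(3), 3),
               tolerance = 1e-8)
  expect_error(eigenvector_centrality(pair_graph(2, 2, integer(0),
                                                 integer(0))),
               "edgeless")
})

test_that("eigenvector centrality matches a dense eigendecomposition", {
  set.seed(404)
  for (rep in 1:10) {
    g <- random_graph(10, 10, 0.15)
    if (n_edges(g) == 0) next
    ec <- eigenvector_centrality(g, tol = 1e-12)
    A <- matrix(0, 20, 20)
    ids <- g$nodes$node
    for (r in seq_len(n_edges(g))) {
      i <- match(paste0("T:", g$edges$teacher[r]), ids)
      j <- match(paste0("C:", g$edges$child[r]), ids)
      A[i, j] <- A[j, i] <- 1
    }
    ev <- eigen(A, symmetric = TRUE)
    v <- abs(ev$vectors[, which.max(ev$values)])
    v <- v / max(v)
    expect_lt(max(abs(ec - v)), 1e-6)
  }
})

test_that("centrality concentrates on the dominant component", {
  # K33 block (spectral radius 3) plus a lone extra edge (radius 1)
  g <- pair_graph(4, 4, c(rep(1:3, each = 3), 4),
                  c(rep(1:3, times = 3), 4))
  ec <- eigenvector_centrality(g)
  expect_equal(unname(ec[c("T:T4", "C:C4")]), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(ec[paste0("T:T", 1:3)]), rep(1, 3),
               tolerance = 1e-6)
})

test_that("relevance TSV export mirrors the summary", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relevance(aggregate_relevance(study_graphs()), f)
  df <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 36)
  expect_equal(df$node_relevance[df$subject == "teacher" &
                                   df$channel == "FP2-AF8"], 21)
})
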