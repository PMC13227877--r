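path3 <- function() toy_gene_graph(rbind(c(1, 2), c(2, 3)))
k4 <- function() toy_gene_graph(t(utils::combn(4, 2)))
star4 <- function() toy_gene_graph(rbind(c(1, 2), c(1, 3), c(1, 4)))

test_that("degree statistics respect direction bookkeeping", {
  expect_equal(degree_stats(path3())$degree, c(1, 2, 1))
  expect_equal(degree_stats(k4())$degree, rep(3, 4))
})

test_that("betweenness matches hand-computed values on canonical graphs", {
  b <- graph_betweenness(path3())
  expect_equal(unname(b[c("V1", "V2", "V3")]), c(0, 1, 0))
  bs <- graph_betweenness(star4())
  expect_equal(unname(bs["V1"]), 1)
  expect_equal(unname(bs[c("V2", "V3", "V4")]), rep(0, 3))
  expect_equal(unname(graph_betweenness(k4())), rep(0, 4))
})

test_that("sampled betweenness with all pivots equals exact", {
  set.seed(11)
  for (i in 1:5) {
    g <- toy_gene_graph(random_toy_edges(8))
    n <- g$n_nodes
    expect_equal(graph_betweenness(g, mode = "sampled", sample_k = n),
                 graph_betweenness(g), tolerance = 1e-10)
  }
  g <- path3()
  expect_error(graph_betweenness(g, mode = "sampled", sample_k = 10),
               "exceeds")
})

test_that("closeness follows the per-component convention", {
  cc <- graph_closeness(path3())
  expect_equal(unname(cc["V2"]), 1)
  expect_equal(unname(cc["V1"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(graph_closeness(k4())), rep(1, 4))
  # two disconnected edges: r = 1 of n - 1 = 3 others, distance 1
  g2 <- toy_gene_graph(rbind(c(1, 2), c(3, 4)))
  expect_equal(unname(graph_closeness(g2)), rep(1 / 3, 4))
})

test_that("pagerank is a probability vector with the right symmetries", {
  pr_k4 <- graph_pagerank(k4())
  expect_equal(sum(pr_k4), 1, tolerance = 1e-9)
  expect_equal(unname(pr_k4), rep(0.25, 4), tolerance = 1e-6)
  pr2 <- graph_pagerank(toy_gene_graph(rbind(c(1, 2))))
  expect_equal(unname(pr2), c(0.5, 0.5), tolerance = 1e-6)
  prs <- graph_pagerank(star4())
  expect_gt(prs["V1"], max(prs[c("V2", "V3", "V4")]))
  expect_error(graph_pagerank(star4(), max_iter = 1), "converge")
  # agrees with an independent implementation
  g <- toy_gene_graph(random_toy_edges(10))
  ref <- igraph::page_rank(g$graph, damping = 0.85, weights = NA)$vector
  expect_equal(unname(graph_pagerank(g)), unname(ref), tolerance = 1e-6)
})

test_that("k-core numbers follow minimum-degree peeling", {
  expect_equal(unname(graph_kcore(k4())), rep(3L, 4))
  expect_equal(unname(graph_kcore(path3())), rep(1L, 3))
  pend <- toy_gene_graph(rbind(t(utils::combn(4, 2)), c(4, 5)))
  kc <- graph_kcore(pend)
  expect_equal(unname(kc["V5"]), 1L)
  expect_equal(unname(kc[c("V1", "V2", "V3", "V4")]), rep(3L, 4))
})

test_that("clustering and triangle counts match closed forms", {
  tri <- toy_gene_graph(t(utils::combn(3, 2)))
  ct <- graph_clustering_triangles(tri)
  expect_equal(ct$clustering, rep(1, 3))
  expect_equal(ct$triangles, rep(1L, 3))
  ct_p <- graph_clustering_triangles(path3())
  expect_equal(ct_p$clustering, rep(0, 3))
  expect_equal(ct_p$triangles, rep(0L, 3))
  ct_k4 <- graph_clustering_triangles(k4())
  expect_equal(ct_k4$triangles, rep(3L, 4))
  expect_equal(ct_k4$clustering, rep(1, 4))
})

test_that("eigenvector centrality is nonnegative with correct ordering", {
  ev <- graph_eigenvector(k4())
  expect_equal(unname(ev), rep(0.5, 4), tolerance = 1e-8)
  evs <- graph_eigenvector(star4())
  expect_gt(evs["V1"], max(evs[c("V2", "V3", "V4")]))
  evp <- graph_eigenvector(path3())
  expect_gt(evp["V2"], evp["V1"])
  # P3 principal eigenvector is (1, sqrt(2), 1)/2
  expect_equal(unname(evp), c(0.5, sqrt(2) / 2, 0.5), tolerance = 1e-6)
})

test_that("small random graphs agree exactly with brute-force oracles", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    edges <- random_toy_edges(n)
    g <- toy_gene_graph(edges)
    ids <- toy_node_ids(g)
    # the constructor drops isolated nodes; renumber the oracle input to
    # the retained nodes so both sides describe the same graph
    present <- sort(ids)
    remap <- match(edges, present)
    edges2 <- matrix(remap, ncol = 2)
    ids2 <- match(ids, present)
    expect_equal(unname(graph_betweenness(g)),
                 oracle_betweenness(edges2, length(present))[ids2],
                 tolerance = 1e-12)
    expect_equal(unname(graph_closeness(g)),
                 oracle_closeness(edges2, length(present))[ids2],
                 tolerance = 1e-12)
    expect_equal(unname(graph_clustering_triangles(g)$triangles),
                 as.integer(oracle_triangles(edges2, length(present))[ids2]))
  }
})

test_that("feature extraction yields a complete deterministic table", {
  g <- toy_gene_graph(rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5)))
  lab <- assign_labels(g, "V1")
  ft <- extract_features(g, lab)
  expect_equal(dim(ft), c(5, 10))
  expect_false(anyNA(ft))
  expect_equal(ft, extract_features(g, lab))
  expect_true(all(ft$kcore <= ft$degree))
  expect_true(all(ft$clustering >= 0 & ft$clustering <= 1))
  expect_equal(sum(ft$pagerank), 1, tolerance = 1e-9)
  expect_true(all(ft$triangles <= choose(ft$degree, 2)))
})

test_that("planted positives have right-shifted degrees in features", {
  fx <- small_planted()
  ft <- fx$features
  expect_gt(mean(ft$degree[ft$label == 1]), mean(ft$degree[ft$label == 0]))
})
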