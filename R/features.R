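#' Per-node degree statistics
#'
#' Outdegree and indegree follow the directed reading of the input edge list
#' (distinct ordered pairs); total degree is the undirected simple-graph
#' degree. On reciprocal-row STRING-dialect files all three coincide.
#'
#' @param graph A `gene_graph`.
#' @return Tibble with columns `gene`, `outdegree`, `indegree`, `degree`.
#' @export
degree_stats <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  if (graph$n_nodes == 0) abort("empty graph")
  graph$degrees
}

#' Betweenness centrality
#'
#' Normalised betweenness on the undirected simple projection: the fraction
#' of all-pairs shortest paths through each node,
#' \eqn{C_B(v) = \sum_{s \ne t \ne v} \sigma_{st}(v) / \sigma_{st}},
#' divided by the pair count \eqn{(n-1)(n-2)/2}; endpoints excluded.
#' `mode = "sampled"` uses Brandes source-pivot sampling with `sample_k`
#' seeded pivots and scales dependencies by \eqn{n/k}; with `sample_k = n`
#' it equals the exact value.
#'
#' @param graph A `gene_graph`.
#' @param mode `"exact"` or `"sampled"`.
#' @param sample_k Number of source pivots for sampled mode.
#' @param seed RNG seed for pivot selection.
#' @return Named numeric vector over nodes.
#' @export
graph_betweenness <- function(graph, mode = c("exact", "sampled"),
                              sample_k = 500, seed = 1) {
  stopifnot(inherits(graph, "gene_graph"))
  mode <- match.arg(mode)
  g <- graph$graph
  n <- igraph::vcount(g)
  if (mode == "exact") {
    if (n <= 2) {
      return(stats::setNames(numeric(n), igraph::V(g)$name))
    }
    b <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = TRUE)
    return(stats::setNames(as.numeric(b), igraph::V(g)$name))
  }
  if (sample_k > n) abort("sample_k exceeds the number of nodes")
  pivots <- with_seed(seed, sample.int(n, sample_k))
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  acc <- numeric(n)
  for (s in pivots) {
    acc <- acc + brandes_dependency(adj, s, n)
  }
  raw <- (n / sample_k) * acc / 2
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  stats::setNames(raw / norm, igraph::V(g)$name)
}

# Single-source Brandes dependency accumulation (unweighted BFS).
# Returns delta_s(v) for all v; summing over all sources gives twice the
# raw undirected betweenness.
brandes_dependency <- function(adj, s, n) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  dist[s] <- 0L
  sigma[s] <- 1
  order_visited <- integer(n)
  head_i <- 1L
  tail_i <- 1L
  order_visited[1L] <- s
  while (head_i <= tail_i) {
    v <- order_visited[head_i]
    head_i <- head_i + 1L
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        tail_i <- tail_i + 1L
        order_visited[tail_i] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  delta <- numeric(n)
  for (i in seq(tail_i, 1L)) {
    w <- order_visited[i]
    for (v in preds[[w]]) {
      delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
    }
  }
  delta[s] <- 0
  delta
}

#' Closeness centrality
#'
#' Per-component convention: for a node reaching \eqn{r} other nodes with
#' total shortest-path distance \eqn{D},
#' \eqn{C_C(v) = (r / (n-1)) \cdot (r / D)}; on a connected graph this is the
#' classical \eqn{(n-1) / \sum_u d(v, u)}. Singleton components score 0.
#'
#' @param graph A `gene_graph`.
#' @return Named numeric vector over nodes.
#' @export
graph_closeness <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n == 1) return(stats::setNames(0, igraph::V(g)$name))
  d <- igraph::distances(g, weights = NA)
  diag(d) <- Inf
  r <- rowSums(is.finite(d))
  total <- rowSums(ifelse(is.finite(d), d, 0))
  cc <- ifelse(r > 0, (r / (n - 1)) * (r / total), 0)
  stats::setNames(as.numeric(cc), igraph::V(g)$name)
}

#' PageRank by damped power iteration
#'
#' Stationary distribution of the damped random walk
#' \eqn{x \leftarrow (1-d)/n + d \, A x / \mathrm{deg}}, iterated until the
#' L1 residual falls below `tol`. Values sum to 1.
#'
#' @param graph A `gene_graph`.
#' @param damping Damping factor (default 0.85).
#' @param tol Convergence tolerance on the L1 residual.
#' @param max_iter Iteration cap; non-convergence is an error carrying the
#'   residual.
#' @return Named numeric probability vector over nodes.
#' @export
graph_pagerank <- function(graph, damping = 0.85, tol = 1e-9,
                           max_iter = 200) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  a <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- igraph::degree(g)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric((1 - damping) / n + damping * (a %*% (x / deg)))
    res <- sum(abs(x_new - x))
    x <- x_new
    if (res < tol) {
      return(stats::setNames(x / sum(x), igraph::V(g)$name))
    }
  }
  abort(paste0("PageRank did not converge in ", max_iter,
               " iterations (residual ", signif(res, 3), ")"))
}

#' k-core number per node
#'
#' Largest k such that the node survives iterative removal of all nodes of
#' degree below k (minimum-degree peeling) on the undirected simple
#' projection.
#'
#' @param graph A `gene_graph`.
#' @return Named integer vector over nodes.
#' @export
graph_kcore <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  k <- igraph::coreness(graph$graph)
  stats::setNames(as.integer(k), igraph::V(graph$graph)$name)
}

#' Local clustering coefficient and triangle count
#'
#' Clustering is \eqn{2 T / (\mathrm{deg} (\mathrm{deg} - 1))} with triangle
#' count T, and 0 for nodes of degree below 2.
#'
#' @param graph A `gene_graph`.
#' @return Tibble with columns `gene`, `clustering`, `triangles`.
#' @export
graph_clustering_triangles <- function(graph) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- graph$graph
  tri <- igraph::count_triangles(g)
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cl[is.nan(cl)] <- 0
  tibble::tibble(
    gene = igraph::V(g)$name,
    clustering = as.numeric(cl),
    triangles = as.integer(tri)
  )
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix, computed per connected
#' component by shifted power iteration (on A + I, which is primitive on a
#' connected graph), nonnegative and L2-normalised within each component.
#'
#' @param graph A `gene_graph`.
#' @param tol Convergence tolerance on the iterate change.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Named numeric vector over nodes.
#' @export
graph_eigenvector <- function(graph, tol = 1e-10, max_iter = 1000) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- graph$graph
  comp <- igraph::components(g)
  out <- numeric(igraph::vcount(g))
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) {
      out[idx] <- 1
      next
    }
    sub <- igraph::induced_subgraph(g, idx)
    a <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
    x <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      x_new <- as.numeric(a %*% x) + x
      x_new <- x_new / sqrt(sum(x_new^2))
      if (max(abs(x_new - x)) < tol) {
        x <- x_new
        converged <- TRUE
        break
      }
      x <- x_new
    }
    if (!converged) {
      abort(paste0("eigenvector centrality did not converge in ",
                   max_iter, " iterations"))
    }
    out[idx] <- abs(x)
  }
  stats::setNames(out, igraph::V(g)$name)
}

#' Settings for topology feature extraction
#'
#' @param betweenness_exact_limit Node count up to which betweenness is
#'   exact; larger graphs use pivot sampling.
#' @param betweenness_sample_k Pivot count for sampled betweenness.
#' @param seed Seed for sampled betweenness.
#' @param pagerank_damping,pagerank_tol,pagerank_max_iter PageRank controls.
#' @param eigen_tol,eigen_max_iter Eigenvector-centrality controls.
#' @return A list of settings for [extract_features()].
#' @export
feature_settings <- function(betweenness_exact_limit = 5000,
                             betweenness_sample_k = 500, seed = 1,
                             pagerank_damping = 0.85, pagerank_tol = 1e-9,
                             pagerank_max_iter = 200,
                             eigen_tol = 1e-10, eigen_max_iter = 1000) {
  list(
    betweenness_exact_limit = betweenness_exact_limit,
    betweenness_sample_k = betweenness_sample_k, seed = seed,
    pagerank_damping = pagerank_damping, pagerank_tol = pagerank_tol,
    pagerank_max_iter = pagerank_max_iter,
    eigen_tol = eigen_tol, eigen_max_iter = eigen_max_iter
  )
}

#' Extract the eight topology features per gene
#'
#' Builds the complete model input: degree, betweenness, PageRank, k-core
#' number, clustering coefficient, closeness, eigenvector centrality and
#' triangle count, plus the 0/1 driver label. Features are exported
#' unscaled; any standardisation is owned by the classifiers.
#'
#' @param graph A `gene_graph`.
#' @param labels Labelled gene tibble from [assign_labels()].
#' @param settings List from [feature_settings()].
#' @return A tibble with columns `gene`, the eight features, and `label`;
#'   one row per graph node, no missing values. Deterministic given
#'   `settings`.
#' @export
extract_features <- function(graph, labels, settings = feature_settings()) {
  stopifnot(inherits(graph, "gene_graph"))
  deg <- degree_stats(graph)
  n <- graph$n_nodes
  mode <- if (n <= settings$betweenness_exact_limit) "exact" else "sampled"
  btw <- graph_betweenness(graph, mode = mode,
                           sample_k = min(settings$betweenness_sample_k, n),
                           seed = settings$seed)
  pr <- graph_pagerank(graph, damping = settings$pagerank_damping,
                       tol = settings$pagerank_tol,
                       max_iter = settings$pagerank_max_iter)
  kc <- graph_kcore(graph)
  ct <- graph_clustering_triangles(graph)
  cc <- graph_closeness(graph)
  ev <- graph_eigenvector(graph, tol = settings$eigen_tol,
                          max_iter = settings$eigen_max_iter)
  out <- deg |>
    dplyr::select("gene", "degree") |>
    dplyr::mutate(
      betweenness = unname(btw[.data$gene]),
      pagerank = unname(pr[.data$gene]),
      kcore = unname(kc[.data$gene]),
    ) |>
    dplyr::left_join(ct, by = "gene") |>
    dplyr::mutate(
      closeness = unname(cc[.data$gene]),
      eigenvector = unname(ev[.data$gene])
    ) |>
    dplyr::select("gene", "degree", "betweenness", "pagerank", "kcore",
                  "clustering", "closeness", "eigenvector", "triangles") |>
    dplyr::left_join(
      dplyr::select(labels, "gene", "label"), by = "gene"
    )
  if (anyNA(out)) abort("labels must cover every graph node")
  attr(out, "settings") <- settings
  attr(out, "graph_size") <- c(nodes = graph$n_nodes, edges = graph$n_edges)
  out
}

# Names of the model feature columns in a feature table.
feature_cols <- function() {
  c("degree", "betweenness", "pagerank", "kcore", "clustering",
    "closeness", "eigenvector", "triangles")
}
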