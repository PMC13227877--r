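# Independent brute-force oracles, written against the definitions only;
# none of these share code with the package implementations.

# adjacency list (1-based) from an edge matrix on n nodes
oracle_adj <- function(edges, n) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]
    b <- edges[i, 2]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

oracle_bfs_dist <- function(adj, s, n) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  queue <- s
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# enumerate every shortest s-t path explicitly (exhaustive DFS on the BFS
# level structure) and count how many pass through each vertex
oracle_betweenness <- function(edges, n) {
  adj <- oracle_adj(edges, n)
  through <- numeric(n)
  enumerate_paths <- function(dist, t, path_tail) {
    v <- path_tail[length(path_tail)]
    if (v == t) return(list(path_tail))
    out <- list()
    for (w in adj[[v]]) {
      if (is.finite(dist[w]) && dist[w] == dist[v] + 1) {
        out <- c(out, enumerate_paths(dist, t, c(path_tail, w)))
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    dist <- oracle_bfs_dist(adj, s, n)
    for (t in (s + 1):n) {
      if (!is.finite(dist[t])) next
      paths <- enumerate_paths(dist, t, s)
      if (length(paths) == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        through[inner] <- through[inner] + 1 / length(paths)
      }
    }
  }
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  through / norm
}

oracle_closeness <- function(edges, n) {
  adj <- oracle_adj(edges, n)
  vapply(seq_len(n), function(v) {
    d <- oracle_bfs_dist(adj, v, n)[-v]
    r <- sum(is.finite(d))
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d[is.finite(d)]))
  }, numeric(1))
}

oracle_triangles <- function(edges, n) {
  adj <- oracle_adj(edges, n)
  has_edge <- function(a, b) b %in% adj[[a]]
  tri <- numeric(n)
  if (n >= 3) {
    for (combo in utils::combn(n, 3, simplify = FALSE)) {
      if (has_edge(combo[1], combo[2]) && has_edge(combo[2], combo[3]) &&
          has_edge(combo[1], combo[3])) {
        tri[combo] <- tri[combo] + 1
      }
    }
  }
  tri
}

# two-sided Fisher exact p by explicit hypergeometric enumeration
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b
  c1 <- a + c_
  n <- a + b + c_ + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force F1-maximising threshold over every distinct score and
# midpoint candidate
oracle_best_f1 <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, u, (u[-1] + u[-length(u)]) / 2)))
  f1s <- vapply(cand, function(t) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  max(f1s)
}

# random connected-ish toy graph as an edge matrix
random_toy_edges <- function(n, p_edge = 0.4) {
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  if (!any(keep)) keep[sample.int(ncol(pairs), 1)] <- TRUE
  t(pairs[, keep, drop = FALSE])
}

# build a gene_graph from a plain edge matrix (nodes named V1..Vn);
# isolated nodes are dropped by construction, so tests compare on the
# nodes present
toy_gene_graph <- function(edges, score = 900) {
  build_gene_graph(tibble::tibble(
    gene_a = paste0("V", edges[, 1]),
    gene_b = paste0("V", edges[, 2]),
    combined_score = score
  ))
}

# map a gene_graph back to integer node ids of the V1..Vn naming
toy_node_ids <- function(graph) {
  as.integer(sub("^V", "", igraph::V(graph$graph)$name))
}
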