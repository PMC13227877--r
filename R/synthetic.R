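#' Specification for a planted-signal synthetic network
#'
#' Describes a scale-free (preferential-attachment) interaction network in
#' which a planted minority of "driver" genes receives extra
#' preferentially-attached edges, right-shifting their degree and
#' betweenness distributions by a controlled standardised effect size.
#'
#' @param n_nodes Number of genes (>= 100).
#' @param positive_fraction Planted driver fraction (default 0.044, the
#'   genome-wide driver prevalence).
#' @param attachment Edges added per node during preferential attachment
#'   (default 5, i.e. mean degree about 10).
#' @param boost Extra-edge multiplier for positives when no target effect
#'   is set; `boost = 1` disables the planted signal.
#' @param target_d Target standardised degree effect (Cohen's d) of
#'   positives versus background (default 1.0); set `NULL` to use `boost`
#'   directly without calibration.
#' @param seed RNG seed.
#' @return A `planted_spec` list.
#' @export
planted_network_spec <- function(n_nodes = 2000, positive_fraction = 0.044,
                                 attachment = 5, boost = 2, target_d = 1.0,
                                 seed = 1) {
  if (n_nodes < 100) abort("n_nodes must be >= 100")
  if (positive_fraction <= 0 || positive_fraction >= 0.5) {
    abort("positive_fraction must be in (0, 0.5)")
  }
  if (boost < 1) abort("boost must be >= 1")
  structure(
    list(n_nodes = n_nodes, positive_fraction = positive_fraction,
         attachment = attachment, boost = boost, target_d = target_d,
         seed = seed),
    class = "planted_spec"
  )
}

# add per-node counts of preferentially-attached extra edges to the
# planted positives; returns the augmented igraph
add_planted_edges <- function(base, positives, extra, seed) {
  if (all(extra == 0)) return(base)
  g <- base
  n <- igraph::vcount(g)
  with_seed(seed, {
    w_base <- igraph::degree(base)
    for (k in seq_along(positives)) {
      if (extra[k] == 0) next
      v <- positives[k]
      nbrs <- as.integer(igraph::neighbors(g, v))
      pool <- setdiff(seq_len(n), c(v, nbrs))
      if (length(pool) < extra[k]) {
        abort("boost exceeds simple-graph capacity")
      }
      pick <- sample(pool, extra[k], prob = w_base[pool] + 1)
      g <- igraph::add_edges(g, rbind(v, pick))
    }
  })
  g
}

#' Generate a planted-signal synthetic interaction network
#'
#' Builds an undirected preferential-attachment graph, plants a minority of
#' positives by granting each extra preferentially-attached edges (never
#' rewiring, so the scale-free tail is preserved), and calibrates the
#' per-positive extra-edge count by generate-and-measure iteration until
#' the standardised degree effect of positives versus background reaches
#' the target. Edge confidence scores are integers drawn uniformly in
#' \[700, 1000\] (the post-filter high-confidence regime). Deterministic
#' given the spec seed.
#'
#' @param spec A [planted_network_spec()].
#' @return A `planted_network` list: `edges` (tibble `gene_a`, `gene_b`,
#'   `combined_score`), `genes`, `positives`, `protein_ids` (named map
#'   gene -> prefixed protein id), `d_measured` (achieved degree effect),
#'   `boost_achieved` (calibrated extra-edge multiplier), `spec`.
#' @export
generate_planted_network <- function(spec = planted_network_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  n <- spec$n_nodes
  base <- with_seed(spec$seed, {
    igraph::sample_pa(n, power = 1, m = spec$attachment, directed = FALSE)
  })
  n_pos <- round_half_up(n * spec$positive_fraction)
  pos_idx <- with_seed(spec$seed + 1, sample.int(n, n_pos))

  measure_d <- function(g) {
    deg <- igraph::degree(g)
    cohens_d(n_pos, mean(deg[pos_idx]), sd(deg[pos_idx]),
             n - n_pos, mean(deg[-pos_idx]), sd(deg[-pos_idx]))
  }

  # each positive receives extra stubs in proportion to its own degree
  # (multiplier b), so the planted class keeps the scale-free tail shape
  base_deg <- igraph::degree(base)
  extras_for <- function(b) {
    pmax(0, round_half_up((b - 1) * base_deg[pos_idx]))
  }
  if (is.null(spec$target_d) || spec$boost == 1) {
    extra <- extras_for(spec$boost)
    g <- add_planted_edges(base, pos_idx, extra, spec$seed + 2)
    best <- list(g = g, boost = spec$boost,
                 d = if (all(extra == 0)) measure_d(base) else measure_d(g))
  } else {
    b <- max(spec$boost, 1.05)
    best <- NULL
    for (it in seq_len(10)) {
      g <- add_planted_edges(base, pos_idx, extras_for(b), spec$seed + 2)
      d_meas <- measure_d(g)
      if (is.null(best) ||
          abs(d_meas - spec$target_d) < abs(best$d - spec$target_d)) {
        best <- list(g = g, boost = b, d = d_meas)
      }
      if (abs(d_meas - spec$target_d) <= 0.1) break
      b <- 1 + (b - 1) * spec$target_d / max(d_meas, 0.05)
    }
  }
  g <- best$g

  genes <- sprintf(paste0("G%0", nchar(n), "d"), seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  scores <- with_seed(spec$seed + 3, {
    sample(700:1000, nrow(el), replace = TRUE)
  })
  edges <- tibble::tibble(
    gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
    combined_score = as.integer(scores)
  )
  protein_ids <- stats::setNames(
    sprintf(paste0("9606.ENSP%0", nchar(n) + 3, "d"), seq_len(n)), genes
  )
  structure(
    list(edges = edges, genes = genes, positives = genes[pos_idx],
         protein_ids = protein_ids, d_measured = best$d,
         boost_achieved = best$boost, spec = spec),
    class = "planted_network"
  )
}

#' @export
print.planted_network <- function(x, ...) {
  cat("<planted_network> ", length(x$genes), " genes, ", nrow(x$edges),
      " edges, ", length(x$positives), " planted positives (degree d = ",
      round(x$d_measured, 2), ")\n", sep = "")
  invisible(x)
}

#' Write a planted network as study input files
#'
#' Emits the exact file dialects the readers consume: a reciprocal-row
#' STRING-style edge list (`protein1 protein2 combined_score`, each
#' interaction listed in both directions, species-prefixed ids), a
#' two-column id-map TSV, and a one-symbol-per-line positive gene list.
#' Byte-identical output for the same object.
#'
#' @param net A `planted_network`.
#' @param dir Output directory (created if needed).
#' @return Named list of the written paths (`edges`, `idmap`, `positives`).
#' @export
write_fixture_files <- function(net, dir) {
  stopifnot(inherits(net, "planted_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pid <- net$protein_ids
  fwd <- paste(pid[net$edges$gene_a], pid[net$edges$gene_b],
               net$edges$combined_score)
  rev <- paste(pid[net$edges$gene_b], pid[net$edges$gene_a],
               net$edges$combined_score)
  paths <- list(
    edges = file.path(dir, "edges.txt"),
    idmap = file.path(dir, "idmap.tsv"),
    positives = file.path(dir, "positives.txt")
  )
  writeLines(c("protein1 protein2 combined_score",
               as.vector(rbind(fwd, rev))), paths$edges)
  writeLines(paste(unname(pid), names(pid), sep = "\t"), paths$idmap)
  writeLines(net$positives, paths$positives)
  paths
}

#' Convert a planted network to a gene graph
#'
#' Routes the generated edges through the same constructor as file input
#' (reciprocal rows included), so out- and in-degrees equal the undirected
#' degree.
#'
#' @param net A `planted_network`.
#' @return A `gene_graph`.
#' @export
as_gene_graph <- function(net) {
  stopifnot(inherits(net, "planted_network"))
  both <- dplyr::bind_rows(
    net$edges,
    tibble::tibble(gene_a = net$edges$gene_b, gene_b = net$edges$gene_a,
                   combined_score = net$edges$combined_score)
  )
  build_gene_graph(both)
}

#' Generate a score/label fixture with known AUC
#'
#' Two unit-variance Gaussians on the logit scale separated by
#' `separation`, mapped through the sigmoid; the expected ROC-AUC is
#' \eqn{\Phi(\mathrm{separation} / \sqrt{2})}.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param separation Mean separation on the logit scale.
#' @param seed RNG seed.
#' @return Tibble with columns `score` (in (0, 1)) and `label`.
#' @export
generate_score_fixture <- function(n_pos, n_neg, separation, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  with_seed(seed, {
    z <- c(rnorm(n_pos, separation / 2), rnorm(n_neg, -separation / 2))
    tibble::tibble(
      score = 1 / (1 + exp(-z)),
      label = c(rep(1L, n_pos), rep(0L, n_neg))
    )
  })
}

#' Split planted positives into training and held-out driver sets
#'
#' Emulates an externally discovered driver set: the held-out positives
#' keep label 0 during training and are used only for external validation.
#'
#' @param positives Character vector of planted positives, or a
#'   `planted_network`.
#' @param fraction Held-out fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with `train_positives` and `holdout_positives` (disjoint).
#' @export
generate_external_holdout <- function(positives, fraction = 0.2, seed = 1) {
  if (inherits(positives, "planted_network")) positives <- positives$positives
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (length(positives) < 10) abort("need at least 10 positives")
  n_hold <- round_half_up(length(positives) * fraction)
  hold <- with_seed(seed, sample(positives, n_hold))
  list(train_positives = setdiff(positives, hold),
       holdout_positives = hold)
}
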