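#' Hub outdegree threshold
#'
#' Mean plus two standard deviations of the outdegree distribution
#' (population SD), the conventional statistical cutoff for calling highly
#' connected hub genes.
#'
#' @param outdegrees Numeric vector of per-gene outdegrees (length >= 2).
#' @return List with `mu`, `sigma`, `threshold = mu + 2 sigma`.
#' @examples
#' hub_threshold(c(1, 2, 3, 4, 5))
#' @export
hub_threshold <- function(outdegrees) {
  if (length(outdegrees) < 2) abort("need at least 2 degree values")
  mu <- mean(outdegrees)
  sigma <- sqrt(mean((outdegrees - mu)^2))
  list(mu = mu, sigma = sigma, threshold = mu + 2 * sigma)
}

#' Identify hub genes
#'
#' Hubs are nodes whose outdegree strictly exceeds the mean + 2 SD
#' threshold. Cancer flags are attached from the label table when given.
#'
#' @param graph A `gene_graph`.
#' @param labels Optional labelled gene tibble from [assign_labels()].
#' @return A `hub_set`: tibble of hubs (`gene`, `outdegree`, `is_cancer`)
#'   with attributes `mu`, `sigma`, `threshold`, and `all_degrees` (the full
#'   per-gene degree/label table, needed for enrichment against non-hubs).
#' @export
identify_hubs <- function(graph, labels = NULL) {
  stopifnot(inherits(graph, "gene_graph"))
  deg <- degree_stats(graph)
  th <- hub_threshold(deg$outdegree)
  all_tbl <- deg
  if (!is.null(labels)) {
    all_tbl <- dplyr::left_join(all_tbl,
                                dplyr::select(labels, "gene", "label"),
                                by = "gene")
  } else {
    all_tbl$label <- NA_integer_
  }
  all_tbl$is_hub <- all_tbl$outdegree > th$threshold
  hubs <- all_tbl |>
    dplyr::filter(.data$is_hub) |>
    dplyr::transmute(
      gene = .data$gene, outdegree = .data$outdegree,
      is_cancer = .data$label == 1
    ) |>
    dplyr::arrange(dplyr::desc(.data$outdegree))
  out <- structure(hubs, class = c("hub_set", class(hubs)))
  attr(out, "mu") <- th$mu
  attr(out, "sigma") <- th$sigma
  attr(out, "threshold") <- th$threshold
  attr(out, "all_degrees") <- all_tbl
  ianet_log("identify_hubs: ", nrow(hubs), " hubs of ", nrow(all_tbl),
            " genes (threshold ", round(th$threshold, 1), ")")
  out
}

#' @export
print.hub_set <- function(x, ...) {
  cat("<hub_set> ", nrow(x), " hubs; threshold = mu + 2 sigma = ",
      round(attr(x, "threshold"), 2), "\n", sep = "")
  NextMethod()
}

#' Tidy a hub set
#' @param x A `hub_set`.
#' @param ... Unused.
#' @return The hub tibble without the class decoration.
#' @export
#' @exportS3Method generics::tidy
tidy.hub_set <- function(x, ...) {
  tibble::as_tibble(unclass_keep(x))
}

#' One-row hub-set summary
#' @param x A `hub_set`.
#' @param ... Unused.
#' @return Tibble with `mu`, `sigma`, `threshold`, `n_hubs`,
#'   `n_cancer_hubs`.
#' @export
#' @exportS3Method generics::glance
glance.hub_set <- function(x, ...) {
  tibble::tibble(
    mu = attr(x, "mu"), sigma = attr(x, "sigma"),
    threshold = attr(x, "threshold"), n_hubs = nrow(x),
    n_cancer_hubs = sum(x$is_cancer, na.rm = TRUE)
  )
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("hub_set"))
  x
}

#' Ego network of a gene
#'
#' The subgraph induced by a centre gene, its direct neighbours and all
#' connecting edges. Density is \eqn{2E / (V(V-1))} on the undirected
#' induced subgraph including the centre. The driver fraction among all
#' neighbours and among the top-k neighbours by edge confidence are
#' reported separately.
#'
#' @param graph A `gene_graph`.
#' @param centre Centre gene symbol (must be a node).
#' @param labels Optional labelled gene tibble.
#' @param top_k Number of highest-confidence partners to summarise
#'   (default 15).
#' @param min_score Optional extra confidence filter on the incident edges
#'   used to pick the top-k partners.
#' @return An `ego_network` list: `centre`, `neighbours` (tibble with
#'   `gene`, `score`, `is_cancer`), `n_nodes`, `n_edges`, `density`,
#'   `cancer_fraction`, `top_k_cancer_fraction`.
#' @export
ego_network <- function(graph, centre, labels = NULL, top_k = 15,
                        min_score = NULL) {
  stopifnot(inherits(graph, "gene_graph"))
  g <- graph$graph
  if (!centre %in% igraph::V(g)$name) {
    abort(paste0("centre gene not in graph: ", centre))
  }
  vc <- which(igraph::V(g)$name == centre)
  nb <- igraph::neighbors(g, vc)
  inc <- igraph::incident(g, vc)
  scores <- igraph::edge_attr(g, "score", inc)
  if (is.null(scores)) scores <- rep(NA_real_, length(inc))
  nb_tbl <- tibble::tibble(gene = nb$name, score = as.numeric(scores))
  if (!is.null(labels)) {
    nb_tbl <- dplyr::left_join(nb_tbl,
                               dplyr::select(labels, "gene", "label"),
                               by = "gene") |>
      dplyr::mutate(is_cancer = .data$label == 1, label = NULL)
  } else {
    nb_tbl$is_cancer <- NA
  }
  nb_tbl <- dplyr::arrange(nb_tbl, dplyr::desc(.data$score))

  sub <- igraph::induced_subgraph(g, c(vc, as.integer(nb)))
  v_n <- igraph::vcount(sub)
  e_n <- igraph::ecount(sub)
  density <- if (v_n < 2) 0 else 2 * e_n / (v_n * (v_n - 1))

  top_tbl <- nb_tbl
  if (!is.null(min_score)) {
    top_tbl <- dplyr::filter(top_tbl, .data$score >= min_score)
  }
  top_tbl <- head(top_tbl, top_k)

  structure(
    list(
      centre = centre, neighbours = nb_tbl,
      n_nodes = v_n, n_edges = e_n, density = density,
      cancer_fraction = mean(nb_tbl$is_cancer),
      top_k_cancer_fraction = if (nrow(top_tbl)) mean(top_tbl$is_cancer)
                              else NA_real_
    ),
    class = "ego_network"
  )
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> centre ", x$centre, ": ", nrow(x$neighbours),
      " neighbours, density ", round(x$density, 3),
      ", driver fraction ", round(x$cancer_fraction, 3), "\n", sep = "")
  invisible(x)
}

#' Compare cancer and non-cancer hubs
#'
#' Per-metric Mann-Whitney comparisons (with Cohen's d) of cancer versus
#' non-cancer hubs across the supplied topology features, plus the
#' hub-versus-non-hub driver enrichment 2x2 test, all under a single
#' Bonferroni family.
#'
#' @param hubset A `hub_set` built with labels.
#' @param features Feature table from [extract_features()] (used for the
#'   per-metric comparisons; metrics = intersection of its feature columns
#'   with `metrics`).
#' @param metrics Character vector of feature columns to compare.
#' @param family_m Bonferroni family size (default 45, the hub-analysis
#'   family).
#' @return List with `comparisons` (tibble, one row per metric) and
#'   `enrichment` (an `enrichment_result` for hubs vs non-hubs).
#' @export
compare_hub_groups <- function(hubset, features,
                               metrics = c("degree", "betweenness",
                                           "pagerank"),
                               family_m = 45) {
  stopifnot(inherits(hubset, "hub_set"))
  all_deg <- attr(hubset, "all_degrees")
  if (all(is.na(hubset$is_cancer))) abort("hub set carries no labels")
  if (!any(hubset$is_cancer) || all(hubset$is_cancer)) {
    abort("both cancer and non-cancer hubs are required")
  }
  hub_feats <- dplyr::inner_join(
    dplyr::select(features, dplyr::all_of(c("gene", intersect(metrics,
                                                              names(features))))),
    dplyr::select(hubset, "gene", "is_cancer"), by = "gene"
  )
  metrics <- intersect(metrics, names(hub_feats))
  comparisons <- purrr::map_dfr(metrics, function(mm) {
    res <- mann_whitney(hub_feats[[mm]][hub_feats$is_cancer],
                        hub_feats[[mm]][!hub_feats$is_cancer])
    dplyr::bind_cols(tibble::tibble(metric = mm), res)
  })
  comparisons$family <- "hub"
  comparisons$m <- family_m
  comparisons$corrected_alpha <- bonferroni_alpha(0.05, family_m)

  a <- sum(all_deg$is_hub & all_deg$label == 1, na.rm = TRUE)
  b <- sum(all_deg$is_hub & all_deg$label == 0, na.rm = TRUE)
  c_ <- sum(!all_deg$is_hub & all_deg$label == 1, na.rm = TRUE)
  d <- sum(!all_deg$is_hub & all_deg$label == 0, na.rm = TRUE)
  enrichment <- odds_ratio_ci(a, b, c_, d, family = "hub", m = family_m)

  list(comparisons = comparisons, enrichment = enrichment)
}
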