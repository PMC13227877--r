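#' Run the full driver-gene identification pipeline
#'
#' End-to-end orchestration: read and confidence-filter the edge list, map
#' identifiers to symbols, build the graph, assign labels, extract the
#' eight topology features, train the imbalance-aware ensemble, identify
#' hubs and their enrichment, and (optionally) run external-set evaluation
#' and pathway enrichment. Stage counts are logged and every report is
#' written under `out_dir` together with a manifest recording seeds and
#' settings; reruns with the same inputs and seeds reproduce the outputs.
#'
#' @param edges_file STRING-style edge list path.
#' @param idmap_file Protein-to-symbol TSV path.
#' @param positives_file Positive (driver) gene list path.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @param confidence Combined-score threshold (default 700).
#' @param spec A [split_spec()].
#' @param configs Learner configurations from [default_configs()].
#' @param target_prior Resampling target positive rate.
#' @param settings Feature-extraction settings from [feature_settings()].
#' @param external_file Optional external validation gene list path.
#' @param gmt_file Optional GMT pathway file for hub enrichment.
#' @return Invisibly, a list with `graph`, `labels`, `features`, `model`,
#'   `hubs`, `hub_stats`, and (when requested) `external`, `pathways`.
#' @export
run_iani_pipeline <- function(edges_file, idmap_file, positives_file,
                              out_dir = NULL, confidence = 700,
                              spec = split_spec(),
                              configs = default_configs(),
                              target_prior = 0.15,
                              settings = feature_settings(),
                              external_file = NULL, gmt_file = NULL) {
  for (f in c(edges_file, idmap_file, positives_file)) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  records <- read_interactions(edges_file)
  kept <- filter_confidence(records, confidence)
  idmap <- read_id_map(idmap_file)
  mapped <- map_to_symbols(kept, idmap)
  graph <- build_gene_graph(mapped)
  labels <- assign_labels(graph, read_gene_list(positives_file))
  features <- extract_features(graph, labels, settings)
  model <- train_iani_ensemble(features, spec = spec, configs = configs,
                               target_prior = target_prior)
  audit_leakage(model)
  hubs <- identify_hubs(graph, labels)
  hub_stats <- compare_hub_groups(hubs, features)

  out <- list(graph = graph, labels = labels, features = features,
              model = model, hubs = hubs, hub_stats = hub_stats)

  if (!is.null(external_file)) {
    ext <- build_external_set(read_gene_list(external_file),
                              exclusions = labels$gene[labels$label == 1],
                              network_nodes = labels$gene)
    scores <- tibble::tibble(
      gene = features$gene,
      score = predict(model, features)
    )
    out$external <- external_validate(
      scores, ext$genes,
      background_genes = setdiff(labels$gene, ext$genes),
      tau = model$tau, features = features
    )
  }
  if (!is.null(gmt_file)) {
    out$pathways <- gene_set_enrichment(hubs$gene, read_gmt(gmt_file),
                                        universe = labels$gene)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(model$test_predictions,
                     file.path(out_dir, "predictions.csv"))
    readr::write_csv(tibble::as_tibble(model$metrics),
                     file.path(out_dir, "metrics.csv"))
    readr::write_csv(tidy(hubs), file.path(out_dir, "hubs.csv"))
    readr::write_csv(hub_stats$comparisons,
                     file.path(out_dir, "hub_comparisons.csv"))
    manifest <- list(
      inputs = list(edges = edges_file, idmap = idmap_file,
                    positives = positives_file),
      confidence = confidence,
      seeds = spec[c("seed_split", "seed_smote", "seed_under", "seed_cv")],
      target_prior = target_prior,
      weights = as.list(model$weights), tau = model$tau,
      n_nodes = graph$n_nodes, n_edges = graph$n_edges,
      n_positives = attr(labels, "n_pos"),
      hub_threshold = attr(hubs, "threshold"), n_hubs = nrow(hubs)
    )
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  invisible(out)
}
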