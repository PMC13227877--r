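# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# reduced learner configurations for fast module-level runs
fast_configs <- function(seed = 1) {
  cfg <- default_configs(seed)
  cfg$random_forest$num_trees <- 150
  cfg$gradient_boosting$nrounds <- 80
  cfg$neural_net <- nn_config(layers = c(32, 16), dropout = c(0.2, 0.2),
                              epochs = 15, patience = 5, seed = seed)
  cfg
}

# small planted study (fast; used by module tests)
small_planted <- function() {
  memo("small_planted", function() {
    net <- generate_planted_network(planted_network_spec(
      n_nodes = 600, positive_fraction = 0.05, target_d = 1.0, seed = 7
    ))
    graph <- as_gene_graph(net)
    labels <- assign_labels(graph, net$positives)
    features <- extract_features(graph, labels)
    list(net = net, graph = graph, labels = labels, features = features)
  })
}

# full-scale planted study under the documented conditions
# (2000 genes, 5% planted positives, degree effect ~ 1, fixed seeds);
# both the imbalance-aware model and the uncorrected baseline are fitted
# on the same feature table
planted_study <- function() {
  memo("planted_study", function() {
    net <- generate_planted_network(planted_network_spec(
      n_nodes = 2000, positive_fraction = 0.05, target_d = 1.0, seed = 7
    ))
    graph <- as_gene_graph(net)
    labels <- assign_labels(graph, net$positives)
    features <- extract_features(graph, labels)
    model <- train_iani_ensemble(features)
    baseline <- train_iani_ensemble(features, resample = FALSE,
                                    use_class_weights = FALSE,
                                    optimise_weights = FALSE,
                                    optimise_tau = FALSE)
    list(net = net, graph = graph, labels = labels, features = features,
         model = model, baseline = baseline)
  })
}

# matched no-signal network (planted boost disabled, otherwise identical)
null_planted_network <- function() {
  memo("null_planted_network", function() {
    net <- generate_planted_network(planted_network_spec(
      n_nodes = 2000, positive_fraction = 0.05, boost = 1, target_d = NULL,
      seed = 7
    ))
    graph <- as_gene_graph(net)
    labels <- assign_labels(graph, net$positives)
    list(net = net, graph = graph, labels = labels)
  })
}
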