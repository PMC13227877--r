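#' Weighted soft voting
#'
#' Convex combination of per-model probabilities,
#' \eqn{P_{ens}(y=1|x) = \sum_i w_i P_i(y=1|x)}.
#'
#' @param per_model_probs Matrix or data frame, one column per model.
#' @param weights Nonnegative weights summing to 1, one per model.
#' @return Numeric vector of ensemble probabilities.
#' @examples
#' soft_vote(cbind(0.9, 0.8, 0.7, 0.6), c(0.15, 0.25, 0.30, 0.30))
#' @export
soft_vote <- function(per_model_probs, weights) {
  p <- as.matrix(per_model_probs)
  if (ncol(p) != length(weights)) {
    abort("one weight per model is required")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be nonnegative and sum to 1")
  }
  as.numeric(p %*% weights)
}

# F1 at each candidate threshold (predict positive when score >= tau).
# Candidates are midpoints of adjacent sorted unique scores plus 0 and 1,
# so no candidate (except the endpoints) ties with a score.
f1_scan <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  sp <- sort(scores[labels == 1])
  sn <- sort(scores[labels == 0])
  n1 <- length(sp)
  n0 <- length(sn)
  tp <- n1 - findInterval(cand, sp)
  fp <- n0 - findInterval(cand, sn)
  # endpoints: ">= 0" keeps everything; ">= 1" keeps exact ones
  tp[cand == 0] <- n1
  fp[cand == 0] <- n0
  tp[cand == 1] <- sum(sp >= 1)
  fp[cand == 1] <- sum(sn >= 1)
  fn <- n1 - tp
  f1 <- ifelse(tp + fp == 0 | tp == 0, 0, 2 * tp / (2 * tp + fp + fn))
  list(cand = cand, f1 = f1)
}

#' F1-optimal decision threshold
#'
#' Scans candidate thresholds (midpoints of adjacent sorted unique scores,
#' plus 0 and 1) and returns the smallest candidate achieving maximal F1 —
#' the tie-break favours recall, correcting the systematic sensitivity loss
#' of a default 0.5 cut under severe class imbalance.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels (both classes required).
#' @return The threshold tau (scalar); attribute `f1` holds the achieved F1.
#' @export
optimise_threshold <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2) abort("both classes must be present")
  sc <- f1_scan(scores, labels)
  best <- max(sc$f1)
  tau <- min(sc$cand[sc$f1 >= best - 1e-12])
  attr(tau, "f1") <- best
  tau
}

#' Classification metrics at a threshold
#'
#' Confusion counts at `tau` (predict positive when `score >= tau`),
#' precision, recall, F1 (harmonic mean of the two), specificity and
#' balanced accuracy, plus threshold-free ROC-AUC (rank statistic,
#' tie-aware) and AUPRC (step-interpolated precision-recall integration,
#' the appropriate summary under class imbalance; equals the prevalence for
#' an uninformative scorer).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; at least one positive required.
#' @param tau Decision threshold (default 0.5).
#' @return A one-row `iani_metrics` tibble with columns `tau`, `tp`, `fp`,
#'   `tn`, `fn`, `precision`, `recall`, `specificity`, `f1`,
#'   `balanced_accuracy`, `roc_auc`, `auprc`; ROC and PR curve coordinates
#'   are attached as attributes `roc_curve` and `pr_curve`.
#' @export
evaluate_scores <- function(scores, labels, tau = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0) abort("no positives: recall undefined")
  pred <- as.integer(scores >= tau)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  specificity <- if (n0 == 0) NA_real_ else tn / (tn + fp)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }

  # ROC-AUC as the rank (Mann-Whitney) statistic, ties averaged
  r <- rank(scores)
  roc_auc <- if (n0 == 0) NA_real_ else {
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }

  # step-wise PR integration over distinct-score thresholds
  ord <- order(scores, decreasing = TRUE)
  y_ord <- labels[ord]
  s_ord <- scores[ord]
  grp_last <- cumsum(rle(s_ord)$lengths)
  cum_tp <- cumsum(y_ord)[grp_last]
  cum_fp <- cumsum(1 - y_ord)[grp_last]
  prec_i <- cum_tp / (cum_tp + cum_fp)
  rec_i <- cum_tp / n1
  auprc <- sum(diff(c(0, rec_i)) * prec_i)

  out <- tibble::tibble(
    tau = as.numeric(tau), tp = tp, fp = fp, tn = tn, fn = fn,
    precision = precision, recall = recall, specificity = specificity,
    f1 = f1,
    balanced_accuracy = (recall + specificity) / 2,
    roc_auc = roc_auc, auprc = auprc
  )
  attr(out, "roc_curve") <- tibble::tibble(
    fpr = c(0, cum_fp / n0), tpr = c(0, cum_tp / n1)
  )
  attr(out, "pr_curve") <- tibble::tibble(recall = rec_i, precision = prec_i)
  class(out) <- c("iani_metrics", class(out))
  out
}

# Simplex grid of voting weights with the given step.
weight_grid <- function(n_models = 4, step = 0.05) {
  k <- round(1 / step)
  grids <- expand.grid(rep(list(0:k), n_models - 1))
  keep <- rowSums(grids) <= k
  grids <- as.matrix(grids[keep, , drop = FALSE])
  cbind(grids, k - rowSums(grids)) / k
}

#' Default base-learner configurations
#'
#' Final hyperparameter values of the four base learners (ridge logistic
#' C = 0.1; forest of 500 depth-20 trees; 300 boosting rounds at learning
#' rate 0.05, depth 6, subsample 0.8; network 128-64-32-16 with focal loss).
#'
#' @param seed Base seed propagated to the stochastic learners.
#' @return Named list of per-learner config lists.
#' @export
default_configs <- function(seed = 1) {
  list(
    logistic = list(C = 0.1),
    random_forest = list(num_trees = 500, max_depth = 20,
                         min_node_size = 2, seed = seed),
    gradient_boosting = list(nrounds = 300, eta = 0.05, max_depth = 6,
                             subsample = 0.8, colsample = 0.8, seed = seed),
    neural_net = nn_config(seed = seed)
  )
}

train_four_learners <- function(data, configs, weights, fold_seed = 0) {
  cfg <- configs
  for (nm in c("random_forest", "gradient_boosting", "neural_net")) {
    cfg[[nm]]$seed <- (cfg[[nm]]$seed %||% 1) + fold_seed
  }
  list(
    logistic = train_logistic(data, cfg$logistic, weights),
    random_forest = train_random_forest(data, cfg$random_forest, weights),
    gradient_boosting = train_gradient_boosting(data, cfg$gradient_boosting,
                                                weights),
    neural_net = train_neural_net(data, cfg$neural_net)
  )
}

predict_four <- function(learners, newdata) {
  vapply(learners, function(l) predict(l, newdata),
         numeric(nrow(newdata)))
}

#' Train the imbalance-aware ensemble
#'
#' The full pipeline: leak-free stratified split; per-fold rebalancing
#' (SMOTE + LHS undersampling, applied to the fit partition of each
#' cross-validation fold only, validation folds untouched); class-weighted
#' training of the four base learners; voting-weight grid search over the
#' simplex maximising F1 on pooled CV-validation predictions; F1-optimal
#' threshold fitted on the same pooled predictions (never on the test set);
#' final learners refitted on the rebalanced full training partition; a
#' single evaluation on the untouched test set.
#'
#' Setting `resample`, `use_class_weights`, `optimise_weights` and
#' `optimise_tau` all to `FALSE` gives the uncorrected baseline (original
#' imbalance, plain losses, equal voting weights, tau = 0.5).
#'
#' @param features Feature table from [extract_features()].
#' @param spec A [split_spec()].
#' @param configs Learner configurations from [default_configs()].
#' @param target_prior Resampling target positive rate (default 0.15).
#' @param k Cross-validation folds (default 5).
#' @param resample Apply SMOTE + LHS rebalancing (default `TRUE`).
#' @param use_class_weights Apply balanced class weights and focal loss
#'   (default `TRUE`); when `FALSE` the network trains with plain
#'   cross-entropy (`gamma = 0, alpha = 0.5`).
#' @param optimise_weights Grid-search voting weights (default `TRUE`);
#'   otherwise equal weights.
#' @param optimise_tau Fit the F1-optimal threshold (default `TRUE`);
#'   otherwise tau = 0.5.
#' @param weight_step Simplex grid step for the weight search.
#' @return An `iani_ensemble` object with elements `learners`, `weights`,
#'   `tau`, `metrics` (test-set [evaluate_scores()] report),
#'   `test_predictions`, `cv_predictions`, and `provenance` (gene sets used
#'   at each stage, for the leak audit).
#' @export
train_iani_ensemble <- function(features, spec = split_spec(),
                                configs = default_configs(),
                                target_prior = 0.15, k = 5,
                                resample = TRUE, use_class_weights = TRUE,
                                optimise_weights = TRUE,
                                optimise_tau = TRUE, weight_step = 0.05) {
  stopifnot(is.data.frame(features), "label" %in% names(features))
  if (!use_class_weights) {
    configs$neural_net$gamma <- 0
    configs$neural_net$alpha <- 0.5
  }
  parts <- stratified_split(features, spec)
  train <- parts$train
  test <- parts$test
  folds <- cv_folds(train, k = k, spec = spec)

  fold_spec <- function(f) {
    split_spec(
      test_fraction = spec$test_fraction, seed_split = spec$seed_split,
      seed_smote = spec$seed_smote + f, seed_under = spec$seed_under + f,
      seed_cv = spec$seed_cv
    )
  }

  cv_pred <- vector("list", k)
  fold_fit_genes <- vector("list", k)
  fold_resampled_genes <- vector("list", k)
  for (f in seq_len(k)) {
    fit_part <- train[folds[[f]]$fit, , drop = FALSE]
    val_part <- train[folds[[f]]$validate, , drop = FALSE]
    rs <- if (resample) {
      rebalance(fit_part, target_prior = target_prior, spec = fold_spec(f))
    } else {
      dplyr::mutate(fit_part, provenance = "original")
    }
    cw <- if (use_class_weights) class_weights(rs$label) else NULL
    learners <- train_four_learners(rs, configs, cw, fold_seed = f)
    probs <- predict_four(learners, val_part)
    cv_pred[[f]] <- tibble::tibble(
      gene = val_part$gene, fold = f,
      p_logistic = probs[, "logistic"],
      p_random_forest = probs[, "random_forest"],
      p_gradient_boosting = probs[, "gradient_boosting"],
      p_neural_net = probs[, "neural_net"],
      label = val_part$label
    )
    fold_fit_genes[[f]] <- fit_part$gene
    fold_resampled_genes[[f]] <- rs$gene[!is.na(rs$gene)]
  }
  cv_pred <- dplyr::bind_rows(cv_pred)
  p_mat <- as.matrix(cv_pred[paste0("p_", names(configs))])

  if (optimise_weights) {
    grid <- weight_grid(ncol(p_mat), weight_step)
    f1_of <- apply(grid, 1, function(w) {
      max(f1_scan(as.numeric(p_mat %*% w), cv_pred$label)$f1)
    })
    w <- grid[which.max(f1_of), ]
  } else {
    w <- rep(1 / ncol(p_mat), ncol(p_mat))
  }
  names(w) <- names(configs)

  cv_scores <- soft_vote(p_mat, w)
  tau <- if (optimise_tau) {
    as.numeric(optimise_threshold(cv_scores, cv_pred$label))
  } else {
    0.5
  }

  rs_full <- if (resample) {
    rebalance(train, target_prior = target_prior, spec = spec)
  } else {
    dplyr::mutate(train, provenance = "original")
  }
  cw_full <- if (use_class_weights) class_weights(rs_full$label) else NULL
  learners <- train_four_learners(rs_full, configs, cw_full, fold_seed = 0)

  probs_test <- predict_four(learners, test)
  scores_test <- soft_vote(probs_test, w)
  metrics <- evaluate_scores(scores_test, test$label, tau)

  test_predictions <- tibble::tibble(
    gene = test$gene,
    p_logistic = probs_test[, "logistic"],
    p_random_forest = probs_test[, "random_forest"],
    p_gradient_boosting = probs_test[, "gradient_boosting"],
    p_neural_net = probs_test[, "neural_net"],
    p_ensemble = scores_test,
    label = test$label,
    label_pred = as.integer(scores_test >= tau)
  )

  structure(
    list(
      learners = learners, weights = w, tau = tau, metrics = metrics,
      test_predictions = test_predictions, cv_predictions = cv_pred,
      spec = spec, target_prior = target_prior,
      provenance = list(
        train_genes = train$gene, test_genes = test$gene,
        final_resampled_genes = rs_full$gene[!is.na(rs_full$gene)],
        fold_fit_genes = fold_fit_genes,
        fold_resampled_genes = fold_resampled_genes,
        resampled_provenance = table(rs_full$provenance),
        pi_resampled = attr(rs_full, "pi_resampled") %||%
          mean(rs_full$label == 1)
      )
    ),
    class = "iani_ensemble"
  )
}

#' @export
print.iani_ensemble <- function(x, ...) {
  cat("<iani_ensemble> weights:",
      paste(names(x$weights), round(x$weights, 2), sep = "=",
            collapse = ", "),
      "\n  tau =", round(x$tau, 3),
      "| test ROC-AUC =", round(x$metrics$roc_auc, 3),
      "recall =", round(x$metrics$recall, 3),
      "precision =", round(x$metrics$precision, 3), "\n")
  invisible(x)
}

#' Predict ensemble driver probabilities for new genes
#'
#' @param object An `iani_ensemble`.
#' @param newdata Feature table (columns as in [extract_features()]).
#' @param type `"prob"` for the soft-vote probability, `"class"` for the
#'   0/1 call at the fitted threshold.
#' @param ... Unused.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict.iani_ensemble <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  probs <- predict_four(object$learners, newdata)
  p <- soft_vote(probs, object$weights)
  if (type == "prob") p else as.integer(p >= object$tau)
}

#' Audit the pipeline for test-set leakage
#'
#' Verifies from recorded provenance that no test-set gene entered any
#' resampled training set or any cross-validation fit partition.
#'
#' @param model An `iani_ensemble`.
#' @return `TRUE` invisibly if clean; otherwise an error describing the
#'   leaked genes.
#' @export
audit_leakage <- function(model) {
  stopifnot(inherits(model, "iani_ensemble"))
  pv <- model$provenance
  leaks <- c(
    intersect(pv$test_genes, pv$final_resampled_genes),
    intersect(pv$test_genes, unlist(pv$fold_fit_genes)),
    intersect(pv$test_genes, unlist(pv$fold_resampled_genes))
  )
  if (length(leaks) > 0) {
    abort(paste0("test-set leakage detected: ",
                 paste(unique(leaks), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ensemble: one row per base learner
#'
#' @param x An `iani_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `learner` and `weight`.
#' @export
#' @exportS3Method generics::tidy
tidy.iani_ensemble <- function(x, ...) {
  tibble::tibble(learner = names(x$weights), weight = unname(x$weights))
}

#' One-row ensemble summary (threshold + test metrics)
#'
#' @param x An `iani_ensemble`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
#' @exportS3Method generics::glance
glance.iani_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(tau = x$tau),
    dplyr::select(tibble::as_tibble(x$metrics), -"tau")
  )
}
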