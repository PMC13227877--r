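#' Focal loss
#'
#' Mean over samples of \eqn{-\alpha_t (1 - p_t)^\gamma \log p_t}, with
#' \eqn{p_t = p} for positives and \eqn{1 - p} for negatives, and
#' \eqn{\alpha_t = \alpha} for positives, \eqn{1 - \alpha} for negatives.
#' With \eqn{\gamma = 0, \alpha = 0.5} this is exactly half the binary
#' cross-entropy. Down-weights confidently classified examples so learning
#' concentrates on hard minority cases.
#'
#' @param p_pred Predicted positive-class probabilities in (0, 1);
#'   values outside are clipped to \[1e-7, 1 - 1e-7\] with a warning.
#' @param y 0/1 labels.
#' @param alpha Positive-class balancing weight (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @return Mean focal loss (scalar).
#' @examples
#' focal_loss(0.5, 1) # 0.25 * 0.25 * log(2)
#' @export
focal_loss <- function(p_pred, y, alpha = 0.25, gamma = 2) {
  stopifnot(length(p_pred) == length(y))
  if (any(p_pred <= 0 | p_pred >= 1)) {
    warn("probabilities clipped to (1e-7, 1 - 1e-7)")
    p_pred <- pmin(pmax(p_pred, 1e-7), 1 - 1e-7)
  }
  p_t <- ifelse(y == 1, p_pred, 1 - p_pred)
  a_t <- ifelse(y == 1, alpha, 1 - alpha)
  mean(-a_t * (1 - p_t)^gamma * log(p_t))
}

# ---- learner container ------------------------------------------------

new_learner <- function(kind, fit, center, scale, cols, config) {
  structure(
    list(kind = kind, fit = fit, center = center, scale = scale,
         cols = cols, config = config),
    class = "iani_learner"
  )
}

#' @export
print.iani_learner <- function(x, ...) {
  cat("<iani_learner:", x$kind, "> trained on",
      length(x$cols), "features\n")
  invisible(x)
}

learner_matrix <- function(data, cols) {
  as.matrix(data[cols])
}

row_weights <- function(labels, weights) {
  if (is.null(weights)) return(rep(1, length(labels)))
  if (length(weights) == length(labels)) return(as.numeric(weights))
  w <- c(neg = unname(weights[[1]]), pos = unname(weights[[2]]))
  if (!is.null(names(weights)) && all(c("neg", "pos") %in% names(weights))) {
    w <- weights[c("neg", "pos")]
  }
  ifelse(labels == 1, w[["pos"]], w[["neg"]])
}

resolve_cols <- function(data) {
  cols <- intersect(feature_cols(), names(data))
  if (length(cols) == 0) {
    cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                    c("label"))
  }
  cols
}

#' Train the L2-penalised logistic regression base learner
#'
#' Models the log-odds of driver membership as a linear combination of the
#' (internally standardised) topology features,
#' \eqn{P(y=1|x) = 1 / (1 + e^{-(\beta_0 + \beta^T x)})}, with ridge
#' penalty strength `1 / (C n)` (inverse-regularisation convention,
#' default C = 0.1).
#'
#' @param data Training table with feature columns and `label`.
#' @param config List; supports `C`.
#' @param weights Class weights from [class_weights()], per-row weights, or
#'   `NULL`.
#' @return An `iani_learner` of kind `"logistic"`.
#' @export
train_logistic <- function(data, config = list(), weights = NULL) {
  cols <- resolve_cols(data)
  y <- data$label
  if (length(unique(y)) < 2) abort("both classes must be present")
  x <- learner_matrix(data, cols)
  if (any(!is.finite(x))) abort("non-finite feature values")
  cc <- config$C %||% 0.1
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  if (ncol(xs) == 1) xs <- cbind(xs, `.dummy` = 0) # glmnet needs >= 2 columns
  w <- row_weights(y, weights)
  fit <- glmnet::glmnet(
    xs, factor(y, levels = c(0, 1)), family = "binomial", alpha = 0,
    lambda = 1 / (cc * nrow(xs)), weights = w, standardize = FALSE
  )
  new_learner("logistic", fit, center, scl, cols, list(C = cc))
}

#' Train the random forest base learner
#'
#' Probability forest (class-vote fraction); defaults: 500 trees, maximum
#' depth 20, minimum node size 2, `sqrt(p)` candidate features per split.
#' Single-threaded and seeded for reproducibility.
#'
#' @inheritParams train_logistic
#' @param config List; supports `num_trees`, `max_depth`, `min_node_size`,
#'   `seed`.
#' @return An `iani_learner` of kind `"random_forest"`.
#' @export
train_random_forest <- function(data, config = list(), weights = NULL) {
  cols <- resolve_cols(data)
  y <- data$label
  if (nrow(data) == 0) abort("empty training data")
  if (length(unique(y)) < 2) abort("both classes must be present")
  df <- data.frame(learner_matrix(data, cols))
  df$.label <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = config$num_trees %||% 500,
    max.depth = config$max_depth %||% 20,
    min.node.size = config$min_node_size %||% 2,
    mtry = max(1, floor(sqrt(length(cols)))),
    case.weights = row_weights(y, weights),
    seed = config$seed %||% 1, num.threads = 1,
    verbose = FALSE, importance = "impurity"
  )
  new_learner("random_forest", fit, NULL, NULL, cols, config)
}

#' Train the gradient boosting base learner
#'
#' Sequential trees correcting previous errors,
#' \eqn{F_m(x) = F_{m-1}(x) + \nu h_m(x)}; defaults: 300 rounds, learning
#' rate 0.05, depth 6, row subsample 0.8, column subsample 0.8. Staged
#' predictions are available through `predict(..., nrounds = m)` for the
#' additive-recursion check. If `valid` is supplied, early stopping
#' (default patience 20 rounds) monitors its loss.
#'
#' @inheritParams train_logistic
#' @param config List; supports `nrounds`, `eta`, `max_depth`, `subsample`,
#'   `colsample`, `early_stopping`, `seed`.
#' @param valid Optional validation table (same columns) for early stopping.
#' @return An `iani_learner` of kind `"gradient_boosting"`.
#' @export
train_gradient_boosting <- function(data, config = list(), weights = NULL,
                                    valid = NULL) {
  cols <- resolve_cols(data)
  y <- data$label
  if (nrow(data) == 0) abort("empty training data")
  if (length(unique(y)) < 2) abort("both classes must be present")
  dtrain <- xgboost::xgb.DMatrix(
    learner_matrix(data, cols), label = y,
    weight = row_weights(y, weights)
  )
  params <- list(
    objective = "binary:logistic",
    eta = config$eta %||% 0.05,
    max_depth = config$max_depth %||% 6,
    subsample = config$subsample %||% 0.8,
    colsample_bytree = config$colsample %||% 0.8,
    nthread = 1,
    seed = config$seed %||% 1
  )
  args <- list(params = params, data = dtrain,
               nrounds = config$nrounds %||% 300, verbose = 0)
  if (!is.null(valid)) {
    dvalid <- xgboost::xgb.DMatrix(learner_matrix(valid, cols),
                                   label = valid$label)
    args$evals <- list(valid = dvalid)
    args$early_stopping_rounds <- config$early_stopping %||% 20
  }
  fit <- do.call(xgboost::xgb.train, args)
  new_learner("gradient_boosting", fit, NULL, NULL, cols, config)
}

# ---- focal-loss neural network ----------------------------------------

#' Neural network configuration
#'
#' @param layers Hidden layer widths (default `c(128, 64, 32, 16)`).
#' @param dropout Per-hidden-layer dropout rates
#'   (default `c(0.3, 0.3, 0.2, 0.2)`).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Training epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param alpha,gamma Focal-loss parameters (defaults 0.25 and 2).
#' @param seed RNG seed covering initialisation, shuffling and dropout.
#' @return A list of settings for [train_neural_net()].
#' @export
nn_config <- function(layers = c(128, 64, 32, 16),
                      dropout = c(0.3, 0.3, 0.2, 0.2), lr = 0.001,
                      batch_size = 64, epochs = 50, patience = 10,
                      alpha = 0.25, gamma = 2, seed = 1) {
  list(layers = layers, dropout = dropout, lr = lr,
       batch_size = batch_size, epochs = epochs, patience = patience,
       alpha = alpha, gamma = gamma, seed = seed)
}

mlp_init <- function(n_in, layers) {
  sizes <- c(n_in, layers, 1)
  params <- list(W = vector("list", length(sizes) - 1),
                 b = vector("list", length(sizes) - 1))
  for (l in seq_len(length(sizes) - 1)) {
    # He initialisation for ReLU layers
    params$W[[l]] <- matrix(
      rnorm(sizes[l] * sizes[l + 1]) * sqrt(2 / sizes[l]),
      nrow = sizes[l]
    )
    params$b[[l]] <- rep(0, sizes[l + 1])
  }
  params
}

mlp_forward <- function(params, x, dropout = NULL) {
  n_layers <- length(params$W)
  h <- x
  cache <- list(a = vector("list", n_layers), mask = vector("list", n_layers))
  for (l in seq_len(n_layers - 1)) {
    z <- sweep(h %*% params$W[[l]], 2, params$b[[l]], "+")
    a <- pmax(z, 0)
    if (!is.null(dropout) && dropout[l] > 0) {
      mask <- matrix(
        (runif(length(a)) > dropout[l]) / (1 - dropout[l]), nrow = nrow(a)
      )
      a <- a * mask
      cache$mask[[l]] <- mask
    }
    cache$a[[l]] <- a
    h <- a
  }
  z_out <- sweep(h %*% params$W[[n_layers]], 2, params$b[[n_layers]], "+")
  p <- 1 / (1 + exp(-z_out))
  list(p = as.numeric(p), cache = cache, x = x)
}

# d(focal loss)/d(logit), mean reduction
focal_grad_logit <- function(p, y, alpha, gamma) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  p_t <- ifelse(y == 1, p, 1 - p)
  a_t <- ifelse(y == 1, alpha, 1 - alpha)
  d_pt <- a_t * gamma * (1 - p_t)^(pmax(gamma - 1, 0)) * log(p_t) -
    a_t * (1 - p_t)^gamma / p_t
  sign_y <- ifelse(y == 1, 1, -1)
  (d_pt * sign_y * p * (1 - p)) / length(y)
}

mlp_backward <- function(params, fwd, y, alpha, gamma) {
  n_layers <- length(params$W)
  grads <- list(W = vector("list", n_layers), b = vector("list", n_layers))
  dz <- matrix(focal_grad_logit(fwd$p, y, alpha, gamma), ncol = 1)
  for (l in rev(seq_len(n_layers))) {
    a_prev <- if (l == 1) fwd$x else fwd$cache$a[[l - 1]]
    grads$W[[l]] <- t(a_prev) %*% dz
    grads$b[[l]] <- colSums(dz)
    if (l > 1) {
      da <- dz %*% t(params$W[[l]])
      if (!is.null(fwd$cache$mask[[l - 1]])) {
        da <- da * fwd$cache$mask[[l - 1]]
      }
      dz <- da * (fwd$cache$a[[l - 1]] > 0)
    }
  }
  grads
}

#' Train the focal-loss neural network base learner
#'
#' Feedforward network with ReLU hidden layers, sigmoid output, inverted
#' dropout, and the Adam optimiser minimising focal loss
#' (\eqn{\gamma = 2, \alpha = 0.25} by default). Features are standardised
#' internally using statistics fitted on the training data only. Training
#' keeps the weights with the lowest epoch loss and stops early after
#' `patience` epochs without improvement. Fully deterministic given
#' `config$seed` (single-threaded).
#'
#' @param data Training table with feature columns and `label`.
#' @param config List from [nn_config()].
#' @return An `iani_learner` of kind `"neural_net"`.
#' @export
train_neural_net <- function(data, config = nn_config()) {
  config <- utils::modifyList(nn_config(), config)
  cols <- resolve_cols(data)
  y <- data$label
  x <- learner_matrix(data, cols)
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  n <- nrow(xs)

  with_seed(config$seed, {
    params <- mlp_init(ncol(xs), config$layers)
    adam <- list(
      mW = lapply(params$W, function(w) w * 0),
      vW = lapply(params$W, function(w) w * 0),
      mb = lapply(params$b, function(b) b * 0),
      vb = lapply(params$b, function(b) b * 0)
    )
    t_step <- 0
    best <- list(loss = Inf, params = params)
    stall <- 0
    history <- numeric(0)
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
      for (b_idx in batches) {
        fwd <- mlp_forward(params, xs[b_idx, , drop = FALSE],
                           dropout = config$dropout)
        grads <- mlp_backward(params, fwd, y[b_idx],
                              config$alpha, config$gamma)
        t_step <- t_step + 1
        for (l in seq_along(params$W)) {
          adam$mW[[l]] <- 0.9 * adam$mW[[l]] + 0.1 * grads$W[[l]]
          adam$vW[[l]] <- 0.999 * adam$vW[[l]] + 0.001 * grads$W[[l]]^2
          adam$mb[[l]] <- 0.9 * adam$mb[[l]] + 0.1 * grads$b[[l]]
          adam$vb[[l]] <- 0.999 * adam$vb[[l]] + 0.001 * grads$b[[l]]^2
          m_hat <- adam$mW[[l]] / (1 - 0.9^t_step)
          v_hat <- adam$vW[[l]] / (1 - 0.999^t_step)
          params$W[[l]] <- params$W[[l]] -
            config$lr * m_hat / (sqrt(v_hat) + 1e-8)
          mb_hat <- adam$mb[[l]] / (1 - 0.9^t_step)
          vb_hat <- adam$vb[[l]] / (1 - 0.999^t_step)
          params$b[[l]] <- params$b[[l]] -
            config$lr * mb_hat / (sqrt(vb_hat) + 1e-8)
        }
      }
      p_full <- mlp_forward(params, xs)$p
      if (anyNA(p_full) || any(!is.finite(p_full))) {
        abort("neural network training diverged (non-finite loss)")
      }
      loss <- focal_loss(pmin(pmax(p_full, 1e-7), 1 - 1e-7), y,
                         alpha = config$alpha, gamma = config$gamma)
      history <- c(history, loss)
      if (loss < best$loss - 1e-9) {
        best <- list(loss = loss, params = params)
        stall <- 0
      } else {
        stall <- stall + 1
        if (stall >= config$patience) break
      }
    }
    fit <- list(params = best$params, history = history)
    new_learner("neural_net", fit, center, scl, cols, config)
  })
}

#' Predict probabilities from a fitted base learner
#'
#' @param object An `iani_learner`.
#' @param newdata Data frame containing the learner's feature columns.
#' @param nrounds For gradient boosting only: use the first `nrounds` trees
#'   (staged prediction).
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict.iani_learner <- function(object, newdata, nrounds = NULL, ...) {
  x <- learner_matrix(newdata, object$cols)
  switch(object$kind,
    logistic = {
      xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
      if (ncol(xs) == 1) xs <- cbind(xs, `.dummy` = 0)
      as.numeric(predict(object$fit, xs, type = "response"))
    },
    random_forest = {
      pr <- predict(object$fit, data = data.frame(x),
                    num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosting = {
      dm <- xgboost::xgb.DMatrix(x)
      if (is.null(nrounds)) {
        as.numeric(predict(object$fit, dm))
      } else {
        as.numeric(predict(object$fit, dm,
                           iterationrange = c(1, nrounds)))
      }
    },
    neural_net = {
      xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
      mlp_forward(object$fit$params, xs)$p
    },
    abort(paste0("unknown learner kind: ", object$kind))
  )
}
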