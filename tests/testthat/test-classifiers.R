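toy_train <- function(n = 200, seed = 3, sep = 2) {
  withr::with_seed(seed, {
    label <- rbinom(n, 1, 0.3)
    tibble::tibble(
      gene = paste0("g", seq_len(n)),
      degree = rnorm(n, 10 + sep * label, 2),
      betweenness = rnorm(n, 0.02 + 0.01 * sep * label, 0.01),
      label = as.integer(label)
    )
  })
}

test_that("focal loss evaluates, reduces, and clips correctly", {
  # single positive at p = 0.5: 0.25 * 0.25 * ln 2
  expect_equal(focal_loss(0.5, 1), 0.25 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(focal_loss(0.5, 1), 0.043322, tolerance = 1e-5)
  # p_t -> 1 drives the loss to 0
  expect_lt(focal_loss(1 - 1e-9, 1), 1e-15)
  # gamma = 0, alpha = 0.5 is exactly half the cross-entropy
  withr::with_seed(5, {
    p <- runif(500, 0.01, 0.99)
    y <- rbinom(500, 1, 0.5)
    ce <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
    expect_equal(focal_loss(p, y, alpha = 0.5, gamma = 0), ce / 2,
                 tolerance = 1e-12)
  })
  expect_warning(focal_loss(c(0, 0.5), c(1, 1)), "clipped")
})

test_that("logistic learner is monotone and handles degenerate features", {
  dat <- toy_train(sep = 4)
  fit <- train_logistic(dat)
  ord <- order(dat$degree)
  # strip the second feature's influence by zeroing it out
  dat1 <- dplyr::mutate(dat, betweenness = 0)
  fit1 <- train_logistic(dat1)
  p1 <- predict(fit1, dat1[ord, ])
  expect_true(all(diff(p1) >= -1e-9))
  # constant feature gets a zero coefficient under the penalty
  datc <- dplyr::mutate(dat, degree = 5)
  fitc <- train_logistic(datc)
  beta <- as.numeric(stats::coef(fitc$fit))[-1]
  expect_equal(beta[match("degree", fitc$cols)], 0, tolerance = 1e-8)
  expect_error(train_logistic(dplyr::mutate(dat, label = 1L)), "both classes")
})

test_that("random forest memorises noiseless data and is seed-stable", {
  dat <- toy_train(n = 60, sep = 8)
  fit <- train_random_forest(dat, list(seed = 5))
  p <- predict(fit, dat)
  expect_equal(as.integer(p >= 0.5), dat$label)
  fit2 <- train_random_forest(dat, list(seed = 5))
  expect_identical(predict(fit2, dat), p)
  expect_error(train_random_forest(dat[0, ]), "empty")
})

test_that("gradient boosting satisfies the additive staged recursion", {
  dat <- toy_train(n = 300)
  fit <- train_gradient_boosting(dat, list(nrounds = 50, seed = 2))
  x <- as.matrix(dat[fit$cols])
  dm <- xgboost::xgb.DMatrix(x)
  m <- 30
  stage <- function(range) {
    predict(fit$fit, dm, iterationrange = range, outputmargin = TRUE)
  }
  # each staged margin includes the constant base margin b; recover b from
  # three stages, then check F_m = F_{m-1} + (stage-m tree contribution)
  b <- stage(c(1, 1)) + stage(c(2, 2)) - stage(c(1, 2))
  expect_lt(diff(range(b)), 1e-5)
  expect_equal(stage(c(1, m)), stage(c(1, m - 1)) + stage(c(m, m)) - b,
               tolerance = 1e-5)

  # training loss decreases with boosting rounds
  logloss <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(dat$label * log(p) + (1 - dat$label) * log(1 - p))
  }
  losses <- vapply(c(1, 10, 25, 50), function(mm) {
    logloss(predict(fit, dat, nrounds = mm))
  }, numeric(1))
  expect_true(all(diff(losses) < 0))

  imp <- xgboost::xgb.importance(model = fit$fit)
  expect_equal(sum(imp$Gain), 1, tolerance = 1e-6)
})

test_that("the focal-loss network trains, bounds output, and is seeded", {
  dat <- toy_train(n = 250, sep = 3)
  cfg <- nn_config(layers = c(16, 8), dropout = c(0.2, 0.2), epochs = 10,
                   patience = 10, seed = 4)
  fit <- train_neural_net(dat, cfg)
  hist <- fit$fit$history
  expect_lt(hist[length(hist)], hist[1])
  p <- predict(fit, dat)
  expect_true(all(p > 0 & p < 1))
  fit2 <- train_neural_net(dat, cfg)
  expect_identical(predict(fit2, dat), p)
})

test_that("network forward pass is symmetric under feature permutation", {
  withr::with_seed(8, {
    x <- matrix(rnorm(40), ncol = 4)
    params <- ianinet:::mlp_init(4, c(6, 3))
    perm <- c(3, 1, 4, 2)
    params_p <- params
    params_p$W[[1]] <- params$W[[1]][perm, ]
    p1 <- ianinet:::mlp_forward(params, x)$p
    p2 <- ianinet:::mlp_forward(params_p, x[, perm])$p
    expect_equal(p1, p2, tolerance = 1e-12)
  })
})

test_that("hyperparameter search finds a 1-D quadratic optimum", {
  obj <- function(cfg) -(cfg$x - 0.62)^2
  res <- tune_hyperparameters(list(x = c(0, 1)), obj, n_iter = 30,
                              method = "gp", seed = 2)
  expect_lt(abs(res$best_config$x - 0.62), 0.05)
  one <- tune_hyperparameters(list(x = c(0, 1)), obj, n_iter = 1, seed = 2)
  expect_equal(nrow(one$trace), 1)
  expect_equal(one$best_value, obj(one$best_config))
  res2 <- tune_hyperparameters(list(x = c(0, 1)), obj, n_iter = 15,
                               method = "random", seed = 7)
  res3 <- tune_hyperparameters(list(x = c(0, 1)), obj, n_iter = 15,
                               method = "random", seed = 7)
  expect_identical(res2$trace, res3$trace)
  expect_error(tune_hyperparameters(list(x = c(1, 0)), obj), "bounds")
})

test_that("soft voting is the stated convex combination", {
  expect_equal(soft_vote(cbind(0.9, 0.8, 0.7, 0.6),
                         c(0.15, 0.25, 0.30, 0.30)), 0.725)
  p <- cbind(0.5, 0.5, 0.5, 0.5)
  expect_equal(soft_vote(p, rep(0.25, 4)), 0.5)
  withr::with_seed(1, {
    probs <- matrix(runif(40), ncol = 4)
    w <- c(0.1, 0.2, 0.3, 0.4)
    v <- soft_vote(probs, w)
    expect_true(all(v >= apply(probs, 1, min) - 1e-12))
    expect_true(all(v <= apply(probs, 1, max) + 1e-12))
  })
  expect_error(soft_vote(cbind(0.5, 0.5), c(1)), "one weight")
  expect_error(soft_vote(cbind(0.5, 0.5), c(0.6, 0.6)), "sum to 1")
})

test_that("threshold optimisation equals exhaustive search", {
  tau <- optimise_threshold(c(0.9, 0.8, 0.4, 0.3, 0.2),
                            c(1, 1, 0, 0, 0))
  expect_equal(as.numeric(tau), 0.6)
  expect_equal(attr(tau, "f1"), 1)
  withr::with_seed(21, {
    for (i in 1:15) {
      n <- sample(10:200, 1)
      scores <- round(runif(n), 2)
      labels <- rbinom(n, 1, 0.3)
      if (length(unique(labels)) < 2) next
      tau <- optimise_threshold(scores, labels)
      expect_equal(attr(tau, "f1"), oracle_best_f1(scores, labels),
                   tolerance = 1e-12)
    }
  })
  expect_error(optimise_threshold(runif(5), rep(1, 5)), "both classes")
})

test_that("metric reports satisfy their defining identities", {
  perfect <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$auprc, 1)

  const <- evaluate_scores(rep(0.4, 100), c(rep(1, 20), rep(0, 80)), 0.5)
  expect_equal(const$roc_auc, 0.5)
  expect_equal(const$auprc, 0.2)

  withr::with_seed(3, {
    for (i in 1:10) {
      scores <- runif(150)
      labels <- rbinom(150, 1, 0.2)
      if (sum(labels) == 0) next
      m <- evaluate_scores(scores, labels, runif(1))
      if (m$precision + m$recall > 0) {
        expect_equal(m$f1,
                     2 * m$precision * m$recall / (m$precision + m$recall),
                     tolerance = 1e-12)
      }
      expect_equal(m$balanced_accuracy, (m$recall + m$specificity) / 2,
                   tolerance = 1e-12)
      # rank AUC agrees with an independent implementation
      ref <- suppressMessages(pROC::auc(labels, scores,
                                        direction = "<", quiet = TRUE))
      expect_equal(m$roc_auc, as.numeric(ref), tolerance = 1e-10)
    }
  })

  # published operating point: precision 0.90, recall 0.81 gives F1 0.85
  expect_equal(2 * 0.90 * 0.81 / (0.90 + 0.81), 0.8526, tolerance = 1e-4)
  expect_error(evaluate_scores(runif(5), rep(0, 5)), "no positives")
})

test_that("ensemble training is reproducible end to end", {
  fx <- small_planted()
  sub <- fx$features
  m1 <- train_iani_ensemble(sub, k = 3,
                            configs = fast_configs())
  m2 <- train_iani_ensemble(sub, k = 3,
                            configs = fast_configs())
  expect_identical(tibble::as_tibble(m1$metrics),
                   tibble::as_tibble(m2$metrics))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$tau, m2$tau)
  expect_equal(sum(m1$weights), 1, tolerance = 1e-9)
  expect_true(audit_leakage(m1))
})
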