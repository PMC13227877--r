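#' Split and resampling specification
#'
#' Holds the test fraction and the four fixed seeds governing the split,
#' SMOTE, undersampling and cross-validation stratification.
#'
#' @param test_fraction Test-set fraction in (0, 1); default 0.2.
#' @param seed_split,seed_smote,seed_under,seed_cv Integer seeds
#'   (defaults 42, 123, 456, 789).
#' @return A `split_spec` list.
#' @export
split_spec <- function(test_fraction = 0.2, seed_split = 42,
                       seed_smote = 123, seed_under = 456, seed_cv = 789) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)")
  }
  structure(
    list(test_fraction = test_fraction, seed_split = seed_split,
         seed_smote = seed_smote, seed_under = seed_under,
         seed_cv = seed_cv),
    class = "split_spec"
  )
}

#' Stratified train/test split
#'
#' Per class, `round(n * test_fraction)` rows (round-half-up) go to the test
#' set and the remainder to training, so the natural class prevalence is
#' preserved in both. Deterministic given `spec$seed_split`.
#'
#' @param table Feature table with a 0/1 `label` column.
#' @param spec A [split_spec()].
#' @return List with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
stratified_split <- function(table, spec = split_spec()) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  counts <- table(table$label)
  if (length(counts) < 2) abort("both classes must be present")
  if (any(counts < 2)) abort("each class needs at least 2 members")
  test_idx <- with_seed(spec$seed_split, {
    unlist(lapply(sort(unique(table$label)), function(cl) {
      idx <- which(table$label == cl)
      n_test <- round_half_up(length(idx) * spec$test_fraction)
      sample(idx, n_test)
    }))
  })
  list(
    train = table[-test_idx, , drop = FALSE],
    test = table[test_idx, , drop = FALSE]
  )
}

#' SMOTE minority oversampling
#'
#' Generates `target_n - nrow(minority_rows)` synthetic minority rows, each
#' of the form \eqn{x_i + u (x_{nn} - x_i)} with \eqn{u \sim U(0,1)} and
#' \eqn{x_{nn}} one of the k nearest minority neighbours of \eqn{x_i}
#' (Euclidean distance on internally standardised features). Every synthetic
#' row lies componentwise between its two parents.
#'
#' @param minority_rows Data frame of minority-class feature rows (numeric
#'   columns only are interpolated).
#' @param target_n Desired minority count after oversampling.
#' @param k Number of nearest neighbours (default 5); must be below the
#'   minority count.
#' @param seed RNG seed.
#' @return Tibble of synthetic rows (0 rows when `target_n` equals the
#'   current count).
#' @export
smote_oversample <- function(minority_rows, target_n, k = 5, seed = 123) {
  stopifnot(is.data.frame(minority_rows))
  n <- nrow(minority_rows)
  if (target_n < n) abort("target_n below current minority count")
  if (k >= n) abort("k must be below the minority count")
  n_new <- target_n - n
  cols <- names(minority_rows)[vapply(minority_rows, is.numeric, TRUE)]
  x <- as.matrix(minority_rows[cols])
  if (n_new == 0) {
    return(tibble::as_tibble(minority_rows[0, cols, drop = FALSE]))
  }
  # neighbour search in standardised space (scale-free); interpolation is
  # performed on the raw coordinates
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  d2 <- as.matrix(stats::dist(xs))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  synth <- with_seed(seed, {
    parents <- sample.int(n, n_new, replace = TRUE)
    picks <- nn[cbind(parents, sample.int(k, n_new, replace = TRUE))]
    u <- runif(n_new)
    x[parents, , drop = FALSE] +
      u * (x[picks, , drop = FALSE] - x[parents, , drop = FALSE])
  })
  tibble::as_tibble(as.data.frame(synth))
}

#' Latin-hypercube-stratified majority undersampling
#'
#' Selects `target_n` representative majority rows: each feature is rank
#' transformed to (0, 1]; a Latin hypercube design of `target_n` points
#' (one point in each of `target_n` equal strata per dimension, permuted
#' independently) is drawn; design points are processed in a seed-shuffled
#' order and each claims the nearest not-yet-selected row in rank space
#' (Euclidean). This preserves the marginal distributional structure of the
#' majority class, unlike uniform random undersampling.
#'
#' @param majority_rows Data frame of majority-class feature rows.
#' @param target_n Number of rows to retain (`<=` the majority count).
#' @param seed RNG seed.
#' @return Integer vector of `target_n` unique row indices into
#'   `majority_rows`.
#' @export
lhs_undersample <- function(majority_rows, target_n, seed = 456) {
  stopifnot(is.data.frame(majority_rows))
  n <- nrow(majority_rows)
  if (target_n > n) abort("target_n exceeds the majority count")
  if (target_n == n) return(seq_len(n))
  cols <- names(majority_rows)[vapply(majority_rows, is.numeric, TRUE)]
  x <- as.matrix(majority_rows[cols])
  p <- ncol(x)
  ranks <- apply(x, 2, function(col) rank(col, ties.method = "average") / n)
  with_seed(seed, {
    design <- lhs::randomLHS(target_n, p)
    ord <- sample.int(target_n)
    selected <- integer(target_n)
    available <- rep(TRUE, n)
    for (j in ord) {
      d2 <- colSums((t(ranks) - design[j, ])^2)
      d2[!available] <- Inf
      pick <- which.min(d2)
      selected[j] <- pick
      available[pick] <- FALSE
    }
    selected
  })
}

#' Balanced per-class weights
#'
#' The balanced heuristic \eqn{w_c = N / (2 N_c)}: each class carries equal
#' total weight, penalising minority misclassification in proportion to its
#' scarcity.
#'
#' @param labels 0/1 vector (or data frame with a `label` column).
#' @return Named numeric vector `c(neg = w_0, pos = w_1)`.
#' @examples
#' class_weights(c(1, rep(0, 9)))
#' @export
class_weights <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  n <- n_pos + n_neg
  c(neg = n / (2 * n_neg), pos = n / (2 * n_pos))
}

#' Rebalance a training set (SMOTE + LHS undersampling)
#'
#' Applies SMOTE oversampling of the positives followed by LHS-stratified
#' undersampling of the negatives so the achieved positive rate lies within
#' `tolerance` of `target_prior`. Default factors (positives x 2.7,
#' negatives x 0.89) scale the minority up and trim the majority while
#' keeping most of it; if the resulting prior would fall outside the band,
#' the majority target is pulled to match `target_prior` exactly. A no-op
#' when the training prior is already within tolerance.
#'
#' @param train Training feature table (columns `gene`, features, `label`).
#' @param target_prior Target positive rate (default 0.15).
#' @param spec A [split_spec()] supplying the SMOTE/undersampling seeds.
#' @param pos_factor Minority oversampling factor (default 2.7).
#' @param neg_factor Majority retention factor (default 0.89).
#' @param k SMOTE neighbour count.
#' @param tolerance Acceptable deviation of the achieved prior.
#' @return A `resampled_set`: tibble with the feature columns, `label`,
#'   `gene` (`NA` for synthetic rows) and `provenance` in
#'   `{original, synthetic, retained-majority}`; attribute `pi_resampled`.
#' @export
rebalance <- function(train, target_prior = 0.15, spec = split_spec(),
                      pos_factor = 2.7, neg_factor = 0.89, k = 5,
                      tolerance = 0.02) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  pos <- dplyr::filter(train, .data$label == 1)
  neg <- dplyr::filter(train, .data$label == 0)
  if (nrow(pos) == 0 || nrow(neg) == 0) abort("both classes must be present")
  cols <- intersect(feature_cols(), names(train))
  if (length(cols) == 0) {
    cols <- setdiff(names(train)[vapply(train, is.numeric, TRUE)], "label")
  }

  prior0 <- nrow(pos) / nrow(train)
  if (abs(prior0 - target_prior) <= tolerance) {
    out <- dplyr::bind_rows(
      dplyr::mutate(pos, provenance = "original"),
      dplyr::mutate(neg, provenance = "retained-majority")
    )
    attr(out, "pi_resampled") <- prior0
    return(out)
  }

  pos_target <- round_half_up(nrow(pos) * pos_factor)
  if (pos_target < nrow(pos)) abort("infeasible oversampling target")
  neg_target <- min(nrow(neg), round_half_up(nrow(neg) * neg_factor))
  achieved <- pos_target / (pos_target + neg_target)
  if (abs(achieved - target_prior) > tolerance) {
    neg_target <- min(
      nrow(neg),
      round_half_up(pos_target * (1 - target_prior) / target_prior)
    )
  }

  synth <- smote_oversample(pos[cols], pos_target, k = k,
                            seed = spec$seed_smote)
  keep <- lhs_undersample(neg[cols], neg_target, seed = spec$seed_under)

  synth_rows <- synth |>
    dplyr::mutate(gene = NA_character_, label = 1L,
                  provenance = "synthetic")
  out <- dplyr::bind_rows(
    dplyr::mutate(pos, provenance = "original"),
    synth_rows,
    dplyr::mutate(neg[keep, , drop = FALSE],
                  provenance = "retained-majority")
  )
  pi_res <- sum(out$label == 1) / nrow(out)
  attr(out, "pi_resampled") <- pi_res
  ianet_log("rebalance: ", nrow(pos), "/", nrow(neg), " -> ",
            sum(out$label == 1), "/", sum(out$label == 0),
            " (pi = ", round(pi_res, 3), ")")
  out
}

#' Stratified cross-validation folds
#'
#' Partitions the training rows into k stratified folds. Each element pairs
#' a `fit` index set with its complementary `validate` set; rebalancing is
#' applied by the caller to the fit part only, while validation folds stay
#' in their original imbalanced state.
#'
#' @param train Training feature table with a `label` column.
#' @param k Number of folds (default 5).
#' @param spec A [split_spec()] supplying `seed_cv`.
#' @return List of k lists, each with integer vectors `fit` and `validate`;
#'   the validation parts partition `seq_len(nrow(train))`.
#' @export
cv_folds <- function(train, k = 5, spec = split_spec()) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  counts <- table(train$label)
  if (length(counts) < 2 || any(counts < k)) {
    abort(paste0("each class needs at least ", k, " members"))
  }
  fold_of <- integer(nrow(train))
  with_seed(spec$seed_cv, {
    for (cl in sort(unique(train$label))) {
      idx <- sample(which(train$label == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(fit = which(fold_of != f), validate = which(fold_of == f))
  })
}
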