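test_that("external set construction applies exclusion then network filter", {
  res <- build_external_set(c("A", "B", "C"), "B", c("A", "C", "D"))
  expect_setequal(res$genes, c("A", "C"))
  expect_equal(res$counts$n, c(3, 2, 2))
  expect_warning(
    empty <- build_external_set(c("A", "B"), c("A", "B", "C"), c("A")),
    "empty"
  )
  expect_length(empty$genes, 0)
})

test_that("external validation computes recall at tau and rank metrics", {
  scores <- tibble::tibble(gene = paste0("g", 1:100),
                           score = c(rep(0.9, 10), runif(90, 0, 0.4)))
  res <- external_validate(scores, paste0("g", 1:10), paste0("g", 11:100),
                           tau = 0.5)
  expect_equal(res$recall, 1)
  expect_equal(res$n_above_threshold, 10)
  expect_gt(res$roc_auc, 0.99)

  const <- tibble::tibble(gene = paste0("g", 1:50), score = 0.3)
  rc <- external_validate(const, paste0("g", 1:5), paste0("g", 6:50), 0.5)
  expect_equal(rc$roc_auc, 0.5)
  expect_error(
    external_validate(const, c("g1", "zz"), paste0("g", 6:50), 0.5),
    "zz"
  )
})

test_that("external recall is invariant to tau-preserving monotone maps", {
  withr::with_seed(2, {
    sc <- tibble::tibble(gene = paste0("g", 1:80), score = runif(80))
  })
  set <- paste0("g", 1:15)
  bg <- paste0("g", 16:80)
  r1 <- external_validate(sc, set, bg, 0.5)$recall
  # strictly monotone map fixing the threshold crossing at 0.5
  sc2 <- dplyr::mutate(sc, score = stats::plogis(8 * (score - 0.5)))
  r2 <- external_validate(sc2, set, bg, 0.5)$recall
  expect_equal(r1, r2)
})

test_that("degree-matched nulls respect the matching window", {
  fx <- small_planted()
  predicted <- withr::with_seed(31, sample(fx$features$gene, 40))
  refs <- list(planted = fx$net$positives)
  nd <- degree_matched_null(predicted, fx$graph, refs, n_sets = 25,
                            tolerance = 0.10, seed = 5)
  degv <- stats::setNames(degree_stats(fx$graph)$degree,
                          degree_stats(fx$graph)$gene)
  tolv <- nd$relaxed_tolerances
  for (s in nd$sets) {
    target_deg <- degv[names(s)]
    match_deg <- degv[s]
    tol <- tolv[names(s)]
    expect_true(all(match_deg >= floor((1 - tol) * target_deg)))
    expect_true(all(match_deg <= ceiling((1 + tol) * target_deg)))
    expect_false(any(s == names(s)))
  }
  expect_error(
    degree_matched_null(predicted, fx$graph, refs, n_sets = 1),
    "n_sets"
  )
})

test_that("null overlap concentrates at prevalence for random references", {
  fx <- small_planted()
  genes <- fx$features$gene
  random_ref <- withr::with_seed(77, sample(genes, round(0.1 * length(genes))))
  predicted <- withr::with_seed(78, sample(genes, 50))
  nd <- degree_matched_null(predicted, fx$graph,
                            list(rnd = random_ref), n_sets = 200, seed = 3)
  expect_lt(abs(nd$results$null_mean - 0.1), 0.05)
  expect_lt(abs(nd$results$z), 3)
})

test_that("a degree-independent subset of the reference scores a large z", {
  fx <- small_planted()
  genes <- fx$features$gene
  # reference drawn uniformly (degree-independent), predictions inside it
  reference <- withr::with_seed(41, sample(genes, 120))
  predicted <- withr::with_seed(42, sample(reference, 40))
  nd <- degree_matched_null(predicted, fx$graph, list(ref = reference),
                            n_sets = 100, seed = 9)
  expect_gt(nd$results$z, 3)
})

test_that("gene-set enrichment flags full-overlap and behaves under null", {
  universe <- paste0("g", 1:500)
  sets <- list(hit = paste0("g", 1:25), other = paste0("g", 100:160))
  res <- gene_set_enrichment(paste0("g", 1:25), sets, universe)
  hit <- res[res$set == "hit", ]
  expect_equal(hit$overlap, 25)
  expect_true(hit$significant)
  expect_gt(hit$odds_ratio, res$odds_ratio[res$set == "other"])

  # uniform query: about 5% of sets significant uncorrected
  rate <- withr::with_seed(55, {
    sets_null <- lapply(1:200, function(i) sample(universe, 30))
    names(sets_null) <- paste0("s", 1:200)
    query <- sample(universe, 60)
    res_null <- gene_set_enrichment(query, sets_null, universe,
                                    family_m = 1)
    mean(res_null$p < 0.05)
  })
  expect_lt(rate, 0.12)
  expect_error(gene_set_enrichment(c("zz"), sets, universe), "universe")
  expect_warning(
    gene_set_enrichment(paste0("g", 1:5),
                        list(out = c("x1", "x2"), hit = sets$hit),
                        universe),
    "disjoint"
  )
})

test_that("held-out planted drivers are recovered above prevalence", {
  fx <- small_planted()
  parts <- generate_external_holdout(fx$net$positives, fraction = 0.25,
                                     seed = 3)
  # retrain with the held-out drivers hidden (labelled background)
  ft <- fx$features
  ft$label <- as.integer(ft$label == 1 &
                           !(ft$gene %in% parts$holdout_positives))
  model <- train_iani_ensemble(ft, configs = fast_configs())
  scores <- tibble::tibble(gene = ft$gene, score = predict(model, ft))
  res <- external_validate(
    scores, parts$holdout_positives,
    background_genes = setdiff(ft$gene, fx$net$positives),
    tau = model$tau
  )
  prevalence <- length(fx$net$positives) / nrow(ft)
  expect_gt(res$recall, prevalence)
  expect_gt(res$roc_auc, 0.5)
})

test_that("GMT parsing returns long-format memberships", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG2\tG4"), f)
  gmt <- read_gmt(f)
  expect_equal(nrow(gmt), 5)
  expect_setequal(gmt$gene[gmt$set == "setA"], c("G1", "G2", "G3"))
  f2 <- tempfile()
  writeLines("bad\tline", f2)
  expect_error(read_gmt(f2), "members")
})
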