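test_that("hub threshold is mu + 2 sigma with population SD", {
  th <- hub_threshold(c(1, 2, 3, 4, 5))
  expect_equal(th$mu, 3)
  expect_equal(th$sigma, sqrt(2))
  expect_equal(th$threshold, 3 + 2 * sqrt(2))
  expect_equal(hub_threshold(rep(7, 10))$threshold, 7)
  # reported full-scale outdegree moments imply a cutoff of 118.76
  expect_equal(45.12 + 2 * 36.82, 118.76)
  expect_error(hub_threshold(5), "at least 2")
  # translation equivariance
  d <- c(3, 9, 14, 2, 8)
  expect_equal(hub_threshold(d + 10)$threshold,
               hub_threshold(d)$threshold + 10)
})

test_that("hub calling uses a strict cutoff", {
  # regular graph: nothing exceeds mu
  ring <- toy_gene_graph(cbind(1:6, c(2:6, 1)))
  expect_equal(nrow(identify_hubs(ring)), 0)
  # one dominant node among near-isolated pairs
  star_edges <- rbind(cbind(1, 2:21), cbind(22:29, 30:37))
  g <- toy_gene_graph(star_edges)
  hubs <- identify_hubs(g)
  expect_equal(hubs$gene, "V1")
})

test_that("ego networks report density and neighbour enrichment", {
  g <- toy_gene_graph(rbind(c(1, 2), c(1, 3), c(1, 4)))
  lab <- suppressWarnings(assign_labels(g, character(0)))
  ego <- ego_network(g, "V1", lab)
  expect_equal(ego$n_nodes, 4)
  expect_equal(ego$density, 0.5)  # 3 edges of 6 possible
  expect_equal(ego$cancer_fraction, 0)

  tri <- toy_gene_graph(t(utils::combn(3, 2)))
  lab3 <- assign_labels(tri, c("V1", "V2", "V3"))
  ego3 <- ego_network(tri, "V1", lab3)
  expect_equal(ego3$cancer_fraction, 1)
  expect_equal(ego3$density, 1)
  expect_error(ego_network(g, "ZZ"), "not in graph")
})

test_that("Fisher exact matches hypergeometric enumeration", {
  res <- fisher_exact(5, 0, 0, 5)
  expect_equal(res$p, 2 / 252, tolerance = 1e-12)
  null <- fisher_exact(10, 10, 10, 10)
  expect_equal(null$p, 1)
  expect_equal(null$odds_ratio, 1)
  withr::with_seed(14, {
    for (i in 1:100) {
      cells <- rpois(4, 4)
      if (any(c(cells[1] + cells[2], cells[3] + cells[4],
                cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
      got <- fisher_exact(cells[1], cells[2], cells[3], cells[4])$p
      want <- oracle_fisher_p(cells[1], cells[2], cells[3], cells[4])
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
  expect_error(fisher_exact(0, 0, 3, 4), "zero margin")
})

test_that("odds ratio CIs follow the log-scale Wald formula", {
  res <- odds_ratio_ci(20, 10, 5, 40)
  expect_equal(res$odds_ratio, 16)
  expect_equal(res$ci_low, 4.82, tolerance = 0.01)
  expect_equal(res$ci_high, 53.13, tolerance = 0.01)

  bal <- odds_ratio_ci(10, 10, 10, 10)
  expect_equal(bal$odds_ratio, 1)
  expect_equal(log(bal$ci_low), -log(bal$ci_high), tolerance = 1e-12)

  withr::with_seed(6, {
    for (i in 1:25) {
      cells <- rpois(4, 8) + 1
      r <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])
      or <- cells[1] * cells[4] / (cells[2] * cells[3])
      se <- sqrt(sum(1 / cells))
      expect_equal(r$odds_ratio, or, tolerance = 1e-9)
      expect_equal(r$ci_low, exp(log(or) - 1.96 * se), tolerance = 1e-9)
      expect_equal(r$ci_high, exp(log(or) + 1.96 * se), tolerance = 1e-9)
      expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    }
  })
  # zero cell triggers the Haldane correction
  z <- odds_ratio_ci(5, 0, 2, 7)
  expect_true(z$haldane_corrected)
  expect_true(is.finite(z$odds_ratio))
})

test_that("Mann-Whitney U and p behave on canonical inputs", {
  same <- mann_whitney(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(same$U, 18)   # n1 n2 / 2
  expect_gt(same$p, 0.9)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12), alternative = "less")
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 1 / choose(6, 3), tolerance = 1e-12)
  expect_equal(sep$method, "exact")

  withr::with_seed(10, {
    for (i in 1:10) {
      x <- rnorm(6)
      y <- rnorm(6, 0.5)
      p_exact <- mann_whitney(x, y)$p
      p_norm <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                    correct = TRUE)$p.value)
      expect_lt(abs(p_exact - p_norm), 0.02)
    }
  })
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Cohen's d uses the pooled-SD formula", {
  expect_equal(cohens_d(10, 5, 2, 10, 5, 2), 0)
  expect_equal(cohens_d(3, 10, 2, 3, 7, 2), 1.5)
  expect_equal(cohens_d(8, 4, 1, 12, 6, 2),
               -cohens_d(12, 6, 2, 8, 4, 1))
  expect_error(cohens_d(5, 1, 0, 5, 1, 0), "zero pooled")
  expect_error(cohens_d(1, 1, 1, 5, 2, 1), "n >= 2")
})

test_that("Bonferroni correction divides alpha by the family size", {
  expect_equal(bonferroni_alpha(0.05, 45), 0.0011, tolerance = 1e-2)
  expect_equal(bonferroni_alpha(0.05, 45), 0.05 / 45)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 150), 0.00033, tolerance = 1e-2)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")
})

test_that("Fisher-z correlation CIs achieve near-nominal coverage", {
  expect_equal(pearson_with_fisher_z(1:10, 1:10)$r, 1)
  expect_equal(pearson_with_fisher_z(1:10, -(1:10))$r, -1)
  rho <- 0.6
  covered <- withr::with_seed(17, {
    vapply(1:200, function(i) {
      x <- rnorm(50)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(50)
      ci <- pearson_with_fisher_z(x, y)
      ci$ci_low <= rho && rho <= ci$ci_high
    }, logical(1))
  })
  expect_gte(mean(covered), 0.90)
  expect_error(pearson_with_fisher_z(rep(1, 10), 1:10), "zero variance")
  expect_error(pearson_with_fisher_z(1:3, 1:3), "at least 4")
})

test_that("hub group comparison separates planted drivers", {
  fx <- small_planted()
  hubs <- identify_hubs(fx$graph, fx$labels)
  expect_true(any(hubs$is_cancer) && any(!hubs$is_cancer))
  res <- compare_hub_groups(hubs, fx$features, family_m = 45)
  expect_setequal(res$comparisons$metric,
                  c("degree", "betweenness", "pagerank"))
  expect_equal(unique(res$comparisons$corrected_alpha), 0.05 / 45)
  expect_true(all(is.finite(res$comparisons$d)))
  expect_gt(res$enrichment$odds_ratio, 1)
  # the planted signal right-shifts driver centralities network-wide
  ft <- fx$features
  for (mm in c("degree", "betweenness")) {
    cmp <- mann_whitney(ft[[mm]][ft$label == 1], ft[[mm]][ft$label == 0])
    expect_gt(cmp$d, 0.5)
    expect_lt(cmp$p, 0.001)
  }
})

test_that("null labels on hubs give negligible effects in expectation", {
  fx <- small_planted()
  ft <- fx$features
  hub_genes <- identify_hubs(fx$graph, fx$labels)$gene
  hf <- ft[ft$gene %in% hub_genes, ]
  ds <- withr::with_seed(23, {
    vapply(1:20, function(i) {
      grp <- sample(c(TRUE, FALSE), nrow(hf), replace = TRUE)
      if (sum(grp) < 2 || sum(!grp) < 2) return(NA_real_)
      mann_whitney(hf$degree[grp], hf$degree[!grp])$d
    }, numeric(1))
  })
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.2)
})
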