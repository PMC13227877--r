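#' Construct an external validation gene set
#'
#' Generic set construction mirroring curated-driver-list filtering:
#' candidates minus exclusions (e.g. the training positives), intersected
#' with the network nodes; survivor counts per stage are recorded. Temporal
#' or version filters are the caller's responsibility (supply a
#' pre-filtered candidate list).
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param exclusions Symbols to remove (e.g. training positives).
#' @param network_nodes Node symbols of the analysis graph.
#' @return List with `genes` (character) and `counts` (tibble of per-stage
#'   survivor counts). Warns if the result is empty.
#' @export
build_external_set <- function(candidates, exclusions, network_nodes) {
  candidates <- unique(candidates)
  after_excl <- setdiff(candidates, exclusions)
  final <- intersect(after_excl, network_nodes)
  counts <- tibble::tibble(
    stage = c("candidates", "after_exclusion", "in_network"),
    n = c(length(candidates), length(after_excl), length(final))
  )
  if (length(final) == 0) warn("external validation set is empty")
  ianet_log("build_external_set: ", paste(counts$n, collapse = " -> "))
  list(genes = final, counts = counts)
}

#' Evaluate model scores against an external gene set
#'
#' Treats every external-set gene as a true positive: recall at the fixed
#' threshold `tau` (genes below threshold are false negatives), and
#' rank-based ROC-AUC / AUPRC scoring set genes against the supplied
#' background. No retraining or threshold adjustment. When `features` is
#' given, degree/betweenness summaries of the missed genes are attached.
#'
#' @param model_scores Tibble with columns `gene` and `score` (ensemble
#'   probabilities for at least every set and background gene).
#' @param gene_set Character vector of external positives.
#' @param background_genes Character vector of scored background genes
#'   (disjoint from `gene_set`).
#' @param tau Fixed decision threshold.
#' @param features Optional feature table for missed-gene summaries.
#' @return One-row tibble: `n_set`, `n_above_threshold`, `recall`,
#'   `roc_auc`, `auprc`; attribute `missed_summary` when `features` given.
#' @export
external_validate <- function(model_scores, gene_set, background_genes,
                              tau, features = NULL) {
  stopifnot(is.data.frame(model_scores),
            all(c("gene", "score") %in% names(model_scores)))
  lookup <- stats::setNames(model_scores$score, model_scores$gene)
  missing <- setdiff(gene_set, model_scores$gene)
  if (length(missing) > 0) {
    abort(paste0("missing scores for: ", paste(missing, collapse = ", ")))
  }
  background_genes <- setdiff(background_genes, gene_set)
  s_set <- unname(lookup[gene_set])
  s_bg <- unname(lookup[intersect(background_genes, model_scores$gene)])
  n_above <- sum(s_set >= tau)
  scores <- c(s_set, s_bg)
  labels <- c(rep(1L, length(s_set)), rep(0L, length(s_bg)))
  mets <- evaluate_scores(scores, labels, tau)
  out <- tibble::tibble(
    n_set = length(gene_set), n_above_threshold = n_above,
    recall = n_above / length(gene_set),
    roc_auc = mets$roc_auc, auprc = mets$auprc
  )
  if (!is.null(features)) {
    missed <- gene_set[s_set < tau]
    cols <- intersect(c("degree", "betweenness"), names(features))
    fs <- dplyr::filter(features, .data$gene %in% missed)
    attr(out, "missed_summary") <- fs |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(cols),
        list(mean = ~ mean(.x), sd = ~ sd(.x))
      ), n = dplyr::n())
  }
  out
}

#' Degree-matched random null distribution
#'
#' For each null replicate, every predicted gene is replaced by a random
#' network gene whose degree lies within `tolerance` of its own
#' (multiplicative window `[floor((1-tol) d), ceiling((1+tol) d)]`, the
#' gene itself excluded), without replacement within a replicate. Overlap
#' proportions of the null sets with each reference set form the empirical
#' null against which the observed overlap is tested with a one-sample
#' z-test using the empirical null SD. A model whose predictions reflect
#' only connectivity shows z near 0; biologically specific predictions
#' show large positive z.
#'
#' @param predicted_set Character vector of predicted driver genes.
#' @param graph A `gene_graph`.
#' @param reference_sets Named list of reference gene-symbol vectors.
#' @param n_sets Number of null replicates (default 1000; must be >= 2).
#' @param tolerance Degree-matching tolerance (default 0.10); relaxed in
#'   +0.05 steps with a warning for genes with no candidate.
#' @param seed RNG seed.
#' @return A `null_distribution` list: `overlaps` (tibble of per-replicate,
#'   per-reference proportions), `results` (tibble with observed
#'   proportion, null mean/SD, `z`, `p` per reference), `sets` (the null
#'   gene sets, named by the predicted gene each entry matches),
#'   `tolerance`, `n_sets`.
#' @export
degree_matched_null <- function(predicted_set, graph, reference_sets,
                                n_sets = 1000, tolerance = 0.10, seed = 1) {
  stopifnot(inherits(graph, "gene_graph"))
  if (n_sets < 2) abort("n_sets must be >= 2 (null SD undefined)")
  if (is.null(names(reference_sets))) {
    names(reference_sets) <- paste0("reference_", seq_along(reference_sets))
  }
  deg_tbl <- degree_stats(graph)
  degv <- stats::setNames(deg_tbl$degree, deg_tbl$gene)
  predicted_set <- intersect(predicted_set, names(degv))
  if (length(predicted_set) == 0) abort("no predicted gene is in the graph")

  ord <- order(degv)
  genes_sorted <- names(degv)[ord]
  deg_sorted <- unname(degv[ord])

  window_candidates <- function(d, tol) {
    lo <- floor((1 - tol) * d)
    hi <- ceiling((1 + tol) * d)
    i1 <- findInterval(lo - 1e-9, deg_sorted) + 1
    i2 <- findInterval(hi + 1e-9, deg_sorted)
    if (i2 < i1) character(0) else genes_sorted[i1:i2]
  }

  cand <- lapply(predicted_set, function(g) {
    tol <- tolerance
    repeat {
      cc <- setdiff(window_candidates(degv[[g]], tol), g)
      if (length(cc) > 0) return(list(cand = cc, tol = tol))
      tol <- tol + 0.05
      warn(paste0("no degree match for ", g,
                  "; tolerance relaxed to ", tol))
      if (tol > 1) abort(paste0("no match candidate for gene ", g))
    }
  })
  relaxed <- vapply(cand, `[[`, 0, "tol")

  ref_member <- lapply(reference_sets, function(rs) {
    stats::setNames(names(degv) %in% rs, names(degv))
  })

  n_pred <- length(predicted_set)
  null_sets <- vector("list", n_sets)
  overlaps <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_sets), function(rep_i) {
      used <- character(0)
      chosen <- character(n_pred)
      for (i in sample.int(n_pred)) {
        cc <- cand[[i]]$cand
        pick <- cc[!cc %in% used]
        if (length(pick) == 0) pick <- cc # fall back with replacement
        chosen[i] <- pick[sample.int(length(pick), 1)]
        used <- c(used, chosen[i])
      }
      null_sets[[rep_i]] <<- stats::setNames(chosen, predicted_set)
      purrr::map_dfr(names(reference_sets), function(nm) {
        tibble::tibble(
          replicate = rep_i, reference = nm,
          proportion = mean(ref_member[[nm]][chosen])
        )
      })
    })
  })

  results <- purrr::map_dfr(names(reference_sets), function(nm) {
    null_p <- overlaps$proportion[overlaps$reference == nm]
    obs <- mean(predicted_set %in% reference_sets[[nm]])
    mu <- mean(null_p)
    s <- sd(null_p)
    z <- if (s == 0) Inf * sign(obs - mu) else (obs - mu) / s
    if (s == 0 && obs == mu) z <- 0
    tibble::tibble(
      reference = nm, observed = obs, null_mean = mu, null_sd = s,
      z = z, p = 2 * pnorm(-abs(z))
    )
  })

  structure(
    list(overlaps = overlaps, results = results, sets = null_sets,
         tolerance = tolerance, n_sets = n_sets,
         relaxed_tolerances = stats::setNames(relaxed, predicted_set)),
    class = "null_distribution"
  )
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$n_sets, " degree-matched null sets\n",
      sep = "")
  print(x$results)
  invisible(x)
}

#' Tidy a degree-matched null result
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return The per-reference results tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.null_distribution <- function(x, ...) x$results

#' Gene-set (pathway) enrichment of a query set
#'
#' Per gene set: overlap with the query, Fisher exact test against the
#' universe, odds ratio with CI, and the Bonferroni-corrected alpha for the
#' pathway family. Sets disjoint from the universe are skipped with a
#' warning.
#'
#' @param query_genes Character vector (must be contained in `universe`).
#' @param gene_sets Named list of gene-symbol vectors, or a GMT tibble from
#'   [read_gmt()].
#' @param universe Background gene symbols.
#' @param family_m Bonferroni family size (default: number of sets tested).
#' @return Tibble, one row per set: `set`, `n_set`, `overlap`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p`, `corrected_alpha`,
#'   `significant`.
#' @export
gene_set_enrichment <- function(query_genes, gene_sets, universe,
                                family_m = NULL) {
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(gene_sets$gene, gene_sets$set)
  }
  if (!all(query_genes %in% universe)) {
    abort("universe must contain every query gene")
  }
  keep <- vapply(gene_sets, function(s) length(intersect(s, universe)) > 0,
                 TRUE)
  if (any(!keep)) {
    warn(paste0("skipping sets disjoint from universe: ",
                paste(names(gene_sets)[!keep], collapse = ", ")))
  }
  gene_sets <- gene_sets[keep]
  m <- family_m %||% length(gene_sets)
  purrr::map_dfr(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    a <- length(intersect(query_genes, s))
    b <- length(setdiff(query_genes, s))
    c_ <- length(setdiff(s, query_genes))
    d <- length(universe) - a - b - c_
    res <- odds_ratio_ci(a, b, c_, d, family = "pathway", m = m)
    tibble::tibble(
      set = nm, n_set = length(s), overlap = a,
      odds_ratio = res$odds_ratio, ci_low = res$ci_low,
      ci_high = res$ci_high, p = res$p,
      corrected_alpha = res$corrected_alpha,
      significant = !is.na(res$p) & res$p < res$corrected_alpha
    )
  })
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member symbols.
#'
#' @param path Path to the GMT file.
#' @return Tibble with columns `set`, `description`, `gene` (long format).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map_dfr(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("GMT lines need name, description, members")
    tibble::tibble(set = f[1], description = f[2], gene = f[-(1:2)])
  })
}
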