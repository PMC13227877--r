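#' Read a STRING-style interaction edge list
#'
#' Parses a whitespace-separated protein interaction file in the STRING
#' `protein.links` dialect: columns `protein1 protein2 combined_score`, with
#' combined confidence scores on the 0--1000 scale and an optional single
#' header line.
#'
#' @param path Path to the edge-list file.
#' @param has_header `TRUE`, `FALSE`, or `NULL` to auto-detect (a first line
#'   whose third field is not an integer is treated as a header).
#' @return A tibble with columns `protein_a`, `protein_b` (character) and
#'   `combined_score` (integer in \[0, 1000\]), one row per data line.
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score", "A B 900", "B C 700"), f)
#' read_interactions(f)
#' @export
read_interactions <- function(path, has_header = NULL) {
  if (!file.exists(path)) abort(paste0("interaction file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  offset <- 0L
  if (length(lines) > 0) {
    first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
    header_like <- length(first) >= 3 &&
      is.na(suppressWarnings(as.integer(first[[3]])))
    if (isTRUE(has_header) || (is.null(has_header) && header_like)) {
      lines <- lines[-1]
      offset <- 1L
    }
  }
  if (length(lines) == 0) {
    ianet_log("read_interactions: 0 records")
    return(tibble::tibble(
      protein_a = character(), protein_b = character(),
      combined_score = integer()
    ))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(paste0(
      "parse error at line ", bad + offset, ": expected >= 3 fields, got ",
      nf[bad]
    ))
  }
  score_chr <- vapply(fields, `[[`, "", 3L)
  score <- suppressWarnings(as.integer(score_chr))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    abort(paste0(
      "parse error at line ", bad + offset, ": non-integer score '",
      score_chr[bad], "'"
    ))
  }
  out <- tibble::tibble(
    protein_a = vapply(fields, `[[`, "", 1L),
    protein_b = vapply(fields, `[[`, "", 2L),
    combined_score = score
  )
  if (any(out$combined_score < 0 | out$combined_score > 1000)) {
    bad <- which(out$combined_score < 0 | out$combined_score > 1000)[1]
    abort(paste0("parse error at line ", bad + offset,
                 ": score outside [0, 1000]"))
  }
  if (any(!nzchar(out$protein_a) | !nzchar(out$protein_b))) {
    abort("empty protein identifier in interaction file")
  }
  ianet_log("read_interactions: ", nrow(out), " records")
  out
}

#' Filter interactions by combined confidence score
#'
#' Retains interactions whose combined score is at or above the threshold
#' (boundary inclusive; 700 is the conventional high-confidence cutoff).
#'
#' @param records Tibble from [read_interactions()].
#' @param threshold Integer in \[0, 1000\]; default 700.
#' @return The subset of `records` with `combined_score >= threshold`,
#'   original order preserved.
#' @export
filter_confidence <- function(records, threshold = 700) {
  stopifnot(is.data.frame(records))
  if (threshold < 0 || threshold > 1000) {
    abort("threshold must be in [0, 1000]")
  }
  out <- dplyr::filter(records, .data$combined_score >= threshold)
  ianet_log("filter_confidence: ", nrow(records), " -> ", nrow(out),
            " records at score >= ", threshold)
  out
}

#' Strip a numeric species prefix from protein identifiers
#'
#' Identifiers of the form `9606.ENSP...` carry an NCBI taxon prefix; this
#' removes a leading `<digits>.` if present and is otherwise the identity.
#'
#' @param identifier Character vector of protein identifiers.
#' @return Character vector of the same length.
#' @examples
#' strip_species_prefix(c("9606.ENSP000123", "ENSP000123", ""))
#' @export
strip_species_prefix <- function(identifier) {
  sub("^[0-9]+\\.", "", identifier)
}

#' Read a protein-to-gene-symbol mapping table
#'
#' Two-column TSV, `protein_id <TAB> gene_symbol`, with no header (or a
#' `#`-prefixed header line, which is skipped). Species prefixes on the
#' protein ids are stripped.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `protein_id` and `gene_symbol`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) abort(paste0("id map not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(protein_id = character(), gene_symbol = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    abort("id map lines must have two tab-separated columns")
  }
  out <- tibble::tibble(
    protein_id = strip_species_prefix(vapply(fields, `[[`, "", 1L)),
    gene_symbol = vapply(fields, `[[`, "", 2L)
  )
  if (any(!nzchar(out$gene_symbol))) abort("empty gene symbol in id map")
  out <- dplyr::distinct(out, .data$protein_id, .keep_all = TRUE)
  ianet_log("read_id_map: ", nrow(out), " protein -> symbol mappings")
  out
}

#' Read a plain gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the text file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(paste0("gene list not found: ", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Map interaction endpoints to gene symbols
#'
#' Strips species prefixes, looks both endpoints up in the id map, and
#' discards interactions containing unmapped identifiers (a detectable miss,
#' not an error). The number of discarded edges is logged and attached as the
#' `n_discarded` attribute.
#'
#' @param records Tibble from [read_interactions()] (optionally already
#'   confidence-filtered).
#' @param idmap Tibble from [read_id_map()].
#' @return Tibble with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
map_to_symbols <- function(records, idmap) {
  stopifnot(is.data.frame(records), is.data.frame(idmap))
  lookup <- stats::setNames(idmap$gene_symbol, idmap$protein_id)
  a <- unname(lookup[strip_species_prefix(records$protein_a)])
  b <- unname(lookup[strip_species_prefix(records$protein_b)])
  keep <- !is.na(a) & !is.na(b)
  out <- tibble::tibble(
    gene_a = a[keep], gene_b = b[keep],
    combined_score = records$combined_score[keep]
  )
  attr(out, "n_discarded") <- sum(!keep)
  ianet_log("map_to_symbols: ", nrow(out), " edges mapped, ",
            sum(!keep), " discarded (unmapped identifiers)")
  out
}

#' Build the gene interaction graph
#'
#' Assembles the mapped symbol-level edge list into a simple undirected
#' graph: self-loops are dropped, duplicate edges are collapsed keeping the
#' maximum confidence score, and isolated nodes are absent by construction.
#' Directed degree bookkeeping (outdegree/indegree over distinct directed
#' pairs, as read) is retained alongside the undirected projection used for
#' centralities; for STRING-dialect files that list each interaction in both
#' directions, outdegree, indegree and undirected degree coincide.
#'
#' @param edges Tibble with columns `gene_a`, `gene_b`, `combined_score`
#'   (from [map_to_symbols()]), or a 3-column data frame in that order.
#' @return A `gene_graph` object: list with elements `graph` (an undirected
#'   simple igraph with a `score` edge attribute), `degrees` (tibble of
#'   per-gene `outdegree`, `indegree`, `degree`) and `n_nodes`/`n_edges`.
#' @export
build_gene_graph <- function(edges) {
  stopifnot(is.data.frame(edges))
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    names(edges)[1:2] <- c("gene_a", "gene_b")
    if (ncol(edges) >= 3) names(edges)[3] <- "combined_score"
  }
  if (!"combined_score" %in% names(edges)) edges$combined_score <- 1000L
  edges <- dplyr::filter(edges, .data$gene_a != .data$gene_b)
  if (nrow(edges) == 0) abort("no edges to build a graph from")

  # directed bookkeeping over distinct ordered pairs, as read
  directed <- dplyr::distinct(edges, .data$gene_a, .data$gene_b)
  out_deg <- table(directed$gene_a)
  in_deg <- table(directed$gene_b)

  # undirected projection: collapse duplicates, keep maximum score
  und <- edges |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$lo, .data$hi) |>
    dplyr::summarise(score = max(.data$combined_score), .groups = "drop")

  g <- igraph::graph_from_data_frame(und, directed = FALSE)
  genes <- igraph::V(g)$name
  degrees <- tibble::tibble(
    gene = genes,
    outdegree = as.integer(out_deg[genes]),
    indegree = as.integer(in_deg[genes]),
    degree = as.integer(igraph::degree(g))
  )
  degrees$outdegree[is.na(degrees$outdegree)] <- 0L
  degrees$indegree[is.na(degrees$indegree)] <- 0L

  res <- structure(
    list(
      graph = g, degrees = degrees,
      n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g)
    ),
    class = "gene_graph"
  )
  ianet_log("build_gene_graph: ", res$n_nodes, " nodes, ", res$n_edges,
            " edges")
  res
}

#' @export
print.gene_graph <- function(x, ...) {
  cat("<gene_graph> ", x$n_nodes, " genes, ", x$n_edges,
      " undirected high-confidence interactions\n", sep = "")
  invisible(x)
}

#' Assign driver / background labels to graph nodes
#'
#' Positives are the intersection of the supplied driver list with the graph
#' nodes; every other node is labelled background (0). Positives lost to the
#' intersection are counted. Labels define the class prior
#' \eqn{\pi = N_+ / (N_+ + N_-)}.
#'
#' @param graph A `gene_graph`.
#' @param positive_genes Character vector of driver gene symbols.
#' @return A tibble with columns `gene` and `label` (integer 0/1), carrying
#'   attributes `n_pos`, `n_neg`, `prior` and `n_lost` (positives absent from
#'   the graph). Warns (does not error) if no positive intersects the graph.
#' @export
assign_labels <- function(graph, positive_genes) {
  stopifnot(inherits(graph, "gene_graph"))
  genes <- igraph::V(graph$graph)$name
  positive_genes <- unique(positive_genes)
  pos <- intersect(positive_genes, genes)
  if (length(pos) == 0) {
    warn("no positive gene intersects the graph; all labels are 0")
  }
  out <- tibble::tibble(
    gene = genes,
    label = as.integer(genes %in% pos)
  )
  attr(out, "n_pos") <- length(pos)
  attr(out, "n_neg") <- length(genes) - length(pos)
  attr(out, "prior") <- length(pos) / length(genes)
  attr(out, "n_lost") <- length(positive_genes) - length(pos)
  ianet_log("assign_labels: ", length(pos), " positives retained of ",
            length(positive_genes), " (", attr(out, "n_lost"), " lost), ",
            attr(out, "n_neg"), " background")
  out
}

#' Class prior (base rate) of the positive class
#'
#' @param labels A labelled gene tibble from [assign_labels()], or any data
#'   frame with a 0/1 `label` column.
#' @return \eqn{N_+ / (N_+ + N_-)}.
#' @examples
#' class_prior(data.frame(label = c(1, 0, 0, 0)))
#' @export
class_prior <- function(labels) {
  stopifnot(is.data.frame(labels), "label" %in% names(labels))
  n <- nrow(labels)
  if (n == 0) abort("no labelled genes")
  sum(labels$label == 1) / n
}
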