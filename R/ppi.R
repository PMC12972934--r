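#' Read a PPI edge list into an undirected simple graph
#'
#' Parses an interaction edge list in either the STRING-export TSV dialect
#' (columns `node1`, `node2`, `combined_score`) or a bare two-column
#' "simple" dialect. Reciprocal duplicate rows are collapsed, self-loops are
#' dropped (with a message), and in the scored dialect edges below
#' `score_threshold` are removed. STRING exports carry scores either as
#' integers on a 0-999 scale or as fractions in [0,1]; the convention is
#' auto-detected from the maximum observed score and can be forced.
#'
#' @param path Path to the edge-list file.
#' @param score_threshold Minimum combined score kept, on the fractional
#'   scale. Default 0.4, STRING's "medium confidence".
#' @param dialect `"string-tsv"` (scored, with header) or `"simple"`
#'   (two whitespace/tab-separated columns, no scores, no threshold).
#' @param score_scale `"auto"` (default), `"fractional"`, or `"integer"`
#'   (0-999; divided by 1000).
#' @return An undirected simple [igraph::igraph] with vertex names and, for
#'   the scored dialect, a `score` edge attribute in [0,1].
#' @export
read_edge_list <- function(path, score_threshold = 0.4,
                           dialect = c("string-tsv", "simple"),
                           score_scale = c("auto", "fractional", "integer")) {
  dialect <- match.arg(dialect)
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) stop("edge list not found: ", path, call. = FALSE)
  if (score_threshold < 0 || score_threshold > 1) {
    stop("score_threshold must be in [0, 1]", call. = FALSE)
  }
  if (dialect == "string-tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "",
                            check.names = FALSE)
    need <- c("node1", "node2")
    if (!all(need %in% names(df))) {
      stop("string-tsv dialect requires columns node1, node2 (got: ",
           paste(names(df), collapse = ", "), ")", call. = FALSE)
    }
    score_col <- intersect(c("combined_score", "score"), names(df))[1]
    if (is.na(score_col)) {
      stop("string-tsv dialect requires a combined_score column",
           call. = FALSE)
    }
    score <- suppressWarnings(as.numeric(df[[score_col]]))
    if (anyNA(score)) {
      bad <- which(is.na(score))[1]
      stop("malformed score in row ", bad, " of ", path, call. = FALSE)
    }
    if (score_scale == "auto") {
      score_scale <- if (max(score) > 1) "integer" else "fractional"
    }
    if (score_scale == "integer") score <- score / 1000
    edges <- data.frame(a = as.character(df$node1),
                        b = as.character(df$node2),
                        score = score, stringsAsFactors = FALSE)
    edges <- edges[edges$score >= score_threshold, , drop = FALSE]
  } else {
    df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                            comment.char = "#")
    if (ncol(df) < 2) stop("simple dialect requires two columns", call. = FALSE)
    # SIF rows "A pp B" are accepted as well as bare pairs "A B"
    if (ncol(df) >= 3 && all(df[[2]] == "pp")) {
      edges <- data.frame(a = as.character(df[[1]]), b = as.character(df[[3]]),
                          stringsAsFactors = FALSE)
    } else {
      edges <- data.frame(a = as.character(df[[1]]), b = as.character(df[[2]]),
                          stringsAsFactors = FALSE)
    }
    edges$score <- NA_real_
  }
  loops <- edges$a == edges$b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  # collapse reciprocal/duplicate rows on the unordered pair
  key <- ifelse(edges$a < edges$b,
                paste(edges$a, edges$b, sep = "\r"),
                paste(edges$b, edges$a, sep = "\r"))
  keep <- !duplicated(key)
  edges <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  if (dialect == "string-tsv") igraph::E(g)$score <- edges$score
  g
}

.topology_feature_cols <- c(
  "degree_centrality", "betweenness", "closeness", "avg_shortest_path_len",
  "n_undirected_edges", "stress", "radiality", "clustering_coeff"
)

#' Node-topology profile of a PPI graph
#'
#' Computes, for every node, the eight topological descriptors used
#' downstream as machine-learning features, plus the maximal clique
#' centrality (MCC). Conventions follow the Cytoscape NetworkAnalyzer
#' toolchain: closeness, average shortest path length and radiality are
#' computed within each node's connected component; betweenness is
#' normalized by (n-1)(n-2)/2 over the whole graph; stress is the raw count
#' of shortest paths (each unordered endpoint pair counted once) passing
#' through the node as an interior vertex; radiality of node v is
#' sum_w (component diameter + 1 - d(v,w)) / (n_component - 1). Isolated
#' nodes get 0 for all distance-based metrics.
#'
#' @param graph An undirected [igraph::igraph].
#' @return A data frame with one row per node: `node`, the eight feature
#'   columns, and `mcc`.
#' @export
compute_topology <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph has no nodes", call. = FALSE)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))

  deg <- igraph::degree(graph)
  degc <- if (n > 1) deg / (n - 1) else rep(0, n)

  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  btw_norm <- if (n > 2) btw / ((n - 1) * (n - 2) / 2) else rep(0, n)

  cc <- igraph::transitivity(graph, type = "local", isolates = "zero")

  comp <- igraph::components(graph)
  d <- igraph::distances(graph)
  closeness <- aspl <- radiality <- numeric(n)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    if (nc == 1L) next  # isolated: all three stay 0
    dc <- d[idx, idx, drop = FALSE]
    diam_c <- max(dc)
    rs <- rowSums(dc)
    closeness[idx] <- (nc - 1) / rs
    aspl[idx] <- rs / (nc - 1)
    radiality[idx] <- rowSums(diam_c + 1 - dc) / (nc - 1) -
      (diam_c + 1) / (nc - 1)  # remove the self term d(v,v)=0
  }

  stress <- stress_centrality(graph)
  mcc <- mcc_scores(graph)

  data.frame(
    node = nodes,
    degree_centrality = degc,
    betweenness = btw_norm,
    closeness = closeness,
    avg_shortest_path_len = aspl,
    n_undirected_edges = deg,
    stress = stress,
    radiality = radiality,
    clustering_coeff = cc,
    mcc = unname(mcc[nodes]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Stress centrality
#'
#' Number of shortest paths passing through each node as an interior vertex,
#' with each unordered endpoint pair counted once.
#'
#' @param graph An undirected [igraph::igraph].
#' @return Named integer-valued numeric vector over the graph's nodes.
#' @export
stress_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  stress <- stats::setNames(numeric(n), nodes)
  if (n < 3L) return(stress)
  for (s in seq_len(n - 1L)) {
    asp <- igraph::all_shortest_paths(graph, from = s, to = (s + 1L):n)
    paths <- asp$vpaths
    if (is.null(paths)) paths <- asp$res
    for (p in paths) {
      iv <- as.integer(p)
      if (length(iv) > 2L) {
        interior <- nodes[iv[-c(1L, length(iv))]]
        stress[interior] <- stress[interior] + 1
      }
    }
  }
  stress
}

#' Maximal clique centrality (MCC)
#'
#' MCC(v) is the sum over all maximal cliques C containing v of (|C|-1)!,
#' the hub-ranking statistic popularized by cytoHubba. An isolated node is
#' its own singleton maximal clique and scores (1-1)! = 1, so MCC >= 1 for
#' every node.
#'
#' @param graph An undirected [igraph::igraph].
#' @param clique_budget Abort if the graph has more maximal cliques than
#'   this (pathologically dense input). Default 1e6.
#' @return Named numeric vector of MCC scores (integer-valued).
#' @export
mcc_scores <- function(graph, clique_budget = 1e6) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph has no nodes", call. = FALSE)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  n_cl <- igraph::count_max_cliques(graph, min = 1)
  if (n_cl > clique_budget) {
    stop("graph has ", n_cl, " maximal cliques, above the budget of ",
         clique_budget, call. = FALSE)
  }
  cliques <- igraph::max_cliques(graph, min = 1)
  mcc <- stats::setNames(numeric(n), nodes)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1L)
    mcc[as.integer(cl)] <- mcc[as.integer(cl)] + w
  }
  mcc
}

#' Top hub nodes by maximal clique centrality
#'
#' Ranks nodes by MCC descending, with ties broken by raw degree descending
#' and then lexicographic symbol order, and returns the leading `k`.
#'
#' @param graph An undirected [igraph::igraph].
#' @param k Number of hubs requested (default 10).
#' @return A data frame `node`, `mcc`, `degree`, `rank` with
#'   `min(k, n)` rows, MCC non-increasing down the rows.
#' @export
top_hubs <- function(graph, k = 10) {
  stopifnot(k >= 1)
  mcc <- mcc_scores(graph)
  deg <- igraph::degree(graph)[names(mcc)]
  ord <- order(-mcc, -deg, names(mcc))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(
    node = names(mcc)[ord],
    mcc = unname(mcc[ord]),
    degree = unname(deg[ord]),
    rank = seq_along(ord),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export a graph and its node attributes for external viewers
#'
#' Writes a SIF edge file (`network.sif`, rows `A pp B`) and a node
#' attribute CSV (`node_attributes.csv`) with the full topological profile,
#' the usual hand-off to Cytoscape-style tools.
#'
#' @param graph An undirected [igraph::igraph].
#' @param topology Data frame from [compute_topology()] (computed if
#'   missing); must cover every node of `graph`.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the two file paths.
#' @export
export_network <- function(graph, topology = NULL, out_dir) {
  if (is.null(topology)) topology <- compute_topology(graph)
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% topology$node)) {
    stop("topology table does not cover every graph node", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  el <- igraph::as_edgelist(graph)
  sif_path <- file.path(out_dir, "network.sif")
  attr_path <- file.path(out_dir, "node_attributes.csv")
  writeLines(if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0),
             sif_path)
  utils::write.csv(topology, attr_path, row.names = FALSE)
  invisible(list(sif = sif_path, attributes = attr_path))
}
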