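string_tsv <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("node1\tnode2\tcombined_score", rows), f)
  f
}

test_that("edge-list ingestion collapses duplicates and drops self-loops", {
  f <- string_tsv(c("A\tB\t0.9", "B\tA\t0.9", "C\tC\t0.5"))
  expect_message(g <- read_edge_list(f), "self-loop")
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
})

test_that("score threshold and scale auto-detection work", {
  f <- string_tsv(c("A\tB\t900", "B\tC\t300", "C\tD\t420"))
  g <- read_edge_list(f, score_threshold = 0.4)   # 0-999 convention
  expect_equal(igraph::ecount(g), 2)
  g_all <- read_edge_list(f, score_threshold = 0)
  expect_equal(igraph::ecount(g_all), 3)
  f2 <- string_tsv(c("A\tB\t0.9", "B\tC\t0.3"))
  expect_equal(igraph::ecount(read_edge_list(f2, 0.4)), 1)
  expect_error(read_edge_list(f, score_threshold = 1.5), "0, 1")
  fbad <- string_tsv(c("A\tB\toops"))
  expect_error(read_edge_list(fbad), "malformed")
})

test_that("simple dialect keeps unscored pairs regardless of threshold", {
  f <- withr::local_tempfile()
  writeLines(c("A B", "B C"), f)
  g <- read_edge_list(f, score_threshold = 0.9, dialect = "simple")
  expect_equal(igraph::ecount(g), 2)
})

test_that("path and complete graphs give the forced metric values", {
  f <- string_tsv(c("A\tB\t0.9", "B\tC\t0.9"))
  topo <- compute_topology(read_edge_list(f))
  b <- topo[topo$node == "B", ]
  expect_equal(b$betweenness, 1.0)
  expect_equal(b$stress, 1)
  expect_equal(b$closeness, 1.0)
  expect_equal(b$mcc, 2)          # two maximal 2-cliques meet at B
  expect_equal(topo$mcc[topo$node == "A"], 1)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- LETTERS[1:4]
  t4 <- compute_topology(k4)
  expect_equal(t4$radiality, rep(1, 4))
  expect_equal(t4$clustering_coeff, rep(1, 4))
  expect_equal(t4$mcc, rep(6, 4))  # one maximal 4-clique, (4-1)! = 6
})

test_that("isolated nodes get zero distance metrics and MCC 1", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("X", "Y", "Z")
  topo <- compute_topology(g)
  expect_equal(topo$avg_shortest_path_len, rep(0, 3))
  expect_equal(topo$radiality, rep(0, 3))
  expect_equal(topo$closeness, rep(0, 3))
  expect_equal(topo$mcc, rep(1, 3))
})

test_that("all topology metrics match the brute-force oracle on random graphs", {
  withr::local_seed(101)
  for (i in 1:30) {
    rg <- rand_graph(sample(4:10, 1), 0.4)
    topo <- compute_topology(rg$g)
    topo <- topo[match(rg$names, topo$node), ]
    oracle <- oracle_topology(rg$adj)
    for (col in names(oracle)) {
      expect_equal(topo[[col]], oracle[[col]], tolerance = 1e-9,
                   ignore_attr = TRUE, label = paste("metric", col))
    }
    expect_equal(sum(topo$n_undirected_edges), 2 * igraph::ecount(rg$g))
  }
})

test_that("MCC matches an independent Bron-Kerbosch enumeration", {
  withr::local_seed(202)
  for (i in 1:30) {
    rg <- rand_graph(sample(4:12, 1), 0.45)
    mcc <- mcc_scores(rg$g)[rg$names]
    expect_equal(unname(mcc), oracle_mcc(rg$adj))
  }
})

test_that("MCC is invariant under node relabeling", {
  withr::local_seed(303)
  rg <- rand_graph(10, 0.4)
  base <- mcc_scores(rg$g)
  for (i in 1:20) {
    perm <- sample(10)
    g2 <- igraph::graph_from_adjacency_matrix(rg$adj[perm, perm],
                                              mode = "undirected")
    igraph::V(g2)$name <- rg$names[perm]
    expect_equal(sort(mcc_scores(g2)[rg$names]), sort(base[rg$names]))
  }
})

test_that("hub ranking sorts by MCC then degree then symbol", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("HUB", "A", "B", "C", "D")
  expect_equal(top_hubs(star, k = 1)$node, "HUB")
  # two K3s (equal MCC); tie broken by degree via a pendant, then by name
  g <- igraph::graph_from_edgelist(rbind(
    c("A", "B"), c("B", "C"), c("A", "C"),
    c("X", "Y"), c("Y", "Z"), c("X", "Z"), c("X", "W")), directed = FALSE)
  hubs <- top_hubs(g, k = 10)
  expect_equal(hubs$node[1], "X")          # mcc 3, degree 3
  expect_true(all(diff(hubs$mcc) <= 0))
  expect_equal(nrow(top_hubs(g, k = 3)), 3)
})

test_that("export writes SIF + attributes and round-trips the edge set", {
  f <- string_tsv(c("A\tB\t0.9", "B\tC\t0.8", "A\tC\t0.7"))
  g <- read_edge_list(f)
  out <- withr::local_tempdir()
  paths <- export_network(g, compute_topology(g), out)
  expect_equal(length(readLines(paths$sif)), 3)
  attrs <- utils::read.csv(paths$attributes)
  expect_equal(nrow(attrs), igraph::vcount(g))
  g2 <- read_edge_list(paths$sif, dialect = "simple")
  same <- igraph::identical_graphs(
    igraph::permute(g, match(igraph::V(g)$name, igraph::V(g2)$name)), g2)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
})

test_that("clique-count budget aborts on pathological density", {
  g <- igraph::make_full_graph(8)
  expect_error(mcc_scores(g, clique_budget = 0), "budget")
})
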