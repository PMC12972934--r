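# Independent brute-force oracles, deliberately implemented without igraph:
# Floyd-Warshall distances, DP geodesic counts, and a plain Bron-Kerbosch
# maximal-clique enumerator. Used to cross-check every topology metric and
# the MCC score on small random graphs.

# all-pairs shortest distances by Floyd-Warshall on an adjacency matrix
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      nd <- d[i, k] + d[k, ]
      upd <- nd < d[i, ]
      d[i, upd] <- nd[upd]
    }
  }
  d
}

# sigma[s, t]: number of shortest s-t paths, by DP in order of distance
geodesic_counts <- function(adj, d) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    reach <- which(is.finite(d[s, ]) & d[s, ] > 0)
    for (t in reach[order(d[s, reach])]) {
      preds <- which(adj[, t] == 1 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  sigma
}

# the full 8-metric oracle profile, matching compute_topology's conventions
oracle_topology <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  sigma <- geodesic_counts(adj, d)
  deg <- rowSums(adj)
  degc <- if (n > 1) deg / (n - 1) else rep(0, n)

  btw <- stress <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      for (s in seq_len(n - 1)) {
        for (t in (s + 1):n) {
          if (s == v || t == v || !is.finite(d[s, t])) next
          if (d[s, v] + d[v, t] == d[s, t]) {
            through <- sigma[s, v] * sigma[v, t]
            stress[v] <- stress[v] + through
            btw[v] <- btw[v] + through / sigma[s, t]
          }
        }
      }
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }

  clo <- aspl <- rad <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(d[v, ]))
    nc <- length(comp)
    if (nc < 2) next
    dc <- d[v, setdiff(comp, v)]
    diam <- max(d[comp, comp])
    clo[v] <- (nc - 1) / sum(dc)
    aspl[v] <- sum(dc) / (nc - 1)
    rad[v] <- sum(diam + 1 - dc) / (nc - 1)
  }

  cc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(length(nb), 2)
  }, numeric(1))

  data.frame(degree_centrality = degc, betweenness = btw, closeness = clo,
             avg_shortest_path_len = aspl, n_undirected_edges = deg,
             stress = stress, radiality = rad, clustering_coeff = cc)
}

# plain Bron-Kerbosch (no pivoting), then MCC = sum (|C|-1)! per node
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      cliques[[length(cliques) + 1]] <<- r
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ] == 1)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  mcc <- numeric(n)
  for (cl in cliques) mcc[cl] <- mcc[cl] + factorial(length(cl) - 1)
  mcc
}

# exhaustive upper-tail hypergeometric probability by direct pmf summation
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Erdos-Renyi adjacency matrix plus the matching igraph, named a, b, c, ...
rand_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  nm <- make.unique(rep(letters, length.out = n), sep = "")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- nm
  list(adj = adj, g = g, names = nm)
}
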