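# Independent brute-force oracles for graph centralities, working directly on
# adjacency matrices (no call into the package's centrality code paths).

# all-pairs shortest-path distances by Floyd-Warshall
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

# number of shortest s-t paths through each vertex, by exhaustive DFS path
# enumeration (feasible for the tiny graphs used in tests)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  bw <- numeric(n)
  enumerate_paths <- function(current, target, len) {
    if (current == target) return(list(current))
    if (len == 0) return(list())
    out <- list()
    for (nb in which(adj[current, ] > 0)) {
      if (d[nb, target] == len - 1) {
        for (p in enumerate_paths(nb, target, len - 1)) {
          out[[length(out) + 1L]] <- c(current, p)
        }
      }
    }
    out
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] == 0) next
      paths <- enumerate_paths(s, t, d[s, t])
      sigma <- length(paths)
      if (sigma == 0) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        bw[interior] <- bw[interior] + 1 / sigma
      }
    }
  }
  bw
}

# centroid value by direct gamma counting from the distance matrix
oracle_centroid <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    comp <- which(is.finite(d[v, ]))
    others <- setdiff(comp, v)
    if (length(others) == 0) {
      out[v] <- 0
      next
    }
    fvals <- sapply(others, function(w) {
      gamma_vw <- sum(d[comp, v] < d[comp, w])
      gamma_wv <- sum(d[comp, w] < d[comp, v])
      gamma_vw - gamma_wv
    })
    out[v] <- min(fvals)
  }
  out
}

random_test_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  adj <- adj + t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n))
  list(graph = g, adj = adj)
}

# small named graph from an edge list given as c("a","b", "b","c", ...)
graph_from_pairs <- function(pairs, isolated = character(0)) {
  el <- matrix(pairs, ncol = 2, byrow = TRUE)
  igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2]),
    directed = FALSE,
    vertices = data.frame(name = unique(c(as.vector(t(el)), isolated))))
}

# Spearman rho by the classical d^2 formula (valid for tie-free data)
rho_d2 <- function(x, y) {
  n <- length(x)
  dd <- rank(x) - rank(y)
  1 - 6 * sum(dd^2) / (n * (n^2 - 1))
}

edge_keys_for_test <- function(net) {
  if (igraph::ecount(net) == 0L) return(character(0))
  el <- igraph::as_edgelist(net)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

# hand-built correlation_result for threshold-logic tests
fake_cres <- function(proteins, rho_pairs, n_used = 13) {
  k <- length(proteins)
  rho <- diag(k); p <- matrix(1, k, k); diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(proteins, proteins)
  for (rp in rho_pairs) {
    i <- rp[[1]]; j <- rp[[2]]
    rho[i, j] <- rho[j, i] <- rp[[3]]
    p[i, j] <- p[j, i] <- rp[[4]]
  }
  structure(list(rho = rho, p = p, n_used = n_used, proteins = proteins,
                 dropped = character(0)), class = "correlation_result")
}

read_tsv_for_test <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
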