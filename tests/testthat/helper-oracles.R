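# Independent brute-force oracles used to validate the graph machinery.
# These enumerate simple paths exhaustively and are practical only for tiny
# graphs (n <= 8), which is exactly their point: they share no code path
# with the implementations they check.

# Enumerate every simple path between two vertices of a small undirected
# graph given as an edge data frame (i, j, length).
enumerate_paths <- function(adj, from, to) {
  paths <- list()
  walk <- function(v, visited, edges_used, len) {
    if (v == to) {
      paths[[length(paths) + 1L]] <<- list(len = len, edges = edges_used,
                                           nodes = visited)
      return(invisible())
    }
    for (k in seq_len(nrow(adj))) {
      nxt <- if (adj$i[k] == v) adj$j[k] else if (adj$j[k] == v) adj$i[k]
             else next
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(edges_used, k), len + adj$len[k])
    }
  }
  walk(from, from, integer(0), 0)
  paths
}

# Fractional betweenness by exhaustive shortest-path enumeration.
# Returns list(node = numeric(n), edge = numeric(nrow(adj))).
brute_force_betweenness <- function(n, adj, tol = 1e-9) {
  node_sc <- numeric(n)
  edge_sc <- numeric(nrow(adj))
  if (nrow(adj) == 0L) return(list(node = node_sc, edge = edge_sc))
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- enumerate_paths(adj, s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      shortest <- paths[lens <= min(lens) + tol]
      cnt <- length(shortest)
      for (p in shortest) {
        edge_sc[p$edges] <- edge_sc[p$edges] + 1 / cnt
        interior <- setdiff(p$nodes, c(s, t))
        node_sc[interior] <- node_sc[interior] + 1 / cnt
      }
    }
  }
  list(node = node_sc, edge = edge_sc)
}

# Direct double-sum modularity oracle:
# Q = (1/2W) sum_ij (w_ij - s_i s_j / 2W) delta(m_i, m_j)
# over the full symmetric weight matrix (diagonal zero).
modularity_double_sum <- function(wmat, memb) {
  W <- sum(wmat) / 2
  s <- rowSums(wmat)
  q <- 0
  n <- nrow(wmat)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + wmat[i, j] - s[i] * s[j] / (2 * W)
      }
    }
  }
  q / (2 * W)
}

# Random small weighted graph; lengths are -log(weight) so weight in
# (0.5, 0.99) keeps all lengths positive and generic (no accidental ties).
random_small_graph <- function(n, p = 0.5) {
  adj <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) {
        w <- stats::runif(1, 0.5, 0.99)
        adj <- rbind(adj, data.frame(i = i, j = j, w = w, len = -log(w)))
      }
    }
  }
  if (is.null(adj)) adj <- data.frame(i = integer(), j = integer(),
                                      w = numeric(), len = numeric())
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(adj) > 0L) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(adj[, c("i", "j")]))))
    g <- igraph::set_edge_attr(g, "weight", value = adj$w)
    g <- igraph::set_edge_attr(g, "length", value = adj$len)
  }
  list(g = g, adj = adj, n = n)
}

# Unit-length graph from an explicit edge list (for hand-computed examples).
unit_graph <- function(n, edges, len = 1) {
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  g <- igraph::add_edges(g, as.vector(t(edges)))
  g <- igraph::set_edge_attr(g, "weight", value = rep(1, nrow(edges)))
  g <- igraph::set_edge_attr(g, "length", value = rep(len, nrow(edges)))
  g
}

# Structure model straight from coordinates.
model_from_xyz <- function(xyz, resno = seq_len(nrow(xyz))) {
  structure_model(data.frame(
    chain = "A", resno = resno, ins = "", resid = "ALA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
}

# The two-triangles-plus-bridge graph used across the network tests:
# vertices 1:3 and 4:6 are triangles, 3-4 is the bridge; all unit weights.
two_triangle_bridge <- function() {
  unit_graph(6, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4),
                      c(4, 5), c(4, 6), c(5, 6)))
}
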