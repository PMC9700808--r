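#' Build a weighted residue graph from cross-correlations
#'
#' Residues i and j are joined iff their motions are strongly coupled
#' (`|c_ij| >= min_abs_corr`) AND they are spatially close
#' (`d_ij <= contact_cutoff`). The contact mask keeps the graph from becoming
#' a dense all-to-all correlation network. Edge weight is `|c_ij|` in (0, 1];
#' edge length for shortest-path computations is `-log |c_ij|`, so perfectly
#' coupled residues are at distance 0. The sign of the correlation is kept as
#' edge metadata but plays no role in clustering.
#'
#' @param cmat Correlation matrix (see [cross_correlation()]).
#' @param d Distance matrix in angstroms, same dimension and order.
#' @param min_abs_corr Correlation threshold in (0, 1). Default 0.5.
#' @param contact_cutoff Spatial cutoff in angstroms. Default 10.
#' @return A `residue_graph`: an igraph object (undirected, no self-loops)
#'   with vertex names taken from the matrix dimnames and edge attributes
#'   `weight`, `length`, `sign`.
#' @export
build_residue_graph <- function(cmat, d, min_abs_corr = 0.5,
                                contact_cutoff = 10) {
  stopifnot(is.matrix(cmat), is.matrix(d),
            all(dim(cmat) == dim(d)),
            min_abs_corr > 0, min_abs_corr < 1)
  n <- nrow(cmat)
  ids <- rownames(cmat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  keep <- abs(cmat) >= min_abs_corr & d <= contact_cutoff
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(idx) > 0L) {
    w <- abs(cmat[idx])
    g <- igraph::add_edges(g, as.vector(t(idx)))
    g <- igraph::set_edge_attr(g, "weight", value = w)
    g <- igraph::set_edge_attr(g, "length", value = -log(w))
    g <- igraph::set_edge_attr(g, "sign", value = sign(cmat[idx]))
  }
  iso <- ids[igraph::degree(g) == 0]
  if (length(iso)) {
    warning("isolated residues in network: ",
            paste(utils::head(iso, 10L), collapse = ", "),
            if (length(iso) > 10L) " ...")
  }
  class(g) <- c("residue_graph", class(g))
  g
}

# igraph insists on strictly positive shortest-path weights; edges with
# |c| = 1 have true length 0 and are clamped to an epsilon that cannot
# reorder any path.
path_lengths <- function(g) {
  len <- igraph::E(g)$length
  if (is.null(len)) len <- rep(1, igraph::ecount(g))
  pmax(len, 1e-12)
}

#' Edge betweenness of a residue graph
#'
#' For each edge, the sum over unordered vertex pairs of the fraction of
#' shortest paths (by edge length `-log w`) running through it; each pair is
#' counted once, and degenerate shortest paths contribute fractionally.
#'
#' @param g A `residue_graph` (any undirected igraph works).
#' @return Numeric vector, one score per edge, named `i|j` by the edge's
#'   endpoint names.
#' @export
edge_betweenness_profile <- function(g) {
  if (igraph::ecount(g) == 0L) return(numeric(0))
  eb <- igraph::edge_betweenness(g, directed = FALSE, weights = path_lengths(g))
  ends <- igraph::as_edgelist(g, names = TRUE)
  names(eb) <- paste(ends[, 1L], ends[, 2L], sep = "|")
  eb
}

#' Node betweenness centrality of a residue graph
#'
#' Per residue, the (fractional) count of shortest paths between other
#' residue pairs passing through it, over correlation-weighted path lengths.
#' Residues with high centrality act as conduits of coupled oscillation;
#' leaves score 0.
#'
#' @param g A `residue_graph`.
#' @return Named numeric vector of non-negative scores.
#' @export
node_betweenness_profile <- function(g) {
  igraph::betweenness(g, directed = FALSE, weights = path_lengths(g))
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_m [ w_in(m)/W - (s(m)/2W)^2 ]` where `W` is the total edge
#' weight, `w_in(m)` the weight inside module m and `s(m)` the summed
#' weighted degree of its members. A graph with no edges has `Q = 0` by
#' convention.
#'
#' @param g A `residue_graph`.
#' @param partition Either a membership vector (one integer per vertex, in
#'   vertex order or named by vertex) or a list of disjoint vertex-name sets
#'   covering the graph.
#' @return Modularity Q in `[-0.5, 1]`.
#' @export
graph_modularity <- function(g, partition) {
  memb <- as_membership(g, partition)
  m <- igraph::ecount(g)
  if (m == 0L) return(0)
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, m)
  ends <- igraph::as_edgelist(g, names = FALSE)
  W <- sum(w)
  deg <- numeric(igraph::vcount(g))
  for (e in seq_len(m)) {
    deg[ends[e, 1L]] <- deg[ends[e, 1L]] + w[e]
    deg[ends[e, 2L]] <- deg[ends[e, 2L]] + w[e]
  }
  q <- 0
  for (mod in unique(memb)) {
    members <- which(memb == mod)
    inside <- memb[ends[, 1L]] == mod & memb[ends[, 2L]] == mod
    q <- q + sum(w[inside]) / W - (sum(deg[members]) / (2 * W))^2
  }
  q
}

#' Girvan-Newman community detection on a residue graph
#'
#' Iteratively removes the edge with the highest betweenness, recomputing
#' betweenness after every removal (igraph's C implementation of the
#' recalculation loop; equal-betweenness ties follow its fixed edge order,
#' so repeated runs are identical). After each removal the
#' connected-component partition is scored by weighted modularity on the
#' original graph; the partition attaining maximal Q is returned (the
#' earliest one on ties). An edgeless graph yields singleton modules with
#' Q = 0.
#'
#' @param g A `residue_graph`.
#' @return A `community_partition`: list with `modules` (list of vertex-name
#'   sets, indexed in order of each module's smallest member), `membership`
#'   (named integer vector), `modularity_q`, and `n_modules`.
#' @export
girvan_newman_partition <- function(g) {
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  m <- igraph::ecount(g)
  if (m == 0L) return(community_partition(seq_len(n), vnames, 0))

  # removal order of the edge-betweenness recalculation loop (C engine);
  # betweenness uses the clamped -log(weight) path lengths
  removal <- igraph::cluster_edge_betweenness(
    g, weights = path_lengths(g), directed = FALSE,
    modularity = FALSE, membership = FALSE)$removed.edges

  ends0 <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(ends0) <- "integer"
  w0 <- igraph::E(g)$weight
  if (is.null(w0)) w0 <- rep(1, m)
  W <- sum(w0)
  deg0 <- numeric(n)
  for (e in seq_len(m)) {
    deg0[ends0[e, 1L]] <- deg0[ends0[e, 1L]] + w0[e]
    deg0[ends0[e, 2L]] <- deg0[ends0[e, 2L]] + w0[e]
  }
  q_of <- function(memb) {
    inside <- memb[ends0[, 1L]] == memb[ends0[, 2L]]
    s <- tapply(deg0, memb, sum)
    sum(w0[inside]) / W - sum((s / (2 * W))^2)
  }

  # Replay the removal sequence backwards with a union-find: the partition
  # after r removals is the component partition over the edges removed last.
  # Q (always scored against the original graph) changes only when two
  # components merge, so it is recomputed just at merge events.
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  memb_now <- function() vapply(seq_len(n), find, integer(1))
  qs <- numeric(m + 1L)                      # qs[r + 1] = Q after r removals
  qs[m + 1L] <- q_of(seq_len(n))             # all edges removed: singletons
  for (t in m:1) {
    e <- removal[t]
    ri <- find(ends0[e, 1L]); rj <- find(ends0[e, 2L])
    if (ri != rj) {
      parent[ri] <- rj
      qs[t] <- q_of(memb_now())
    } else {
      qs[t] <- qs[t + 1L]
    }
  }
  best_r <- which.max(qs) - 1L               # earliest removal state on ties
  best_q <- qs[best_r + 1L]

  parent <- seq_len(n)
  if (best_r < m) {
    for (t in (best_r + 1L):m) {
      e <- removal[t]
      ri <- find(ends0[e, 1L]); rj <- find(ends0[e, 2L])
      if (ri != rj) parent[ri] <- rj
    }
  }
  community_partition(memb_now(), vnames, best_q)
}

# Canonical form: modules indexed 1..M in order of their smallest member
# (by vertex position), membership renumbered to match.
community_partition <- function(memb, vnames, q) {
  memb <- as.integer(memb)
  first_seen <- vapply(split(seq_along(memb), memb), min, integer(1))
  relabel <- rank(first_seen)
  new_memb <- relabel[match(memb, as.integer(names(first_seen)))]
  names(new_memb) <- vnames
  modules <- split(vnames, new_memb)
  names(modules) <- NULL
  out <- list(modules = modules, membership = new_memb,
              modularity_q = q, n_modules = length(modules))
  class(out) <- "community_partition"
  out
}

#' @export
print.community_partition <- function(x, ...) {
  cat("community_partition:", x$n_modules, "modules, Q =",
      signif(x$modularity_q, 4), "\n")
  sizes <- lengths(x$modules)
  cat("module sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two community partitions around a flagged residue set
#'
#' Reports how a set of residues of interest (e.g. modified lysines) is
#' distributed over the modules of each partition. Module labels are
#' arbitrary, so the comparison uses the *dispersion* of the flagged set --
#' the number of distinct modules hosting flagged residues -- never label
#' identity.
#'
#' @param pa,pb `community_partition` objects for the two structures.
#' @param flagged Character vector of residue ids present in both partitions.
#' @return A `partition_comparison`: list with module counts `m_a`, `m_b`,
#'   the module indices hosting flagged residues in each
#'   (`flagged_modules_a`, `flagged_modules_b`), dispersion counts
#'   `dispersion_a`, `dispersion_b`, and `delta_q = Q_b - Q_a`.
#' @export
compare_partitions <- function(pa, pb, flagged) {
  stopifnot(inherits(pa, "community_partition"),
            inherits(pb, "community_partition"))
  flagged <- as.character(flagged)
  for (nm in list(a = pa, b = pb)) {
    missing <- setdiff(flagged, names(nm$membership))
    if (length(missing)) {
      stop("flagged residues absent from partition: ",
           paste(missing, collapse = ", "))
    }
  }
  mods_a <- sort(unique(unname(pa$membership[flagged])))
  mods_b <- sort(unique(unname(pb$membership[flagged])))
  out <- list(
    m_a = pa$n_modules, m_b = pb$n_modules,
    flagged_modules_a = mods_a, flagged_modules_b = mods_b,
    dispersion_a = length(mods_a), dispersion_b = length(mods_b),
    delta_q = pb$modularity_q - pa$modularity_q
  )
  class(out) <- "partition_comparison"
  out
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat("partition_comparison\n")
  cat(sprintf("  modules:            A = %d, B = %d\n", x$m_a, x$m_b))
  cat(sprintf("  flagged modules A:  %s\n",
              paste(x$flagged_modules_a, collapse = ", ")))
  cat(sprintf("  flagged modules B:  %s\n",
              paste(x$flagged_modules_b, collapse = ", ")))
  cat(sprintf("  flagged dispersion: A = %d, B = %d\n",
              x$dispersion_a, x$dispersion_b))
  cat(sprintf("  delta Q (B - A):    %+0.4f\n", x$delta_q))
  invisible(x)
}

#' Write a residue graph as an edge-list TSV
#'
#' Columns: `i`, `j`, `weight`, `length`, `sign`.
#'
#' @param g A `residue_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  ends <- igraph::as_edgelist(g, names = TRUE)
  m <- igraph::ecount(g)
  grab <- function(attr, fallback) {
    v <- igraph::edge_attr(g, attr)
    if (is.null(v)) rep(fallback, m) else v
  }
  df <- data.frame(i = ends[, 1L], j = ends[, 2L],
                   weight = grab("weight", 1),
                   length = grab("length", NA_real_),
                   sign = grab("sign", NA_real_),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a community partition as TSV
#'
#' Columns: `residue_id`, `module_index`.
#'
#' @param p A `community_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(p, path) {
  df <- data.frame(residue_id = names(p$membership),
                   module_index = unname(p$membership),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- internal -----------------------------------------------------------------

as_membership <- function(g, partition) {
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (is.list(partition)) {
    all_members <- unlist(partition, use.names = FALSE)
    if (anyDuplicated(all_members) ||
        !setequal(as.character(all_members), vnames)) {
      stop("partition is not a disjoint cover of the graph's vertices")
    }
    memb <- integer(n)
    for (i in seq_along(partition)) {
      memb[match(as.character(partition[[i]]), vnames)] <- i
    }
    return(memb)
  }
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), vnames)) {
      stop("partition names do not cover the graph's vertices")
    }
    return(as.integer(partition[vnames]))
  }
  if (length(partition) != n) stop("membership length != vertex count")
  as.integer(partition)
}
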