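test_that("build_residue_graph applies the correlation-and-contact edge rule", {
  n <- 4
  cmat <- diag(n)
  cmat[upper.tri(cmat)] <- cmat[lower.tri(cmat)] <- 0.1
  d <- matrix(5, n, n); diag(d) <- 0
  g <- suppressWarnings(build_residue_graph(cmat, d, min_abs_corr = 0.5,
                                            contact_cutoff = 10))
  expect_equal(igraph::ecount(g), 0L)

  # 3-bead path with perfect correlation on contacts -> edges of length 0
  cmat <- rbind(c(1, 1, 0.2), c(1, 1, 1), c(0.2, 1, 1))
  d <- rbind(c(0, 6, 12), c(6, 0, 6), c(12, 6, 0))
  g <- build_residue_graph(cmat, d, min_abs_corr = 0.5, contact_cutoff = 10)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::E(g)$length, c(0, 0))
})

test_that("edge sets match a double-loop filter oracle on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    raw <- matrix(runif(n * n, -1, 1), n)
    cmat <- (raw + t(raw)) / 2; diag(cmat) <- 1
    d <- ca_distance_matrix(model_from_xyz(matrix(rnorm(3 * n, sd = 4),
                                                  ncol = 3)))
    g <- suppressWarnings(build_residue_graph(cmat, d, 0.5, 10))
    expected <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (abs(cmat[i, j]) >= 0.5 && d[i, j] <= 10) {
        expected <- expected + 1L
        expect_true(igraph::are_adjacent(g, i, j))
        eid <- igraph::get_edge_ids(g, c(i, j))
        expect_equal(igraph::E(g)$weight[eid], abs(cmat[i, j]))
        expect_equal(igraph::E(g)$sign[eid], sign(cmat[i, j]))
      }
    }
    expect_equal(igraph::ecount(g), expected)
  }
})

test_that("isolated residues trigger a warning listing them", {
  cmat <- diag(3); cmat[1, 2] <- cmat[2, 1] <- 0.9
  d <- matrix(3, 3, 3); diag(d) <- 0
  dimnames(cmat) <- dimnames(d) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_warning(build_residue_graph(cmat, d, 0.5, 10), "c")
})

test_that("betweenness matches hand-computed examples", {
  triangle <- unit_graph(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(unname(edge_betweenness_profile(triangle)), rep(1, 3))

  bridge <- two_triangle_bridge()
  eb <- edge_betweenness_profile(bridge)
  expect_equal(unname(which.max(eb)), 4L)  # the 3-4 bridge edge
  expect_named(eb)

  single <- unit_graph(2, rbind(c(1, 2)))
  expect_equal(unname(edge_betweenness_profile(single)), 1)

  path5 <- unit_graph(5, cbind(1:4, 2:5))
  nb <- node_betweenness_profile(path5)
  expect_equal(unname(nb[3]), 4)   # pairs (1,4),(1,5),(2,4),(2,5)
  expect_equal(unname(nb[c(1, 5)]), c(0, 0))  # leaves

  star <- unit_graph(5, cbind(1, 2:5))
  expect_equal(unname(node_betweenness_profile(star)[1]), 6)  # C(4,2)
})

test_that("betweenness equals exhaustive enumeration on small graphs", {
  set.seed(77)
  for (rep in 1:40) {
    rg <- random_small_graph(sample(4:8, 1))
    if (nrow(rg$adj) == 0L) next
    oracle <- brute_force_betweenness(rg$n, rg$adj)
    expect_equal(unname(node_betweenness_profile(rg$g)), oracle$node,
                 tolerance = 1e-8)
    expect_equal(unname(edge_betweenness_profile(rg$g)), oracle$edge,
                 tolerance = 1e-8)
  }
})

test_that("graph_modularity matches conventions and the double-sum oracle", {
  bridge <- two_triangle_bridge()
  all_one <- rep(1L, 6)
  expect_equal(graph_modularity(bridge, all_one), 0)
  split <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(graph_modularity(bridge, split), 5 / 14)

  set.seed(13)
  for (rep in 1:10) {
    rg <- random_small_graph(sample(5:8, 1), p = 0.6)
    if (nrow(rg$adj) == 0L) next
    memb <- sample(1:3, rg$n, replace = TRUE)
    wmat <- matrix(0, rg$n, rg$n)
    for (k in seq_len(nrow(rg$adj))) {
      wmat[rg$adj$i[k], rg$adj$j[k]] <- rg$adj$w[k]
      wmat[rg$adj$j[k], rg$adj$i[k]] <- rg$adj$w[k]
    }
    expect_equal(graph_modularity(rg$g, memb),
                 modularity_double_sum(wmat, memb), tolerance = 1e-12)
    # cross-check against igraph's weighted implementation
    expect_equal(graph_modularity(rg$g, memb),
                 igraph::modularity(rg$g, memb, weights = igraph::E(rg$g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("graph_modularity validates its partition argument", {
  bridge <- two_triangle_bridge()
  expect_error(graph_modularity(bridge, list(c("1", "2"), c("2", "3"))),
               "not a disjoint cover")
  expect_error(graph_modularity(bridge, rep(1L, 5)), "length")
})

test_that("girvan_newman_partition recovers planted communities", {
  bridge <- two_triangle_bridge()
  p <- girvan_newman_partition(bridge)
  expect_equal(p$n_modules, 2L)
  expect_equal(p$modules, list(c("1", "2", "3"), c("4", "5", "6")))
  expect_equal(p$modularity_q, 5 / 14, tolerance = 1e-12)

  cliques <- unit_graph(8, rbind(
    c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4),
    c(5, 6), c(5, 7), c(5, 8), c(6, 7), c(6, 8), c(7, 8)))
  p2 <- girvan_newman_partition(cliques)
  expect_equal(p2$n_modules, 2L)
  expect_equal(p2$modules, list(as.character(1:4), as.character(5:8)))

  single <- unit_graph(2, rbind(c(1, 2)))
  p3 <- girvan_newman_partition(single)
  expect_equal(p3$n_modules, 1L)
  expect_equal(p3$modularity_q, 0)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  p4 <- girvan_newman_partition(edgeless)
  expect_equal(p4$n_modules, 3L)
  expect_equal(p4$modularity_q, 0)
})

test_that("partition output is internally consistent and deterministic", {
  set.seed(5)
  for (rep in 1:6) {
    rg <- random_small_graph(8, p = 0.5)
    if (igraph::ecount(rg$g) == 0L) next
    p <- girvan_newman_partition(rg$g)
    # returned Q matches modularity() recomputed on the returned partition
    expect_equal(p$modularity_q, graph_modularity(rg$g, p$membership),
                 tolerance = 1e-12)
    # never worse than the trivial one-module partition
    expect_gte(p$modularity_q, 0 - 1e-12)
    # modules indexed by smallest member, disjoint cover
    firsts <- vapply(p$modules, function(m) min(match(m, names(p$membership))),
                     numeric(1))
    expect_equal(firsts, sort(firsts))
    expect_setequal(unlist(p$modules), names(p$membership))
    # repeated runs bit-identical
    expect_identical(p, girvan_newman_partition(rg$g))
  }
})

test_that("compare_partitions reports dispersion, not labels", {
  memb_a <- c(a = 1L, b = 1L, c = 1L, d = 2L, e = 2L)
  memb_b <- c(a = 1L, b = 2L, c = 3L, d = 3L, e = 3L)
  pa <- strucnet:::community_partition(memb_a, names(memb_a), 0.30)
  pb <- strucnet:::community_partition(memb_b, names(memb_b), 0.25)
  cmp <- compare_partitions(pa, pb, c("a", "b", "c"))
  expect_equal(cmp$dispersion_a, 1L)
  expect_equal(cmp$dispersion_b, 3L)
  expect_equal(cmp$delta_q, -0.05)

  same <- compare_partitions(pa, pa, c("a", "d"))
  expect_equal(same$dispersion_a, same$dispersion_b)
  expect_equal(same$m_a, same$m_b)
  expect_equal(same$delta_q, 0)

  expect_error(compare_partitions(pa, pb, c("a", "z")), "z")
})

test_that("graph and partition writers emit well-formed TSV", {
  bridge <- two_triangle_bridge()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(bridge, tf)
  edges <- utils::read.delim(tf)
  expect_named(edges, c("i", "j", "weight", "length", "sign"))
  expect_equal(nrow(edges), 7L)

  tp <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(girvan_newman_partition(bridge), tp)
  part <- utils::read.delim(tp)
  expect_named(part, c("residue_id", "module_index"))
  expect_equal(sort(unique(part$module_index)), 1:2)
})
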