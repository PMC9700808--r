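two_bead <- function() {
  d <- matrix(c(0, 5, 5, 0), 2, 2)
  build_kirchhoff(d, cutoff_rc = 7.3)
}

# three beads in a row, spaced so only neighbors touch
three_bead_path <- function() {
  xyz <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0))
  build_kirchhoff(ca_distance_matrix(model_from_xyz(xyz)), cutoff_rc = 7.3)
}

test_that("build_kirchhoff produces contact Laplacians", {
  expect_equal(unname(two_bead()$gamma), matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(unname(three_bead_path()$gamma),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))

  s <- make_chain(chain_spec(20, seed = 9))
  d <- ca_distance_matrix(s)
  k <- build_kirchhoff(d, cutoff_rc = 7.3)
  expect_equal(unname(rowSums(k$gamma)), rep(0, 20))
  # double-loop construction oracle
  ref <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    if (i != j && d[i, j] <= 7.3) ref[i, j] <- -1
  }
  diag(ref) <- -rowSums(ref)
  expect_equal(unname(k$gamma), ref)
})

test_that("build_kirchhoff flags contactless residues and graphs", {
  far <- model_from_xyz(rbind(c(0, 0, 0), c(3, 0, 0), c(50, 0, 0)))
  expect_warning(build_kirchhoff(ca_distance_matrix(far), 7.3),
                 "zero contacts")
  lonely <- model_from_xyz(rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0)))
  expect_error(build_kirchhoff(ca_distance_matrix(lonely), 7.3),
               "disconnected contact graph")
})

test_that("decompose recovers analytic spectra and the trace identity", {
  m2 <- decompose(two_bead())
  expect_equal(m2$values, c(0, 2), tolerance = 1e-12)
  expect_equal(m2$n_null, 1L)

  m3 <- decompose(three_bead_path())
  expect_equal(m3$values, c(0, 1, 3), tolerance = 1e-12)

  k <- build_kirchhoff(ca_distance_matrix(make_chain(chain_spec(25, seed = 4))),
                       7.3)
  m <- decompose(k)
  expect_equal(sum(m$values), sum(diag(k$gamma)))
  # orthonormal eigenvectors
  expect_equal(crossprod(m$vectors), diag(25), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("decompose rejects disconnected contact graphs", {
  # two dimers far apart: valid Laplacian, two null modes
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(100, 0, 0), c(103, 0, 0))
  k <- build_kirchhoff(ca_distance_matrix(model_from_xyz(xyz)), 7.3)
  expect_error(decompose(k), "disconnected contact graph")
})

test_that("null mode count matches graph components (traversal oracle)", {
  set.seed(21)
  for (rep in 1:8) {
    n <- sample(6:15, 1)
    xyz <- matrix(rnorm(3 * n, sd = 6), ncol = 3)
    d <- ca_distance_matrix(model_from_xyz(xyz))
    contact <- d <= 7.3; diag(contact) <- FALSE
    if (!any(contact)) next
    g <- igraph::graph_from_adjacency_matrix(contact, mode = "undirected")
    n_comp <- igraph::components(g)$no
    k <- suppressWarnings(build_kirchhoff(d, 7.3))
    ev <- eigen(k$gamma, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev < 1e-8 * max(ev)), n_comp)
  }
})

test_that("cross_correlation is the normalized Kirchhoff pseudo-inverse", {
  cc2 <- cross_correlation(decompose(two_bead()))
  expect_equal(unname(cc2), rbind(c(1, -1), c(-1, 1)), tolerance = 1e-12)

  k3 <- three_bead_path()
  cc3 <- cross_correlation(decompose(k3))
  expect_equal(unname(diag(cc3)), rep(1, 3))
  pinv <- MASS::ginv(k3$gamma)
  ref <- pinv / sqrt(outer(diag(pinv), diag(pinv)))
  expect_equal(unname(cc3), ref, tolerance = 1e-10)

  s <- make_chain(chain_spec(30, seed = 12))
  k <- build_kirchhoff(ca_distance_matrix(s), 7.3)
  cc <- cross_correlation(decompose(k))
  pinv <- MASS::ginv(k$gamma)
  expect_equal(unname(cc), pinv / sqrt(outer(diag(pinv), diag(pinv))),
               tolerance = 1e-8)
  expect_true(all(abs(cc) <= 1 + 1e-12))
})

test_that("correlations are invariant under rigid motions", {
  s <- make_chain(chain_spec(25, seed = 3))
  xyz <- as.matrix(s[, c("x", "y", "z")])
  set.seed(99)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_rot) < 0) qr_rot[, 1] <- -qr_rot[, 1]
  moved <- model_from_xyz(xyz %*% qr_rot +
                          matrix(c(10, -4, 2), nrow(xyz), 3, byrow = TRUE))
  cc_a <- cross_correlation(decompose(build_kirchhoff(ca_distance_matrix(s), 7.3)))
  cc_b <- cross_correlation(decompose(build_kirchhoff(ca_distance_matrix(moved), 7.3)))
  expect_equal(cc_a, cc_b, tolerance = 1e-9)
})

test_that("truncated-mode correlations converge to the all-mode answer", {
  s <- make_chain(chain_spec(20, seed = 8))
  m <- decompose(build_kirchhoff(ca_distance_matrix(s), 7.3))
  full <- cross_correlation(m, "all")
  errs <- vapply(c(2, 5, 10, 19), function(nm) {
    max(abs(cross_correlation(m, nm) - full))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-10)
})

test_that("mean-square fluctuations follow the mode spectrum", {
  expect_equal(unname(mean_square_fluctuations(decompose(two_bead()))),
               c(0.25, 0.25))
  msf3 <- mean_square_fluctuations(decompose(three_bead_path()))
  expect_equal(unname(msf3[1]), unname(msf3[3]))  # path-end symmetry
})

test_that("a loosened tail fluctuates more than the helical core", {
  # the loosened segment sits at the terminus: a floppy tail swings freely,
  # whereas an interior linker is a low-amplitude hinge between two lobes
  segs <- data.frame(start = c(1, 51), end = c(50, 70),
                     packing = c("compact", "loose"))
  s <- make_chain(chain_spec(70, segs, seed = 6))
  msf <- mean_square_fluctuations(decompose(
    build_kirchhoff(ca_distance_matrix(s), 7.3)))
  expect_gt(mean(msf[55:70]), mean(msf[5:46]))
})

test_that("GNM agrees with an independent structural-bioinformatics oracle", {
  s <- make_chain(chain_spec(40, seed = 3))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, tf)
  # bio3d warns about CA-only traces looking multi-chain; harmless here
  ref <- suppressWarnings(bio3d::gnm(bio3d::read.pdb(tf), cutoff = 7.3))

  m <- decompose(build_kirchhoff(ca_distance_matrix(s), 7.3))
  cc <- cross_correlation(m)
  expect_equal(unname(unclass(bio3d::dccm(ref))), unname(cc),
               tolerance = 1e-8)
  # fluctuations agree up to bio3d's physical prefactor
  msf <- mean_square_fluctuations(m)
  ratio <- ref$fluctuations / msf
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
})

test_that("matrix and profile TSV writers round-trip", {
  s <- make_chain(chain_spec(8, seed = 2))
  cc <- cross_correlation(decompose(build_kirchhoff(ca_distance_matrix(s), 7.3)))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(cc, tf)
  back <- as.matrix(utils::read.delim(tf, row.names = 1))
  expect_equal(unname(back), unname(cc), tolerance = 1e-12)

  tp <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(mean_square_fluctuations(decompose(
    build_kirchhoff(ca_distance_matrix(s), 7.3))), tp, "msf")
  prof <- utils::read.delim(tp)
  expect_named(prof, c("residue", "msf"))
  expect_equal(nrow(prof), 8L)
})
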