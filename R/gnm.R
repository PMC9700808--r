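#' Build the Kirchhoff (connectivity) matrix of a Gaussian network model
#'
#' Residues whose alpha carbons lie within `cutoff_rc` of each other are
#' joined by a unit spring; the Kirchhoff matrix is the Laplacian of the
#' resulting contact graph. The spring constant and the kT scale are both 1:
#' only ratios and normalized quantities are used downstream.
#'
#' @param d Symmetric distance matrix in angstroms (see
#'   [ca_distance_matrix()]).
#' @param cutoff_rc Contact cutoff in angstroms. Default 7.3, the
#'   conventional C-alpha GNM cutoff.
#' @return A `kirchhoff` object: list with `gamma` (n x n Laplacian, row sums
#'   zero, off-diagonals 0/-1) and `cutoff_rc`.
#' @export
build_kirchhoff <- function(d, cutoff_rc = 7.3) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), cutoff_rc > 0)
  contact <- (d <= cutoff_rc)
  diag(contact) <- FALSE
  gamma <- -1 * contact
  diag(gamma) <- colSums(contact)
  deg <- diag(gamma)
  if (all(deg == 0)) stop("disconnected contact graph: no contacts at cutoff ",
                          cutoff_rc, " A")
  if (any(deg == 0)) {
    warning("residues with zero contacts at cutoff ", cutoff_rc, " A: ",
            paste(utils::head(which(deg == 0), 10L), collapse = ", "))
  }
  dimnames(gamma) <- dimnames(d)
  out <- list(gamma = gamma, cutoff_rc = cutoff_rc)
  class(out) <- "kirchhoff"
  out
}

#' Normal-mode decomposition of a Kirchhoff matrix
#'
#' Full symmetric eigendecomposition; eigenvalues are returned ascending with
#' orthonormal eigenvectors. Modes whose eigenvalue is below
#' `null_tol * max(lambda)` are flagged as null (rigid-body) modes; a
#' connected contact graph has exactly one.
#'
#' @param k A `kirchhoff` object.
#' @param null_tol Relative tolerance for declaring a mode null.
#' @return A `gnm_modes` object: list with `values` (ascending), `vectors`
#'   (columns matching `values`), `n_null`, and `cutoff_rc`.
#' @export
decompose <- function(k, null_tol = 1e-8) {
  stopifnot(inherits(k, "kirchhoff"))
  e <- eigen(k$gamma, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  lam_max <- max(values)
  if (min(values) < -1e-8 * max(1, lam_max)) {
    stop("Kirchhoff matrix not positive semidefinite (min eigenvalue ",
         format(min(values)), ")")
  }
  n_null <- sum(values < null_tol * lam_max)
  if (n_null > 1L) stop("disconnected contact graph: ", n_null, " null modes")
  if (n_null < 1L) stop("no null mode found; not a valid Laplacian")
  rownames(vectors) <- rownames(k$gamma)
  out <- list(values = values, vectors = vectors, n_null = n_null,
              cutoff_rc = k$cutoff_rc)
  class(out) <- "gnm_modes"
  out
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat("gnm_modes:", length(x$values), "modes (", x$n_null, "null ),",
      "cutoff", x$cutoff_rc, "A\n")
  cat("lowest non-null eigenvalues:",
      paste(signif(utils::head(x$values[-seq_len(x$n_null)], 5L), 4),
            collapse = ", "), "\n")
  invisible(x)
}

# Raw covariance from the mode spectrum: sum over retained non-null modes of
# u_k u_k^T / lambda_k (the Kirchhoff pseudo-inverse when all modes are kept).
gnm_covariance <- function(m, n_modes = "all") {
  stopifnot(inherits(m, "gnm_modes"))
  keep <- seq_along(m$values)[-seq_len(m$n_null)]
  if (length(keep) == 0L) stop("no non-null modes available")
  if (!identical(n_modes, "all")) {
    stopifnot(is.numeric(n_modes), n_modes >= 1)
    keep <- keep[seq_len(min(n_modes, length(keep)))]
  }
  u <- m$vectors[, keep, drop = FALSE]
  sigma <- u %*% (t(u) / m$values[keep])
  dimnames(sigma) <- list(rownames(m$vectors), rownames(m$vectors))
  sigma
}

#' Normalized residue cross-correlation matrix
#'
#' Cross-correlations of residue fluctuations from the GNM mode spectrum:
#' the raw covariance is the pseudo-inverse of the Kirchhoff matrix
#' (optionally truncated to the softest `n_modes` non-null modes), normalized
#' so the diagonal is exactly 1. Values near +1 mark residues oscillating in
#' phase, near -1 in anti-phase.
#'
#' @param m A `gnm_modes` object.
#' @param n_modes `"all"` (default) or the number of softest non-null modes
#'   to retain.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
cross_correlation <- function(m, n_modes = "all") {
  sigma <- gnm_covariance(m, n_modes)
  v <- diag(sigma)
  if (any(v <= 0)) stop("internal error: non-positive fluctuation variance")
  cc <- sigma / sqrt(outer(v, v))
  cc <- (cc + t(cc)) / 2
  diag(cc) <- 1
  cc
}

#' Per-residue mean-square fluctuations
#'
#' The diagonal of the Kirchhoff pseudo-inverse, in arbitrary units
#' (kT/gamma = 1). Flexible regions (loops, disordered segments) score high,
#' packed cores low.
#'
#' @param m A `gnm_modes` object.
#' @param n_modes `"all"` or number of softest non-null modes.
#' @return Named numeric vector, one value per residue.
#' @export
mean_square_fluctuations <- function(m, n_modes = "all") {
  diag(gnm_covariance(m, n_modes))
}

#' Write a residue-indexed square matrix as TSV
#'
#' Dense whitespace-delimited text with a header row of residue ids.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Write a per-residue profile (MSF, centrality, disorder score) as TSV
#'
#' @param x Named numeric vector.
#' @param path Output path.
#' @param value_name Column name for the values.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path, value_name = "value") {
  df <- data.frame(residue = if (is.null(names(x))) seq_along(x) else names(x),
                   value = as.numeric(x))
  names(df)[2L] <- value_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
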