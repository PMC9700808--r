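#' Read a protein structure's C-alpha trace from PDB text
#'
#' Parses standard PDB `ATOM` records and keeps one alpha-carbon per residue,
#' in file order. Multi-model files (NMR ensembles, prediction servers) are
#' handled through `model_index`; alternate locations are resolved by highest
#' occupancy, then first occurrence.
#'
#' @param pdb Either a path to a PDB file or a character vector of PDB lines
#'   (a single string containing newlines is also accepted).
#' @param model_index 1-based index of the `MODEL` block to read. Files
#'   without `MODEL` records are treated as a single model.
#' @param chain_filter Optional single chain identifier; residues from other
#'   chains are dropped.
#' @param label Free-text label stored on the returned model.
#'
#' @return A `structure_model`: a data frame with one row per residue and
#'   columns `chain`, `resno`, `ins` (insertion code, `""` if none), `resid`
#'   (3-letter residue name), `x`, `y`, `z` (angstroms), plus a `label`
#'   attribute. Residue identity is keyed by (chain, resno, ins); sequence
#'   numbers follow the 1-based PDB convention.
#' @export
read_structure <- function(pdb, model_index = 1L, chain_filter = NULL,
                           label = "") {
  lines <- as_pdb_lines(pdb)
  validate_atom_coords(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  p <- bio3d::read.pdb(tf, multi = TRUE, rm.alt = FALSE, verbose = FALSE)

  n_models <- max(1L, nrow(p$xyz))
  if (model_index < 1L || model_index > n_models) {
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model", if (n_models > 1L) "s", ")")
  }
  at <- p$atom
  xyz <- matrix(p$xyz[model_index, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]

  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no CA atoms found")

  at$ins[is.na(at$ins)] <- ""
  at$chain[is.na(at$chain)] <- ""
  key <- paste(at$chain, at$resno, at$ins, sep = "|")
  if (anyDuplicated(key)) {
    at$o[is.na(at$o)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                          function(i) i[which.max(at$o[i])]))
    at <- at[sort(keep), , drop = FALSE]
  }

  res <- data.frame(
    chain = at$chain, resno = at$resno, ins = at$ins, resid = at$resid,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure_model(res, label = label)
}

#' Construct and validate a structure model
#'
#' @param residues Data frame with columns `chain`, `resno`, `ins`, `resid`,
#'   `x`, `y`, `z`.
#' @param label Free-text label.
#' @return A validated `structure_model`.
#' @export
structure_model <- function(residues, label = "") {
  needed <- c("chain", "resno", "ins", "resid", "x", "y", "z")
  miss <- setdiff(needed, names(residues))
  if (length(miss)) stop("residues lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(residues) == 0L) stop("empty structure: no residues")
  if (anyNA(residues[, c("x", "y", "z")])) stop("NaN/NA coordinates in structure")
  for (ch in unique(residues$chain)) {
    r <- residues$resno[residues$chain == ch & residues$ins == ""]
    if (is.unsorted(r, strictly = TRUE)) {
      stop("seq_positions not strictly increasing within chain '", ch, "'")
    }
  }
  attr(residues, "label") <- label
  class(residues) <- c("structure_model", "data.frame")
  residues
}

#' @export
print.structure_model <- function(x, ...) {
  lab <- attr(x, "label")
  cat("structure_model:", nrow(x), "residues",
      if (!is.null(lab) && nzchar(lab)) paste0("(", lab, ")"), "\n")
  cat("chains:", paste(unique(x$chain), collapse = ", "), "\n")
  invisible(x)
}

#' Residue identifiers of a structure model
#'
#' Keys are `resno` (with insertion code appended if present) for
#' single-chain models and `chain:resno` otherwise.
#'
#' @param s A `structure_model`.
#' @return Character vector, one id per residue.
#' @export
residue_ids <- function(s) {
  ids <- paste0(s$resno, s$ins)
  if (length(unique(s$chain)) > 1L) ids <- paste0(s$chain, ":", ids)
  ids
}

#' Write a C-alpha trace as a PDB file
#'
#' @param s A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
    resno = s$resno, resid = s$resid,
    chain = ifelse(nzchar(s$chain), s$chain, "A"),
    insert = ifelse(nzchar(s$ins), s$ins, NA),
    elety = rep("CA", nrow(s))
  )
  invisible(path)
}

#' Pairwise C-alpha distance matrix
#'
#' @param s A `structure_model`.
#' @return A dense symmetric numeric matrix of Euclidean distances in
#'   angstroms with zero diagonal; dimnames are the residue ids.
#' @export
ca_distance_matrix <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  d <- as.matrix(stats::dist(as.matrix(s[, c("x", "y", "z")])))
  ids <- residue_ids(s)
  dimnames(d) <- list(ids, ids)
  d
}

#' Pairwise distances within a residue subset
#'
#' Computes all unordered pair distances among the given sequence positions,
#' with mean/median summaries so the same subset can be compared across two
#' conformers (e.g. wild type vs mutant). Distances are measured between
#' alpha carbons.
#'
#' @param s A `structure_model`.
#' @param positions Integer sequence positions (`resno`); for multi-chain
#'   models all chains are searched and positions must be unambiguous.
#' @return A `pair_distance_table`: list with `pairs` (data frame
#'   `pair_i`, `pair_j`, `distance_A`), `mean`, `median`, and `n_positions`.
#'   With fewer than two positions the pair table is empty and the summaries
#'   are `NA` (flagged by `degenerate = TRUE`).
#' @export
residue_set_distances <- function(s, positions) {
  stopifnot(inherits(s, "structure_model"))
  idx <- match(positions, s$resno)
  if (anyNA(idx)) {
    stop("positions not present in structure: ",
         paste(positions[is.na(idx)], collapse = ", "))
  }
  ids <- residue_ids(s)[idx]
  xyz <- as.matrix(s[idx, c("x", "y", "z")])
  if (length(idx) < 2L) {
    out <- list(pairs = data.frame(pair_i = character(), pair_j = character(),
                                   distance_A = numeric()),
                mean = NA_real_, median = NA_real_,
                n_positions = length(idx), degenerate = TRUE)
    class(out) <- "pair_distance_table"
    return(out)
  }
  cmb <- utils::combn(length(idx), 2L)
  dd <- sqrt(rowSums((xyz[cmb[1L, ], , drop = FALSE] -
                      xyz[cmb[2L, ], , drop = FALSE])^2))
  pairs <- data.frame(pair_i = ids[cmb[1L, ]], pair_j = ids[cmb[2L, ]],
                      distance_A = dd, stringsAsFactors = FALSE)
  out <- list(pairs = pairs, mean = mean(dd), median = stats::median(dd),
              n_positions = length(idx), degenerate = FALSE)
  class(out) <- "pair_distance_table"
  out
}

#' @export
print.pair_distance_table <- function(x, ...) {
  cat("pair_distance_table:", nrow(x$pairs), "pairs over",
      x$n_positions, "positions\n")
  if (x$degenerate) {
    cat("degenerate: summaries undefined\n")
  } else {
    cat(sprintf("mean %.3f A, median %.3f A\n", x$mean, x$median))
  }
  invisible(x)
}

#' Write a pair distance table as TSV
#'
#' @param x A `pair_distance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_distances <- function(x, path) {
  stopifnot(inherits(x, "pair_distance_table"))
  utils::write.table(x$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

as_pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(readLines(pdb, warn = FALSE))
  }
  unlist(strsplit(pdb, "\n", fixed = TRUE), use.names = FALSE)
}

# PDB fixed columns: x 31-38, y 39-46, z 47-54
validate_atom_coords <- function(lines) {
  at <- grep("^ATOM", lines)
  if (length(at) == 0L) stop("empty structure: no ATOM records")
  for (i in at) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields)))) {
      stop("malformed coordinate field in PDB line ", i, ": ",
           trimws(lines[i]))
    }
  }
  invisible(TRUE)
}
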