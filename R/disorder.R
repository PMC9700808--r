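# Kyte-Doolittle hydropathy, rescaled to [0,1] inside foldindex_profile
kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Net charge at neutral pH; histidine carries 0 by FoldIndex convention
aa_charge <- c(
  A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0, H = 0, I = 0,
  L = 0, K = 1, M = 0, F = 0, P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0
)

#' Construct a protein sequence
#'
#' @param seq One-letter amino-acid string (or character vector of letters).
#' @param id Sequence identifier.
#' @return A `protein_sequence`: character scalar with an `id` attribute.
#'   Only the 20 standard residues are accepted.
#' @export
protein_sequence <- function(seq, id = "seq") {
  s <- toupper(paste(seq, collapse = ""))
  if (nchar(s) < 1L) stop("empty sequence")
  letters <- strsplit(s, "")[[1L]]
  bad <- setdiff(unique(letters), names(kd_hydropathy))
  if (length(bad)) {
    stop("non-standard residues in sequence: ", paste(bad, collapse = ", "))
  }
  structure(s, id = id, class = "protein_sequence")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A list of `protein_sequence` objects, named by FASTA ids.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(names(ss), function(nm) strsplit(nm, "\\s+")[[1L]][1L],
                character(1), USE.NAMES = FALSE)
  out <- lapply(seq_along(ss), function(i) {
    protein_sequence(as.character(ss[[i]]), id = ids[i])
  })
  names(out) <- ids
  out
}

#' Write protein sequences as FASTA
#'
#' @param seqs A `protein_sequence` or list of them.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "protein_sequence")) seqs <- list(seqs)
  ss <- Biostrings::AAStringSet(vapply(seqs, as.character, character(1)))
  names(ss) <- vapply(seqs, attr, character(1), "id")
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' FoldIndex foldability profile of a protein sequence
#'
#' Per position, over a centered sliding window (clipped at the termini),
#' computes the mean Kyte-Doolittle hydrophobicity rescaled to \[0, 1\] via
#' `(h + 4.5)/9` and the mean net charge (K, R = +1; D, E = -1; others 0),
#' then the foldability index `I = 2.785 <H> - |<R>| - 1.151`, clamped to
#' \[-1, 1\]. Positions with `I < 0` are predicted unfolded: low mean
#' hydrophobicity combined with high net charge marks intrinsically
#' disordered regions.
#'
#' @param s A `protein_sequence` (or plain string).
#' @param window Odd window size >= 1. Default 51.
#' @param nonstandard `"error"` (default) rejects non-standard residues;
#'   `"ignore"` excludes them from the window means.
#' @return A `disorder_profile` with `scale_kind = "foldindex"`.
#' @export
foldindex_profile <- function(s, window = 51L,
                              nonstandard = c("error", "ignore")) {
  nonstandard <- match.arg(nonstandard)
  if (!inherits(s, "protein_sequence")) {
    if (nonstandard == "error") {
      s <- protein_sequence(s)
    } else {
      s <- structure(toupper(paste(s, collapse = "")), id = "seq",
                     class = "protein_sequence")
    }
  }
  stopifnot(window >= 1L, window %% 2L == 1L)
  letters <- strsplit(as.character(s), "")[[1L]]
  n <- length(letters)
  h <- (kd_hydropathy[letters] + 4.5) / 9
  r <- aa_charge[letters]
  known <- as.numeric(!is.na(h))
  h[is.na(h)] <- 0
  r[is.na(r)] <- 0

  half <- (window - 1L) %/% 2L
  win_sum <- function(v) {
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    cs[hi + 1L] - cs[lo]
  }
  denom <- win_sum(known)
  if (any(denom == 0)) stop("window contains no standard residues")
  idx <- 2.785 * (win_sum(h) / denom) - abs(win_sum(r) / denom) - 1.151
  disorder_profile(pmin(pmax(idx, -1), 1), scale_kind = "foldindex",
                   window = window, id = attr(s, "id"))
}

#' Construct a per-residue disorder profile
#'
#' @param score Numeric vector of per-residue scores.
#' @param scale_kind `"foldindex"` (range \[-1, 1\], below 0 = unfolded) or
#'   `"pondr"` (range \[0, 1\], >= 0.5 = disordered).
#' @param window Window size used to produce the scores (NA if external).
#' @param id Sequence identifier.
#' @return A `disorder_profile` object.
#' @export
disorder_profile <- function(score, scale_kind = c("foldindex", "pondr"),
                             window = NA_integer_, id = "seq") {
  scale_kind <- match.arg(scale_kind)
  score <- as.numeric(score)
  if (anyNA(score)) stop("NA scores in disorder profile")
  rng <- if (scale_kind == "foldindex") c(-1, 1) else c(0, 1)
  if (any(score < rng[1L] - 1e-12) || any(score > rng[2L] + 1e-12)) {
    stop("scores outside the declared ", scale_kind, " range [",
         rng[1L], ", ", rng[2L], "]")
  }
  out <- list(score = score, scale_kind = scale_kind, window = window,
              id = id)
  class(out) <- "disorder_profile"
  out
}

#' @export
print.disorder_profile <- function(x, ...) {
  crit <- if (x$scale_kind == "foldindex") "score < 0" else "score >= 0.5"
  frac <- mean(if (x$scale_kind == "foldindex") x$score < 0
               else x$score >= 0.5)
  cat("disorder_profile (", x$scale_kind, "): ", length(x$score),
      " residues, ", round(100 * frac, 1), "% meeting ", crit, "\n", sep = "")
  invisible(x)
}

#' Read a PONDR-style per-residue score table
#'
#' Expects a two-column TSV (`position`, `score`), positions contiguous from
#' 1, scores in \[0, 1\]. A header row is accepted.
#'
#' @param x Path to a TSV file, or its text content.
#' @return A `disorder_profile` with `scale_kind = "pondr"`.
#' @export
read_score_table <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && is.na(suppressWarnings(
        as.numeric(strsplit(lines[1L], "\t")[[1L]][1L])))) {
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("empty score table")
  parts <- strsplit(lines, "\t")
  pos <- as.integer(vapply(parts, `[`, character(1), 1L))
  score <- as.numeric(vapply(parts, `[`, character(1), 2L))
  if (anyNA(pos) || anyNA(score)) stop("malformed score table row")
  if (!identical(pos, seq_along(pos))) {
    stop("positions must be contiguous from 1")
  }
  disorder_profile(score, scale_kind = "pondr")
}

#' Write a disorder profile as a two-column TSV
#'
#' @param p A `disorder_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(p, path) {
  stopifnot(inherits(p, "disorder_profile"))
  utils::write.table(
    data.frame(position = seq_along(p$score), score = p$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call disordered segments from a profile
#'
#' Finds maximal runs of positions meeting the scale-appropriate criterion
#' (pondr: score >= 0.5; foldindex: score < 0) and discards runs shorter
#' than `min_run`. Segments are reported 1-based, half-open: `(start, end)`
#' covers positions `start .. end - 1`.
#'
#' @param p A `disorder_profile`.
#' @param min_run Minimum run length to report. Default 3.
#' @return Data frame with columns `start`, `end` (half-open), `length`;
#'   disjoint, sorted, maximal.
#' @export
call_disordered_segments <- function(p, min_run = 3L) {
  stopifnot(inherits(p, "disorder_profile"), min_run >= 1L)
  hit <- if (p$scale_kind == "foldindex") p$score < 0 else p$score >= 0.5
  r <- rle(hit)
  ends_1b <- cumsum(r$lengths)
  starts_1b <- ends_1b - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts_1b[keep], end = ends_1b[keep] + 1L,
             length = r$lengths[keep], row.names = NULL)
}

#' Write disorder segments in BED-like 0-based convention
#'
#' Three columns: sequence id, 0-based half-open start and end (i.e. the
#' 1-based half-open `(start, end)` shifted down by one).
#'
#' @param segments Data frame from [call_disordered_segments()].
#' @param path Output path.
#' @param id Sequence id for column 1.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path, id = "seq") {
  df <- data.frame(id = rep(id, nrow(segments)),
                   start = segments$start - 1L, end = segments$end - 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
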