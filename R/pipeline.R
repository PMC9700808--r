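#' Assemble a run configuration
#'
#' Central container of paths and parameters for the orchestrated analyses.
#' Every parameter has the package-wide default, so a config may set only
#' what it needs.
#'
#' @param wt_pdb,mut_pdb,fasta,score_tsv,binding_csv Optional input paths.
#' @param decay_csvs Optional character vector of decay CSV paths.
#' @param cutoff_rc GNM contact cutoff (A). Default 7.3.
#' @param min_abs_corr Correlation threshold for network edges. Default 0.5.
#' @param contact_cutoff Spatial mask for network edges (A). Default 10.
#' @param window FoldIndex window (odd). Default 51.
#' @param min_run Minimum disorder-segment length. Default 3.
#' @param n_modes `"all"` or number of GNM modes for correlations.
#' @param bootstrap_n Bootstrap resamples for kinetic fits. Default 0.
#' @param seed Integer seed.
#' @param flagged_positions Residues of interest for the structural
#'   comparison. Default: 86, 158, 159, 162, 164, 168, 169, 170, 174.
#' @return A `run_config` list.
#' @export
run_config <- function(wt_pdb = NULL, mut_pdb = NULL, fasta = NULL,
                       score_tsv = NULL, decay_csvs = NULL,
                       binding_csv = NULL,
                       cutoff_rc = 7.3, min_abs_corr = 0.5,
                       contact_cutoff = 10, window = 51L, min_run = 3L,
                       n_modes = "all", bootstrap_n = 0L, seed = 1L,
                       flagged_positions = c(86L, 158L, 159L, 162L, 164L,
                                             168L, 169L, 170L, 174L)) {
  stopifnot(cutoff_rc > 0, min_abs_corr > 0, min_abs_corr < 1,
            contact_cutoff > 0, window >= 1L, window %% 2L == 1L,
            min_run >= 1L, bootstrap_n >= 0L)
  out <- list(wt_pdb = wt_pdb, mut_pdb = mut_pdb, fasta = fasta,
              score_tsv = score_tsv, decay_csvs = decay_csvs,
              binding_csv = binding_csv, cutoff_rc = cutoff_rc,
              min_abs_corr = min_abs_corr, contact_cutoff = contact_cutoff,
              window = as.integer(window), min_run = as.integer(min_run),
              n_modes = n_modes, bootstrap_n = as.integer(bootstrap_n),
              seed = as.integer(seed),
              flagged_positions = as.integer(flagged_positions))
  class(out) <- "run_config"
  out
}

#' Read a run configuration from a plain-text file
#'
#' One `key = value` per line; `#` starts a comment. List-valued keys
#' (`flagged_positions`, `decay_csvs`) take comma-separated values.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  args <- list()
  num_keys <- c("cutoff_rc", "min_abs_corr", "contact_cutoff", "window",
                "min_run", "bootstrap_n", "seed")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- if (k == "flagged_positions") {
      as.integer(strsplit(v, "\\s*,\\s*")[[1L]])
    } else if (k == "decay_csvs") {
      strsplit(v, "\\s*,\\s*")[[1L]]
    } else if (k %in% num_keys) {
      as.numeric(v)
    } else if (k == "n_modes") {
      if (identical(v, "all")) "all" else as.integer(v)
    } else v
  }
  do.call(run_config, args)
}

#' Run the full dynamics pipeline on one structure
#'
#' Structure -> distance matrix -> Kirchhoff -> modes -> cross-correlations
#' -> residue graph -> Girvan-Newman partition -> betweenness centrality.
#'
#' @param s A `structure_model`.
#' @param cutoff_rc,min_abs_corr,contact_cutoff,n_modes See [run_config()].
#' @return A list with all intermediates: `model`, `dmat`, `kirchhoff`,
#'   `modes`, `cmat`, `msf`, `graph`, `partition`, `centrality`.
#' @export
analyze_structure <- function(s, cutoff_rc = 7.3, min_abs_corr = 0.5,
                              contact_cutoff = 10, n_modes = "all") {
  dmat <- ca_distance_matrix(s)
  k <- build_kirchhoff(dmat, cutoff_rc = cutoff_rc)
  modes <- decompose(k)
  cmat <- cross_correlation(modes, n_modes = n_modes)
  g <- build_residue_graph(cmat, dmat, min_abs_corr = min_abs_corr,
                           contact_cutoff = contact_cutoff)
  list(model = s, dmat = dmat, kirchhoff = k, modes = modes, cmat = cmat,
       msf = mean_square_fluctuations(modes, n_modes = n_modes),
       graph = g, partition = girvan_newman_partition(g),
       centrality = node_betweenness_profile(g))
}

#' Compare two structures through their residue-network dynamics
#'
#' Runs [analyze_structure()] on both conformers, compares their community
#' partitions around the flagged residues, and summarizes flagged pairwise
#' distances. Deterministic given the inputs and parameters.
#'
#' @param cfg A `run_config`. Structures are read from `wt_pdb`/`mut_pdb`
#'   unless given directly.
#' @param wt,mut Optional `structure_model`s overriding the config paths.
#' @param out_dir Optional directory; when set, all intermediates are
#'   written there (TSV matrices, edge lists, partitions, JSON report).
#' @return A `structure_comparison_report`: list with `comparison` (see
#'   [compare_partitions()]), `wt`/`mut` analysis bundles, flagged distance
#'   summaries, and the parameters used.
#' @export
run_compare_structures <- function(cfg = run_config(), wt = NULL, mut = NULL,
                                   out_dir = NULL) {
  if (is.null(wt)) {
    if (is.null(cfg$wt_pdb)) stop("stage input: no wild-type structure given")
    wt <- read_structure(cfg$wt_pdb, label = "WT")
  }
  if (is.null(mut)) {
    if (is.null(cfg$mut_pdb)) stop("stage input: no mutant structure given")
    mut <- read_structure(cfg$mut_pdb, label = "mutant")
  }
  run_one <- function(s, tag) {
    tryCatch(
      analyze_structure(s, cutoff_rc = cfg$cutoff_rc,
                        min_abs_corr = cfg$min_abs_corr,
                        contact_cutoff = cfg$contact_cutoff,
                        n_modes = cfg$n_modes),
      error = function(e) stop("stage ", tag, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  a <- run_one(wt, "analyze(WT)")
  b <- run_one(mut, "analyze(mutant)")

  flagged_ids_a <- residue_ids(wt)[match(cfg$flagged_positions, wt$resno)]
  flagged_ids_b <- residue_ids(mut)[match(cfg$flagged_positions, mut$resno)]
  if (anyNA(flagged_ids_a) || anyNA(flagged_ids_b)) {
    stop("flagged positions absent from structure: ",
         paste(cfg$flagged_positions[is.na(flagged_ids_a) |
                                     is.na(flagged_ids_b)], collapse = ", "))
  }
  cmp <- compare_partitions(a$partition, b$partition, flagged_ids_a)
  dist_wt <- residue_set_distances(wt, cfg$flagged_positions)
  dist_mut <- residue_set_distances(mut, cfg$flagged_positions)

  report <- list(comparison = cmp, wt = a, mut = b,
                 flagged_distances = list(wt = dist_wt, mut = dist_mut),
                 parameters = cfg[c("cutoff_rc", "min_abs_corr",
                                    "contact_cutoff", "n_modes",
                                    "flagged_positions")])
  class(report) <- "structure_comparison_report"
  if (!is.null(out_dir)) write_comparison_report(report, out_dir)
  report
}

#' @export
print.structure_comparison_report <- function(x, ...) {
  cat("structure_comparison_report\n")
  print(x$comparison)
  cat(sprintf("  flagged mean pairwise distance: WT %.2f A, mutant %.2f A\n",
              x$flagged_distances$wt$mean, x$flagged_distances$mut$mean))
  invisible(x)
}

write_comparison_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  for (tag in c("wt", "mut")) {
    a <- report[[tag]]
    write_matrix_tsv(a$cmat, fp(paste0(tag, "_correlation.tsv")))
    write_profile_tsv(a$msf, fp(paste0(tag, "_msf.tsv")), "msf")
    write_profile_tsv(a$centrality, fp(paste0(tag, "_centrality.tsv")),
                      "betweenness")
    write_edge_list(a$graph, fp(paste0(tag, "_edges.tsv")))
    write_partition_tsv(a$partition, fp(paste0(tag, "_partition.tsv")))
    write_pair_distances(report$flagged_distances[[tag]],
                         fp(paste0(tag, "_flagged_distances.tsv")))
  }
  cmp <- report$comparison
  json <- list(
    m_wt = cmp$m_a, m_mut = cmp$m_b,
    flagged_modules_wt = cmp$flagged_modules_a,
    flagged_modules_mut = cmp$flagged_modules_b,
    dispersion_wt = cmp$dispersion_a, dispersion_mut = cmp$dispersion_b,
    delta_q = cmp$delta_q,
    flagged_mean_distance_wt = report$flagged_distances$wt$mean,
    flagged_mean_distance_mut = report$flagged_distances$mut$mean,
    parameters = report$parameters
  )
  jsonlite::write_json(json, fp("comparison.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' Run the disorder analyses of a configuration
#'
#' FoldIndex profiling of the FASTA sequence (if given) and classification
#' of an external PONDR-style score table (if given); segments are called on
#' each profile.
#'
#' @param cfg A `run_config` with `fasta` and/or `score_tsv` set.
#' @param out_dir Optional output directory for profile TSVs and BED-like
#'   segment files.
#' @return Named list of `list(profile, segments)` per input.
#' @export
run_disorder <- function(cfg, out_dir = NULL) {
  if (is.null(cfg$fasta) && is.null(cfg$score_tsv)) {
    stop("stage input: no fasta or score_tsv given")
  }
  out <- list()
  if (!is.null(cfg$fasta)) {
    seqs <- read_fasta(cfg$fasta)
    for (s in seqs) {
      p <- foldindex_profile(s, window = cfg$window)
      out[[paste0("foldindex_", attr(s, "id"))]] <-
        list(profile = p, segments = call_disordered_segments(p, cfg$min_run))
    }
  }
  if (!is.null(cfg$score_tsv)) {
    p <- read_score_table(cfg$score_tsv)
    out[["pondr"]] <-
      list(profile = p, segments = call_disordered_segments(p, cfg$min_run))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      write_score_table(out[[nm]]$profile,
                        file.path(out_dir, paste0(nm, "_profile.tsv")))
      write_segments_bed(out[[nm]]$segments,
                         file.path(out_dir, paste0(nm, "_segments.bed")),
                         id = nm)
    }
  }
  out
}

#' Run the kinetics analyses of a configuration
#'
#' Fits a half-life to every decay CSV and a Kd to the binding CSV.
#'
#' @param cfg A `run_config` with `decay_csvs` and/or `binding_csv` set.
#' @param out_dir Optional output directory for fit JSONs.
#' @return List with `half_life` (list of fits) and `kd` (fit or NULL).
#' @export
run_kinetics <- function(cfg, out_dir = NULL) {
  if (is.null(cfg$decay_csvs) && is.null(cfg$binding_csv)) {
    stop("stage input: no decay_csvs or binding_csv given")
  }
  fits <- list(half_life = list(), kd = NULL)
  for (path in cfg$decay_csvs) {
    fits$half_life[[basename(path)]] <-
      fit_half_life(read_decay_csv(path), bootstrap = cfg$bootstrap_n,
                    seed = cfg$seed)
  }
  if (!is.null(cfg$binding_csv)) {
    fits$kd <- fit_kd(read_binding_csv(cfg$binding_csv),
                      bootstrap = cfg$bootstrap_n, seed = cfg$seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(fits$half_life)) {
      write_fit_json(fits$half_life[[nm]],
                     file.path(out_dir, paste0("halflife_",
                                               sub("\\.csv$", "", nm),
                                               ".json")))
    }
    if (!is.null(fits$kd)) {
      write_fit_json(fits$kd, file.path(out_dir, "kd.json"))
    }
  }
  fits
}
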