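Package: strucnet
Title: Residue Network Dynamics, Disorder Profiling and Kinetics for
    Protein Structure Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares protein conformers through the lens of their intrinsic
    dynamics. Builds Gaussian network models from alpha-carbon traces,
    converts the resulting residue cross-correlations into weighted graphs,
    partitions them with Girvan-Newman edge-betweenness clustering scored by
    weighted modularity, and profiles betweenness centrality per residue.
    Also provides FoldIndex foldability profiling of protein sequences,
    classification of externally supplied per-residue disorder scores,
    least-squares estimation of protein half-life from cycloheximide-chase
    densitometry and of dissociation constants from saturation binding data,
    and seeded synthetic-data generators (bead-chain structures, sequences,
    decay and binding curves) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
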