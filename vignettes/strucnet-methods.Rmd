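---
title: "Comparing protein conformers through residue network dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing protein conformers through residue network dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucnet)
```

## The scientific problem

Charge-neutralizing mutations in an intrinsically disordered, lysine-rich
protein segment (the kind of segment that is a substrate for
post-translational modification and a hub for protein--protein
interactions) can make that segment *locally ordered*. strucnet quantifies
the structural consequence of such mutations from predicted or experimental
structure models, without requiring anything beyond a C-alpha trace. The
package also carries the two quantitative companions such a study needs:
sequence-level foldability profiling, and least-squares kinetics (protein
half-life from cycloheximide-chase densitometry, dissociation constants
from saturation binding).

## The model chain

### Gaussian network model

Each residue is a bead at its C-alpha position; beads within a cutoff
$r_c$ are joined by identical springs. The network's Kirchhoff (Laplacian)
matrix $\Gamma$ has $\Gamma_{ij} = -1$ for contacts and contact degree on
the diagonal. Its eigendecomposition gives the normal modes; the
pseudo-inverse (computed from the non-null modes, $\sigma = \sum_k
\lambda_k^{-1} u_k u_k^\top$) gives residue mean-square fluctuations
(diagonal) and cross-correlations (normalized off-diagonal):

$$ C_{ij} = \frac{\sigma_{ij}}{\sqrt{\sigma_{ii}\,\sigma_{jj}}} \in [-1, 1]. $$

*Parameters.* $r_c$ defaults to 7.3 Å, the conventional C-alpha GNM
cutoff; no cutoff is uniquely "right" and the value is exposed everywhere
(`cutoff_rc`). The spring constant and $k_BT/\gamma$ scale are fixed at 1
because every downstream quantity is either normalized (correlations) or
compared between two structures (fluctuations). All non-null modes are used
by default (`n_modes = "all"`); a small-mode truncation is available and
converges monotonically to the all-mode answer. Modes with
$\lambda < 10^{-8}\lambda_{\max}$ are treated as null; a connected contact
graph must yield exactly one, and a disconnected graph is an error rather
than a silent per-component analysis, because the intended inputs are
single-chain monomers.

The classic isotropic GNM is used rather than an anisotropic (3n × 3n)
model: the downstream network analysis consumes only scalar coupling
strengths, for which the isotropic model is the standard and cheapest
source.

### From correlations to a residue graph

Correlations alone produce a dense all-to-all matrix, so an edge is kept
only where coupling is strong *and* the residues are spatially close:
$|C_{ij}| \ge$ `min_abs_corr` (default 0.5) and $d_{ij} \le$
`contact_cutoff` (default 10 Å). Edge weight is $|C_{ij}|$; the length used
for shortest paths is $-\log |C_{ij}|$, so path length accumulates
multiplicatively in coupling strength. Anti-correlated pairs enter by
absolute value -- they are strongly coupled, just in anti-phase -- and the
sign is kept as edge metadata. Perfectly coupled pairs have length 0; the
shortest-path engine requires strictly positive lengths, so lengths are
clamped at $10^{-12}$ for path computations only, far below anything that
could reorder a path.

### Girvan--Newman communities and centrality

Communities are found by iteratively deleting the edge with the highest
betweenness (recomputed after every deletion) and scoring each intermediate
connected-component partition with weighted Newman--Girvan modularity

$$ Q = \sum_m \left[ \frac{w_{in}(m)}{W} -
   \left(\frac{s(m)}{2W}\right)^2 \right], $$

always evaluated against the *original* graph. The returned partition is
the one maximizing $Q$ (earliest on ties); an edgeless graph yields
singleton modules with $Q = 0$ by convention. The removal sequence comes
from igraph's C implementation of the recalculation loop, which is
deterministic (equal-betweenness ties follow its fixed internal edge
order), so repeated runs are bit-identical; the modularity scoring and the
maximum-$Q$ stopping rule are computed by this package by replaying the
removal sequence backwards through a union--find. Module indices are
renumbered by each module's smallest member, and cross-structure
comparisons never rely on label identity: the comparison statistic is the
*dispersion* of a flagged residue set -- how many distinct modules host
flagged residues -- because module labels are not comparable between two
different graphs.

Node betweenness over the same weighted lengths profiles which residues
carry the coupled-oscillation traffic; leaves score zero.

## Disorder profiling

The foldability index over a centered sliding window (default 51 residues,
clipped at the termini) is

$$ I = 2.785\,\langle H \rangle - |\langle R \rangle| - 1.151, $$

with $\langle H \rangle$ the mean Kyte--Doolittle hydrophobicity rescaled
to $[0,1]$ via $(h + 4.5)/9$ and $\langle R \rangle$ the mean net charge
(K, R = +1; D, E = −1; histidine 0, the standard neutral-pH convention).
Scores are clamped to $[-1, 1]$; $I < 0$ marks unfolded residues. The
constants are the published FoldIndex formula; this package adopts them
as-is rather than refitting. Externally produced per-residue disorder
scores (PONDR-style, range $[0,1]$, $\ge 0.5$ = disordered) are consumed
from a two-column table -- that predictor is a trained neural network and
is deliberately not reimplemented. The segment caller reports maximal runs
meeting the scale-appropriate criterion, 1-based half-open, dropping runs
shorter than `min_run` (default 3; single-residue disorder calls are noise
at the scores' typical precision).

## Kinetics

Half-life: one-phase exponential decay without plateau,
$y = I_0 e^{-kt}$, $t_{1/2} = \ln 2 / k$, fit by Levenberg--Marquardt
least squares initialized from the log-linear estimate (or by the
log-linear regression itself, `method = "loglinear"`; the two agree
exactly on noiseless data). Intensities are actin-normalized ratios, so no
plateau term is fitted by default. Binding: the one-site hyperbola
$f = B_{\max} c / (K_d + c)$ with Hill coefficient 1, $B_{\max}$ optionally
fixed at 1. Uncertainty comes from a seeded nonparametric bootstrap
(resampling observations), since densitometry error models are rarely
known. Units are fixed by the CSV dialects -- hours and micromolar -- to
prevent silent unit mistakes.

## What the synthetic generator emulates

The generator exists so every stage is testable without third-party
structure downloads, and its defaults *are* the study conditions used by
the acceptance checks.

* **Chains** are built from segments: ideal α-helix ("compact": rise
  1.5 Å/residue, radius 2.3 Å, twist 100°), extended conformation
  ("loose": rise 3.5 Å -- about half the compact contact density at the
  7.3 Å cutoff), a confined self-avoiding random walk ("coil": step 3.8 Å,
  excluded volume 4.5 Å, confinement radius $5.5\,L^{1/3}$ Å), and a
  deterministic serpentine bundle of short antiparallel helices
  ("bundle": 14-residue helices, 3-residue turns, 8.5 Å lateral spacing).
  Gaussian jitter (default σ = 0.3 Å) emulates model noise. Everything is
  a pure function of spec + seed.
* **The WT/mutant pair** (`make_wt_mut_pair`, default 200 residues with
  flagged positions 86, 158, 159, 162, 164, 168, 169, 170, 174) gives the
  WT-like chain a coil segment spanning the flagged range and the
  mutant-like chain a bundle there. The coil reproduces what structure
  predictors emit for disordered segments -- a collapsed, low-density but
  spatially cohesive blob that the community analysis keeps nearly whole.
  The bundle realizes "localized orderedness": globally *more compact*
  (smaller flagged pairwise distances), yet each short helix nucleates its
  own community, so the flagged set scatters over more modules. This
  design was reached by explicitly testing alternatives: a single
  continuous helix in place of the disordered segment makes the contrast
  *invert* (Girvan--Newman slices the WT extended thread into more
  modules than the mutant helix), so "one rigid helix" is the wrong
  emulation of a locally ordered mutant segment and the bundle is used
  instead.
* **Decay curves** carry multiplicative lognormal noise (densitometry
  ratios are positive and roughly log-normal); **binding curves** carry
  additive Gaussian noise clipped to the valid fraction-bound range;
  **sequences** are sampled from per-block alphabets (hydrophobic I/L/V/F,
  charged+ K/R, charged− D/E, mixed uniform-20).

What passing tests on these synthetics does *not* show: real predicted
structures have side-chain packing, irregular secondary structure and
model-quality artifacts that a bead chain lacks, and real module counts
depend on the (stochastic) structure prediction itself. The synthetic
contrast demonstrates that the *pipeline* resolves the ordered-vs-
disordered signature, not that any particular protein will show a
particular module count.

## Numerical choices and degenerate inputs

* Eigendecomposition: base `eigen(symmetric = TRUE)`; eigenvalues returned
  ascending; PSD asserted at $-10^{-8}\lambda_{\max}$.
* Correlation matrices are symmetrized against floating-point asymmetry
  and their diagonal set to exactly 1.
* Alternate PDB locations resolve by highest occupancy, then first seen;
  insertion codes are kept as part of the residue key; 1-based PDB
  numbering keyed by (chain, position).
* A single-residue subset yields an empty pair table with `NA` summaries,
  flagged `degenerate`.
* Modularity of a one-module partition is exactly 0; a single-edge graph
  returns one module ($Q = 0$) because every split scores negative.
* Decay fits reject non-positive rate constants ("no measurable decay");
  binding fits warn when no observation exceeds half-saturation.

## Problem sizes

The package's reference study conditions are 200-residue chains, 20
replicate seeds for the WT/mutant contrast, 200 simulations for each
kinetic recovery study, and 1000 bootstrap resamples for fit standard
errors. These sizes give stable medians and run comfortably on a single
CPU; all are parameters, not constants.

## Known limitations

* The GNM is isotropic and parameter-free by design; absolute fluctuation
  scales are arbitrary and only ratios/contrasts are meaningful.
* Module counts reported for any real protein depend on the (stochastic)
  structure prediction and on every network parameter; this package makes
  the parameters explicit instead of promising to reproduce any specific
  count.
* Girvan--Newman recomputation costs $O(E^2 V)$ in the worst case;
  ~200-residue monomers partition in seconds, but thousand-residue
  complexes would call for a faster community method (deliberately not
  substituted here, since the edge-betweenness formulation is the method
  under study).
* FoldIndex windows shorter than ~9 residues are noisy and windows longer
  than the protein simply average it; window sensitivity is the user's to
  explore (`window` everywhere).
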