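# strucnet

Residue network dynamics, disorder profiling and kinetics for comparing
protein conformers in R.

## The problem

Charge-neutralizing mutations in a lysine-rich intrinsically disordered
protein segment can make that segment locally ordered, with consequences
for partner binding, post-translational modification and protein
stability. Given nothing but C-alpha structure models of the two variants
(e.g. from a structure-prediction server), strucnet quantifies that
transition three ways:

1. **Intrinsic dynamics.** A Gaussian network model (GNM) is built on the
   C-alpha contact graph (Kirchhoff matrix Γ, springs within a cutoff
   r_c = 7.3 Å). Its normal modes give residue cross-correlations
   `C_ij = σ_ij / sqrt(σ_ii σ_jj)` from the pseudo-inverse
   `σ = Σ_k λ_k⁻¹ u_k u_kᵀ`. Strongly coupled residues in spatial contact
   (|C_ij| ≥ 0.5, d_ij ≤ 10 Å) form a weighted graph (weight |C_ij|,
   path length −log |C_ij|) that is partitioned by **Girvan–Newman
   edge-betweenness clustering** with a weighted-modularity stopping rule,
   and profiled by betweenness centrality. Two structures are compared by
   their module counts and by the *dispersion* of a flagged residue set —
   how many distinct modules host the flagged residues.
2. **Sequence foldability.** FoldIndex profiles
   `I = 2.785⟨H⟩ − |⟨R⟩| − 1.151` over a sliding window (Kyte–Doolittle
   hydropathy rescaled to [0,1]; K/R = +1, D/E = −1); `I < 0` marks
   unfolded residues. External per-residue disorder scores (range [0,1],
   ≥ 0.5 = disordered) are read from TSV; segments are called from either
   scale.
3. **Kinetics.** Protein half-life from cycloheximide-chase densitometry
   (one-phase exponential, `t½ = ln 2 / k`, Levenberg–Marquardt or
   log-linear least squares) and dissociation constants from saturation
   binding (one-site hyperbola `f = Bmax·c/(Kd + c)`), with seeded
   bootstrap standard errors.

A seeded synthetic-data module generates bead-chain structures (helix,
extended, self-avoiding coil, helix-bundle packings), sequences with
controlled charge/hydrophobicity composition, and decay/binding curves, so
the entire pipeline is testable end to end without downloads.

## Worked example

```r
library(strucnet)

# a matched pair: WT-like chain with a disordered (coil) segment spanning
# the flagged lysine positions, mutant-like chain with a locally ordered
# helix bundle there
pair <- make_wt_mut_pair(seed = 1)
report <- run_compare_structures(run_config(seed = 1),
                                 wt = pair$wt, mut = pair$mut)
report
#> structure_comparison_report
#> partition_comparison
#>   modules:            A = 8, B = 12
#>   flagged modules A:  4, 7
#>   flagged modules B:  8, 9, 10
#>   flagged dispersion: A = 2, B = 3
#>   delta Q (B - A):    -0.2145
#>   flagged mean pairwise distance: WT 12.76 A, mutant 12.73 A
```

Reading: the mutant-like structure partitions into more co-oscillating
modules (12 vs 8), and its flagged residues scatter over more of them
(dispersion 3 vs 2) while sitting closer together in space — the network
signature of a disordered segment that has become locally ordered.

Kinetics on simulated densitometry data:

```r
fit_half_life(simulate_decay(3.8, noise_sigma = 0.05, seed = 8))
#> half_life_fit (nls): t1/2 = 3.82 h (k = 0.181 /h, I0 = 1)
#>   n = 9, RSS = 0.000697
fit_kd(simulate_binding(1.6, noise_sigma = 0.03, seed = 8))
#> kd_fit: Kd = 1.43 uM (Bmax = 0.939)
#>   n = 10, RSS = 0.00511
```

A thin command-line front end (`inst/exec/strucnet`) exposes the same
pipeline as subcommands `compare-structures`, `disorder`, `fit-halflife`,
`fit-kd`, and `simulate`, with `--config` (plain-text `key = value`
files), `--seed`, and `--out-dir` flags. All intermediates (correlation
matrices, edge lists, partitions, centrality and distance tables, fit
JSONs) are written as plain text so every report value can be re-derived.

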