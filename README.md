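# bltsa — branched local tangent space alignment for single-cell pseudotime

Single-cell RNA-seq captures snapshots of cells at different stages of a
differentiation process; pseudotime inference reconstructs the underlying
ordering from those snapshots. `bltsa` implements branched local tangent
space alignment (BLTSA), a manifold-learning approach to pseudotime for
trajectories with bifurcations and multi-furcations. It is aimed at
analysts who have a genes × cells expression matrix (or an existing
low-dimensional embedding) and want a per-cell pseudotime τ ∈ [0, 1] plus
branch assignments, with every stage of the inference inspectable.

## The method

Cells are modeled as samples from a low-dimensional self-intersecting
manifold — a tree of 1-D branches. Working on a diffusion-map embedding
X ∈ R^(D×N) (D = 2 by default), the pipeline:

1. **Classifies cells** from their k-nearest neighborhoods (k = 50).
   The SVD of the centered neighborhood X̄ᵢ gives a tangent basis Uᵢ and
   local coordinates Θᵢ; the *nonlinearity* σ₂²/σ₁² flags junction-adjacent
   (branching) cells above its 80th percentile, and the *consistency*
   (2/(k(k−1))) Σ_{p,q∈Nᵢ∖i} sgn((x_p−x_i)ᵀ(x_q−x_i)) flags tips
   (trajectory endpoints) above δ_t = 0.9. The root is the earliest tip.
2. **Clusters the non-branching cells into branches** by normalized
   spectral clustering, choosing the branch count by a silhouette
   criterion computed in the kNN-graph metric, then absorbs each branching
   cell greedily into the branch minimizing the average of tangent
   distance ‖(I − UⱼUⱼᵀ)(xᵢ − xⱼ)‖ and Euclidean distance, refitting its
   tangent model as it joins.
3. **Aligns local coordinates globally**: per-cell neighborhoods are
   redistributed within branch ∪ root branch with adaptive size in
   [40, 100], each contributes an alignment matrix
   Wᵢ = (I − eeᵀ/k)(I − Θᵢ⁺Θᵢ), and the pseudotime is the smallest
   non-trivial eigenvector of B = Σᵢ SᵢWᵢWᵢᵀSᵢᵀ, rooted and rescaled to
   [0, 1].

The package also ships three trajectory simulators with ground truth
(a fully geometric trifurcation, sigmoid-mean expression bifurcations with
Poisson- and Gamma-derived noise scales, and a simplified kinetic tree),
Pearson/Spearman evaluation helpers, a pseudotime-ordered expression
smoother, and readers/writers for dense TSV/CSV and MatrixMarket matrices.

## Worked example

```r
library(bltsa)

sim <- simulate_geometric_trifurcation(seed = 7)   # 400 cells, 4 branches
cfg <- bltsa_config(normalize = FALSE, reduce = FALSE, seed = 7)
res <- run_bltsa(sim$matrix, cfg, time_labels = sim$true_tau)
res
#> BLTSA pseudotime result
#>   cells: 400  branches: 4  root: cell1
#>   tau range: [0, 1]
#>   tips: 9  branching: 77

correlation_metrics(res$tau, sim$true_tau)
#> $pcc
#> [1] 0.972
#> $srcc
#> [1] 0.979

head(res$annotation, 3)
#>    cell nonlinearity consistency     category is_root
#> 1 cell1    0.4535106   0.9600000          tip    TRUE
#> 2 cell2    0.5524486   0.8032653 intermediate   FALSE
#> 3 cell3    0.7442787   0.9102041          tip   FALSE
```

The input here is a simulated trifurcation generated directly in the 2-D
trajectory plane, so count normalization and re-embedding are switched
off; for an expression matrix the defaults (size-factor normalization,
diffusion map to D = 2) apply. `res$tau` holds the pseudotime (0 at the
root tip, 1 at the farthest trajectory end), `res$branch` the branch
labels (4 branches found: the trunk plus three arms), `res$annotation` the
per-cell scores behind the tip/branching calls, and
`correlation_metrics()` compares the inferred ordering with the
generator's ground truth — Pearson 0.97 and Spearman 0.98 on this seed.
`write_results(res, dir)` writes `pseudotime.tsv`, `branches.tsv`,
`cells.tsv` and `run.log`.

A thin command-line wrapper lives at `inst/cli/bltsa.R`
(`run` / `simulate` / `evaluate` subcommands) for shell-driven use.

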