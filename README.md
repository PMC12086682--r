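# mdmflow

Diffusion-based analysis and visualization of **developmental multimodal
single-cell data** in R. `mdmflow` is for analysts who have per-cell
measurements of several modalities (transcriptome, chromatin accessibility,
protein epitopes, histone marks — or topic-model latent modalities derived
from a single assay) and want a joint low-dimensional embedding that
preserves the ordering, continuity and branching of differentiation
trajectories, plus diffusion-based imputation of sparse feature counts.

## The model

Three pieces, run in sequence by `run_mdm()`:

1. **Cell-specific modality weights.** For cell *c*, let **d**<sub>c</sub><sup>m,l</sup>
   be the distances, measured in modality-*m* space, from *c* to its *k*
   nearest neighbors found in modality *l*. Distances are rank-normalized by
   a per-modality empirical CDF estimated from *P* sampled cell pairs, and

   s<sub>c</sub><sup>m</sup> = Σ<sub>l≠m</sub> median(ECDF<sup>m</sup>(**d**<sub>c</sub><sup>m,l</sup>)),

   smoothed over the highest-scoring modality's neighborhood and passed
   through a softmax with temperature α (default 10):
   w<sub>c</sub><sup>m</sup> = e<sup>α s<sub>c</sub><sup>m</sup></sup> / Σ<sub>l</sub> e<sup>α s<sub>c</sub><sup>l</sup></sup>.
   Each cell's weights sum to 1 and quantify which modality carries its
   developmental signal.

2. **Multimodal diffusion maps (MDM).** Per modality, a density-adjusted
   Gaussian kernel κ(c₁,c₂) = exp(−d²/(ε<sub>c₁</sub>ε<sub>c₂</sub>)) with
   ε<sub>c</sub> the distance to the *N*-th neighbor (default 20). Kernels
   are weight-averaged, K<sup>m</sup> = ½(w<sub>c₁</sub><sup>m</sup>+w<sub>c₂</sub><sup>m</sup>)κ<sup>m</sup>,
   row-normalized, summed into the multimodal Markov chain K = Σ D<sup>m</sup>K<sup>m</sup>,
   row-normalized again and symmetrized: K̂ = DK + (DK)ᵀ. The embedding is
   the eigenvalue-scaled eigenvectors of K̂, skipping the non-informative
   first pair: [λ̂₂q̂₂, …, λ̂<sub>N+1</sub>q̂<sub>N+1</sub>].

3. **Layout graphs and imputation.** Constant-out-degree graphs for
   ForceAtlas2/UMAP layouts (plain nearest neighbors, transition-aware, or
   timestamp-restricted), and diffusion imputation
   G<sub>imputed</sub> = Q Λᵗ Qᵀ G whose cost is independent of the number
   of diffusion steps *t*.

Simulated developmental datasets (a three-modality binary tree and a
two-modality rare-transitions design), embedding-quality scores
(signature cohesiveness, vector-field alignment, terminal-state separation,
cell-type correlation structure) and topic-model latent modalities for
unimodal data are included. See the vignette
(`vignettes/multimodal-diffusion-maps.Rmd`) for the full account of
parameters and design choices.

## Worked example

```r
library(mdmflow)

sim <- make_rare_transitions(seed = 1)   # 4500 cells, 9 types, 2 modalities
w   <- compute_weights(sim$modalities, k = 60, seed = 1)
round(head(w, 3), 3)
#>           modality1 modality2
#> cell00001     0.982     0.018
#> cell00002     0.980     0.020
#> cell00003     0.950     0.050
```

The first cells belong to lineage A, introduced by modality 1, and the
weights put ~0.95–0.98 of their mass there. Against the one-hot ground
truth the computed weights reach a mean squared error of **0.1152**, versus
**0.25** for uniform weights:

```r
weight_mse(w, target_weights(sim))
#> [1] 0.1151817
```

```r
res <- run_mdm(sim$modalities, n_components = 20, n_graph_neighbors = 60,
               weights = w)
round(res$embedding[1:3, 1:4], 4)
#>             MDM1    MDM2    MDM3   MDM4
#> cell00001 0.0231 -0.0075 -0.0324 0.0457
#> cell00002 0.0241 -0.0030  0.0093 0.0206
#> cell00003 0.0101  0.0356  0.0017 0.0005

g <- nn_graph(res$embedding, out_degree = 60)   # 270000 edges, 60 per node
export_graph(g, "edges.tsv")                    # feed to ForceAtlas2/UMAP
```

Each embedding column is an eigenvalue-scaled eigenvector of the symmetrized
multimodal chain; coordinates are small because eigenvectors are unit-norm
over 4500 cells. A 20-nearest-neighbor label-purity vote in this embedding
(0.73) exceeds either raw modality alone (0.44 and 0.48), because modality 1
cannot separate types D–I and modality 2 cannot separate A–C.

A command-line interface wrapping the same functions ships at
`inst/cli/mdmflow.R`:

```sh
Rscript inst/cli/mdmflow.R simulate --dataset binary-tree --seed 1 --out sim/
Rscript inst/cli/mdmflow.R mdm --in sim/modality1.tsv,sim/modality2.tsv,sim/modality3.tsv \
    --dims 10 --out embedding.tsv
```

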