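---
title: "Multimodal diffusion maps: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal diffusion maps: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdmflow)
```

## The problem

Multimodal single-cell assays measure several feature sets — transcriptome,
chromatin accessibility, protein epitopes, histone marks — in the same cell.
During differentiation these modalities are not equally informative at the
same time: chromatin opens before transcription commences, epitopes lag
behind mRNA. A joint low-dimensional embedding of a developmental dataset
therefore has to decide, per cell, which modality's geometry carries the
developmental signal, and it has to preserve the ordering, continuity and
branching of trajectories rather than just cluster structure. `mdmflow`
addresses this with three coupled pieces: cell-specific modality weights,
a weighted multimodal Markov chain eigendecomposed into a diffusion-map
embedding (MDM), and graph construction for force-directed layouts that can
incorporate externally inferred cell-cell transition probabilities.

## Cell-specific modality weights

We interpret differentiation as movement in feature space: a cell whose
neighborhood is expanded in modality $m$ is likely undergoing a developmental
process visible in $m$. For cell $c$, let $\mathbf d_c^{m,l}$ be the vector
of distances, measured in modality-$m$ space, from $c$ to its $k$ nearest
neighbors found in modality $l$. Raw distances are not comparable across
modalities, so each modality's distances are rank-normalized by an empirical
CDF estimated from $P$ uniformly sampled cell pairs. The modality score is

$$s_c^m = \sum_{l \ne m} \operatorname{median}\!\big(\mathrm{ECDF}^m(\mathbf d_c^{m,l})\big),$$

smoothed by averaging score rows over the cell itself and its $k$ nearest
neighbors in its highest-scoring modality, and normalized per cell with a
softmax at temperature $\alpha$:

$$w_c^m = \frac{e^{\alpha s_c^m}}{\sum_l e^{\alpha s_c^l}}.$$

Parameters and defaults:

* `k = 20` neighbors (units: cells). The simulated-data benchmarks in this
  package use `k = 60`, matching the neighborhood width at which the weight
  benchmark is defined.
* `P = 1000` sampled pairs. The ECDF needs only enough pairs for stable
  quantiles; 1000 is ample for thousands of cells.
* `alpha = 10`. Values near 1 give near-uniform weights; very large values
  make the weights one-hot. 10 separates modalities decisively without
  saturating.

Three implementation decisions matter for reproducibility. First, the same
seeded pair sample is reused for every modality's ECDF; this makes weights
exactly equivariant under modality permutation while remaining a uniform
pair sample. Second, smoothing includes the cell itself, which keeps
isolated cells stable. Third, argmax ties (in smoothing and in feature-topic
assignment) always break toward the lower index, so runs are deterministic.
Because the ECDF is rank-based, rescaling any modality's embedding by a
positive constant leaves the weights unchanged — the tests assert this
invariance.

## The multimodal Markov chain and its embedding

Each modality gets a sparse density-adjusted Gaussian kernel over its
nearest-neighbor graph,

$$\kappa(c_1, c_2) = \exp\!\Big(-\frac{d(c_1,c_2)^2}{\varepsilon_{c_1}\varepsilon_{c_2}}\Big),$$

where $\varepsilon_c$ is the distance from $c$ to its $N$-th neighbor
(`n_kernel_neighbor = 20`), adapting bandwidth to local density. The graph
keeps `n_graph_neighbors` edges per cell (defaulting to the larger of the
weight and kernel neighbor counts; graph sparsity is a performance choice,
and the dense limit is recovered at `n_graph_neighbors = C - 1`) and is
symmetrized by union. Kernels are combined through the weights,

$$K^m_{c_1 c_2} = \tfrac{w_{c_1}^m + w_{c_2}^m}{2}\,\kappa^m(c_1,c_2),
\qquad K = \sum_m D^m K^m,$$

with $D^m$ the row-normalizer of $K^m$, and the combined chain is
row-normalized once more and symmetrized along the diagonal,
$\widehat K = DK + (DK)^\top$. The top $N + E + 1$ eigenpairs of
$\widehat K$ are computed (`n_extra = E = 10` guard pairs absorb the
accuracy loss of trailing Lanczos eigenvectors and are discarded), and the
embedding takes eigenvalue-scaled eigenvectors skipping the first pair,
which is non-informative for developmental ordering:

$$\mathrm{MDM} = [\hat\lambda_2 \hat q_2, \dots, \hat\lambda_{N+1} \hat q_{N+1}].$$

Numerical choices: eigenvalues are ordered by decreasing algebraic value
(not magnitude); the implementation tolerates negative trailing eigenvalues
— symmetry and nonnegativity of $\widehat K$ do not by themselves guarantee
positive semi-definiteness — and simply never retains them at practical
$N + E + 1 \ll C$. Eigenvector signs are fixed by making each column's
largest-magnitude entry positive. A deterministic Lanczos starting vector
makes the sparse path reproducible; instances of up to 500 cells use a dense
solver. Duplicate cells would give $\varepsilon_c = 0$, so the bandwidth is
floored at a machine-epsilon-scaled value with a warning. Cells isolated in
every modality keep zero chain rows and land at the embedding origin with a
warning rather than an error. All reductions are computed by serial
accumulation per row, so results do not depend on evaluation order.

On small instances the entire sparse pipeline (kernel, chain, eigensystem,
embedding) is checked against an independent dense implementation to
1e-6; with one modality and unit weights it reduces exactly to a classical
diffusion map.

## Layout graphs

For force-directed visualization the embedding is converted into a directed
graph with a constant out-degree per node, in three variants: (i) plain
nearest neighbors in MDM space; (ii) transition-aware — among a cell's
`candidate_pool` nearest MDM neighbors (default `10 * out_degree`; the
search neighborhood is otherwise unspecified, so it is configurable), the
`out_degree` targets with the highest externally supplied transition
probability are linked, shortfalls being filled with the closest unlinked
neighbors, and cells with no transitions fall back to variant (i); and
(iii) timestamped — candidates are restricted to the subsequent timestamp
(terminal timestamps search within themselves). Ties always break by
probability descending, then distance, then cell index. The layout engines
themselves (ForceAtlas2, UMAP) are external consumers of the exported edge
list and are deliberately not reimplemented.

## Diffusion imputation

The symmetric operator's eigendecomposition turns $t$-step diffusion of a
count matrix $G$ into $Q \Lambda^t Q^\top G$: only the eigenvalue vector is
powered, so the cost is independent of $t$. With a complete basis this
equals the explicit operator power exactly (the tests assert agreement at
1e-6 for $t \in \{0,1,3,5\}$); with the retained $N + E + 1$ pairs it is a
truncated approximation. Unlike the embedding, imputation keeps the first
eigenpair — dropping the stationary component would destroy the mass
structure of the diffused signal. Truncation can produce small negative
imputed values; they are kept by default, with a `clip_nonnegative` flag for
count semantics.

The same machinery expands a seed cell set to a subtrajectory: a 0/1
indicator is diffused $t$ steps and cells above a threshold are selected.
No selection rule is published for this step; a fixed absolute threshold is
brittle under basis truncation, so the default keeps cells above the 90th
percentile of non-seed diffused values (configurable), always retaining the
seed. A relative floor of `1e-12 * max(|values|)` guards against projection
rounding noise, so a disconnected component is never selected spuriously.

## Latent modalities for unimodal data

To apply the multimodal workflow to unimodal data, a topic model (latent
Dirichlet allocation, fit by batch variational Bayes for `n_iterations = 30`
by default, priors `1/T`) splits features into groups by their most probable
topic. LDA is a count model, so it runs on raw counts. The default
"top features" rule keeps features whose within-topic probability exceeds
the uniform level $1/F$ (a top-$k$ rule is available); each nonempty group
becomes a latent modality, log-normalized (`log1p` of counts scaled to
10,000 per cell) before entering the MDM, and the per-cell topic
proportions over retained topics, renormalized to sum to 1, serve as the
modality weights.

## Simulated benchmark datasets

Two generators reproduce the study conditions used throughout the tests.
The *binary tree* has three modalities and 6000 observations in six types
A–F, 1000 per type; modality 1 introduces lineages A–B, modality 2 C–D,
modality 3 E–F. The *rare transitions* dataset has two modalities and 4500
observations in nine types A–I, 500 per type; A–C form a transient chain of
unit segments in modality 1 and D–I are six Gaussian branches in modality 2.
The exact branch geometry is not published, so the generators fix a
documented default: unit-spaced Gaussian centers with isotropic sd 0.5
(covariance $0.25\,I$) along branches of length 4, and head-to-tail unit
segments for A–C. Types not introduced by a modality sit at a single
Gaussian blob at their lineage's junction point, so the introducing modality
is uniquely informative — which is what makes the one-hot target weights
well defined — while trajectories stay connected across modalities.

Gaussian oversampling (3x) is followed by density-based downsampling to the
per-type count, retaining point $x$ with probability proportional to
$d(x, \mathrm{NN}_{25}(x))^3$. The cubic law is read as a retention
probability: keeping sparse-region points flattens density so the
downstream kNN structure along trajectories is stable. Pseudotime ranks
observations by distance from the lineage root; noise shuffles every
consecutive block of 100 ranks, so no rank moves by 100 or more.

What the generators emulate is branching low-dimensional geometry with
modality-specific information content. What they do not emulate: count
noise, dropout, library-size variation, or high-dimensional feature spaces.
Tests passing on these data show the weighting and embedding machinery
recovers geometry and modality relevance; they do not certify performance
on real sparse count matrices.

## Benchmark scores

The embedding-quality scores are pure functions of their inputs; velocity
directions, transition probabilities, absorption probabilities and
signature activities are consumed from files, never computed here.
Signature cohesiveness selects the top 5% of cells by activity, scores each
as the mean activity of its 3 nearest neighbors (searched among all cells),
links selected cells within `eps` (default: median distance of 1000 random
pairs) and returns $\Phi = -\log\sum_G \exp(-\sum_{c \in G}\psi_c)$ over
connected components — implemented as plain radius-graph components, which
is exactly density clustering with a minimum neighborhood of one, so no
selected cell is discarded as noise. The vector-field score is the median
over transition-bearing cells (cells without transitions have no defined
score) of median cosine similarities toward the 3 highest-probability
targets. Terminal-state separation locates each state at the mean of its
top 1% absorption cells and subtracts competing states' mean absorption in
its neighborhood. Cross-method score rescaling to a [0, 1] leaderboard is a
reporting step left to the caller.

## Problem sizes and known limitations

The test suite exercises full-size generated datasets (6000 and 4500
observations) for the end-to-end recovery checks and 40–200-cell instances
for oracle equivalence, which keeps a complete run under a minute on one
CPU. Known limitations: `h5ad` support covers dense and CSR/CSC `X` with
`obs/_index`/`var/_index` only; the LDA is a batch fit (no online updates);
approximate nearest-neighbor backends are not bundled — the exact kd-tree
search is the default and the test reference; and distributed execution is
out of scope, with determinism guaranteed instead (identical seeds give
identical results).
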