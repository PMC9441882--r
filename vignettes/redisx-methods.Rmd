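---
title: "Stratifying patient cohorts with continuous max-flow graph cuts"
author: "redisx package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying patient cohorts with continuous max-flow graph cuts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redisx)
```

## The problem

A diagnosis such as rheumatoid arthritis or coronary artery disease
groups together patients whose molecular states can differ
substantially. Given a gene × sample matrix of log-scale expression
values, `redisx` asks: how many transcriptomic subpopulations does this
cohort actually contain, and which patient belongs to which? The answer
drives downstream questions — per-subpopulation differential expression
against healthy controls, signature genes unique to one subpopulation,
and hub genes on an interaction network.

## The model

The pipeline is semi-supervised in an unusual sense: it supervises
itself. For a requested cluster number $k$:

1. **Features.** The top 5,000 high-variance genes are kept (unbiased
   variance, $n-1$ divisor) and each gene is standardized across
   samples. Variance is computed on the raw input, before
   standardization.
2. **Pre-labels.** Agglomerative hierarchical clustering produces $k$
   pre-labels under the inter-cluster distance
   $$d(\mathcal{C}_i,\mathcal{C}_j)=\frac{1}{|\mathcal{C}_i||\mathcal{C}_j|}
   \sum_{x\in \mathcal{C}_i}\sum_{y\in \mathcal{C}_j}\lVert x-y\rVert,$$
   the average-linkage form. Each cluster contributes an equal number
   of *seeds* — the minimal cluster size — chosen as the most central
   members (medoid policy) by default.
3. **Graph.** Samples become nodes of a cosine $K$-nearest-neighbour
   graph ($K=10$), symmetrized by union; negative cosines (possible
   after z-scoring) are clamped to zero so the weights can act as
   transition probabilities.
4. **Diffusion priors.** With transition matrix
   $A_{ij}=w_{ij}/\sum_{j'}w_{ij'}$, degrees $d_{ii}=\sum_j w_{ij}$ and
   the symmetric normalization $\hat A = D^{1/2}AD^{-1/2}$, the
   $m$-step connectivity $r_{ij}=(\hat A^m_{ij})^2/(\hat A^m_{ii}\hat
   A^m_{jj})$ measures how strongly two samples communicate through the
   graph ($m=2$). A non-seed's prior probability for cluster $k$
   averages $r$ over that cluster's seed set and normalizes across
   clusters; seeds get probability one on their own cluster. Priors are
   clamped into $[\varepsilon, 1-\varepsilon]$, $\varepsilon=10^{-6}$,
   and rows renormalized, so the region forces
   $f_k(x_i) = -\log p_k(x_i) + \log(1-p_k(x_i))$ stay finite.
5. **Graph cut.** Hard labels minimize the multiclass min-cut energy
   with region forces,
   $$E(\Phi)=\alpha\sum_{(i,j)\in E}\sum_{k} w_{ij}\,
   |\phi_k(x_i)-\phi_k(x_j)| + \sum_{i}\sum_k \phi_k(x_i) f_k(x_i),$$
   over one-hot $\Phi$. The binary problem is NP-hard, so the feasible
   set is relaxed to the probability simplex (the continuous max-flow
   relaxation) and solved by a primal–dual algorithm; the relaxed
   assignment is thresholded row-wise (argmax, ties to the lowest
   index).
6. **Cluster-number selection.** Because the cut term pulls
   well-connected samples together, requested clusters that the graph
   does not support end up empty — the solver *merges* them. The
   pipeline runs once per requested $k=1..20$ and records the
   surviving (non-empty) cluster count; the modal count is the optimal
   cluster number. Ties break toward the larger $k$ (and are flagged),
   so coarse always-present votes do not override genuine fine
   structure.

## The regularization parameter

A clamped seed prior exerts a fixed force swing of
$2L = 2\log((1-\varepsilon)/\varepsilon) \approx 27.6$ between its own
and any competing cluster, while relabelling a node can save at most
$2\alpha d_i$ of cut energy, where $d_i$ is its weighted degree
(typically $\sim$3–8 on a $K=10$ cosine graph). If
$\alpha < L/d_i$ a seed can never be absorbed into a neighbouring
cluster, no requested cluster can ever empty, and the merge-based
selection of the cluster number is structurally inoperable — every
requested $k$ survives and the mode degenerates. The default therefore
sets
$$\alpha = \frac{2L}{\bar d}, \qquad \bar d = \tfrac1n\sum_i d_i,$$
(`alphaAuto()`): a seed is absorbed exactly when its neighbourhood
disagrees unanimously and its degree is at least half the mean. Seeds
inside genuine structure are protected by their agreeing
neighbourhood, not by the pin, so the planted-$k$ fit is unaffected.
A fixed numeric `alpha` can be supplied in the configuration for users
who want the raw energy trade-off.

## Numerical choices

- **Primal–dual solver.** Chambolle–Pock with the weighted
  edge-difference operator $B$ ((BΦ)$_{e,k} = w_e(\Phi_{ik} -
  \Phi_{jk})$); dual update is an entrywise box projection onto
  $[-1,1]$, primal update the sort-based Euclidean projection of each
  row onto the simplex. Step sizes $\tau=\sigma=0.99/\lVert\alpha
  B\rVert$ with the operator norm estimated by 20 power iterations
  started from a fixed random vector (the constant vector lies in the
  null space of $B$ and must be avoided). Over-relaxation $\theta=1$.
  $\Phi$ is warm-started from the priors (the logistic transform of
  $-F$, renormalized), which is deterministic and consistent with the
  semi-supervised design.
- **Convergence.** Mean absolute change of both $\Phi$ *and* $\Psi$
  below $10^{-6}$, cap 10,000 iterations; non-convergence returns the
  last iterate with a warning, never an error. The dual change matters:
  after a strong warm start the primal can sit at a simplex vertex with
  zero change while the dual is still accumulating toward its box
  bound, and only once it saturates can it push the primal off a
  suboptimal vertex — a primal-only test stops too early.
- **Tie-breaks.** All deterministic: agglomeration ties pick the pair
  whose clusters have the smallest (then second-smallest) lowest-index
  members; KNN similarity ties pick the lower sample index; argmax
  ties pick the lowest cluster index; equal-variance genes are ranked
  lexicographically; medoid ties pick the lower sample index. Repeated
  runs on identical input are bit-identical.
- **Degenerate inputs.** Zero-variance genes are zeroed with a warning
  rather than an error; a node with zero connectivity to every seed
  receives a uniform prior with a warning; an isolated graph node
  (possible when all a sample's cosine similarities are negative) is a
  hard error naming the node. `k = 1` short-circuits to a single
  cluster, and an edgeless graph reduces the solve to a per-row
  minimum-force assignment.
- **Linkage naming.** The average-linkage formula above is sometimes
  referred to as Ward's method in the clustering literature around
  this algorithm family; the two are different. This package
  implements the formula as its default (`linkage = "average"`) and
  offers `linkage = "ward"` (via `hclust`'s `ward.D2`) for users who
  prefer the variance-minimizing method.
- **Prior normalization.** The seed-averaged connectivity is
  normalized with each competing cluster's *own* seed average in the
  denominator (the natural reading of the ratio), so priors sum to one
  by construction.

## The synthetic generator

`makeClusteredExpression()` emulates an RMA-style microarray cohort:
log-scale intensities with per-gene baselines from $\mathcal N(0,1)$,
$k$ planted subpopulations each shifting its own disjoint block of
genes by $\pm$`effect` (first half up, deterministic), i.i.d. Gaussian
noise with sd `sigma`, and optional controls at baseline.
`makePairedDatasets()` adds a signature block shared — same genes,
same signed shifts — between one designated cluster of each of two
cohorts, emulating a cross-disease subpopulation.

The default conditions (effect 5, sigma 0.5, 40 samples per cluster,
500 genes, 50 DE genes per cluster) describe *well-separated*
subpopulations: the per-gene effect is 10 noise standard deviations.
What the generator does **not** emulate: batch effects, probe-level
artefacts, count noise (no negative-binomial mode), correlated genes
within pathways, or label noise in the control group. Tests passing on
this generator therefore demonstrate the machinery — pre-labelling,
priors, the solver, merging, the selection rule — not robustness to
the full messiness of public expression repositories.

## Differential expression and hub scoring

Per cluster, genes are compared against the shared controls with a
two-sided Welch test on the log scale (log-fold change = mean
difference). By default each group's per-gene variance is shrunk
toward the 10%-trimmed mean of all gene variances with 4 prior degrees
of freedom — a light empirical-Bayes moderation that stabilizes small
cohorts; `moderate = FALSE` gives the plain Welch test. This is a
deliberate simplification of a full linear-model moderation framework
(such as limma's); on shared designs the two rank evidence nearly
identically, which the test suite checks, but numerical parity is not
a goal. P-values are BH-adjusted within cluster; rows pass at
`p < 0.05` (raw by default; configurable to adjusted) and
`|logFC| > 0.05`. Genes significant in more than one cluster are
dropped by `excludeOverlapping()`, leaving each subpopulation's unique
signature. Hub genes on a user-supplied network are ranked by Maximal
Clique Centrality, $\mathrm{MCC}(v)=\sum_{C\ni v}(|C|-1)!$ over
maximal cliques (exact enumeration; isolated nodes score 1).

## Problem sizes used in the test suite

Unit tests run on reduced instances (15–20 samples per cluster,
150–300 genes) so the suite stays quick; the acceptance tests exercise
the full study conditions above, including a 20-dataset-per-$k$
recovery experiment for planted $k\in\{2,3,4,5\}$ and a 50-instance
brute-force oracle comparison ($n\le 8$, $K\le 3$, where exhaustive
enumeration is feasible). `scripts/acceptance.R` recomputes the same
quantities at 5 datasets per planted $k$, which keeps a full run in a
few minutes on one core.

## Known limitations

- The cluster-number vote includes the degenerate $k=1$ run
  (configurable via `kMin`); cohorts whose true structure is very fine
  relative to `kMax` = 20 are censored at 20.
- Diffusion steps `m` must be even: odd powers can zero the diagonal
  of $\hat A^m$ on bipartite structures, making the connectivity ratio
  undefined.
- The relaxation is exact on the instances we can verify exhaustively,
  but no tightness guarantee exists for general multiclass instances.
- MCC scores use double-precision arithmetic; cliques above ~18 nodes
  lose exactness in the factorial (practically irrelevant for
  interaction-network subgraphs, which the 3×10^6 maximal-clique guard
  limits anyway).
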