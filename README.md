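# redisx

Patient stratification from gene expression by continuous max-flow
graph cuts.

A clinical diagnosis often lumps together patients whose transcriptomic
states differ. `redisx` re-groups the samples of a cohort from a gene ×
sample expression matrix: it pre-labels samples by agglomerative
hierarchical clustering, refines the labels with a **continuous
max-flow (CMF)** multiclass min-cut on a cosine K-nearest-neighbour
similarity graph, and — because the graph cut *merges* requested
clusters the data do not support — selects the number of subpopulations
as the modal count of surviving clusters over requested k = 1..20.
Downstream, it scores per-cluster differential expression against
healthy controls (with cross-cluster overlap exclusion, yielding each
subpopulation's unique signature) and ranks hub genes on a supplied
interaction network by Maximal Clique Centrality.

It is aimed at computational biologists working with bulk (or
pseudo-bulk) expression cohorts — microarray series matrices or
normalized count tables — who want a reproducible, deterministic
stratification with an internal criterion for the cluster number.

## The model in brief

For each requested k, hierarchical pre-labels (average linkage,
d(Ci,Cj) = |Ci|⁻¹|Cj|⁻¹ ΣΣ‖x−y‖) supply equal-sized seed sets; m-step
diffusion connectivity r_ij = (Â^m_ij)² / (Â^m_ii Â^m_jj) on the KNN
graph (Â = D^{1/2} A D^{−1/2}, m = 2) turns the seeds into prior
probabilities p_k(x_i) and region forces f_k = −log p_k + log(1−p_k);
the hard labels minimize

    E(Φ) = α Σ_{(i,j)∈E} Σ_k w_ij |φ_k(x_i) − φ_k(x_j)| + Σ_i Σ_k φ_k(x_i) f_k(x_i)

via a primal–dual solver on the simplex relaxation, thresholded
row-wise. Requested clusters whose seeds are overwhelmed by their
neighbourhood end empty; the mode of the surviving counts over
k = 1..20 is the reported cluster number. See the methods vignette
(`vignettes/redisx-methods.Rmd`) for assumptions, the default choice
of α, and numerical details.

## Worked example

A synthetic cohort with three planted subpopulations (40 patients
each, 500 genes, 50 signature genes per subpopulation shifted by ±5 on
log scale, noise sd 0.5) plus 30 healthy controls:

```r
library(redisx)

spec <- syntheticSpec(kPlanted = 3, samplesPerCluster = 40,
                      nControls = 30, nGenes = 500, nDePerCluster = 50,
                      effect = 5, sigma = 0.5, seed = 1)
sim   <- makeClusteredExpression(spec)
cases <- sim$dataset[, names(sim$labels)]

ev <- evaluateClusterNumber(cases, redisxConfig(kMax = 10))
ev
#> ClusterEvaluationResult over k = 1..10
#>   surviving counts: 1 2 3 3 3 3 3 3 3 3
#>   optimal k: 3
```

Every requested k ≥ 3 collapses back to 3 surviving clusters — the
planted structure — so the mode is 3. Fitting at that k recovers the
planted labels exactly:

```r
fit <- redisxFit(cases, optimalK(ev))
table(planted = sim$labels, discovered = fit$labels)
#>        discovered
#> planted  1  2  3
#>       1 40  0  0
#>       2  0 40  0
#>       3  0  0 40
```

Per-cluster differential expression against the controls, keeping only
genes significant in exactly one cluster:

```r
degs <- excludeOverlapping(
  dePerCluster(sim$dataset, fit$labels, sim$controlIds))
table(degs$cluster)
#>  1  2  3
#> 54 53 68
head(degs[order(degs$p_value), ], 3)
#>       gene_id cluster    log_fc      p_value        p_adj direction
#> 186 gene00149       3 -5.100542 4.626125e-59 2.313062e-56      down
#> 26  gene00026       1 -5.207109 4.048304e-58 2.024152e-55      down
#> 165 gene00128       3 -4.946365 5.835258e-58 1.458814e-55      down
```

Each cluster's signature contains its 50 planted genes (at their ±5
log-fold changes) plus a handful of false positives at the raw p < 0.05
threshold. Hub genes on an interaction network are ranked with
`mccScores(edges, topN = 20)`.

The same pipeline is scriptable from a shell via the thin CLI
(`inst/exec/redisx`): `redisx synth`, `redisx cluster --k auto`,
`redisx evaluate`, `redisx de`, `redisx hub`. Real cohorts load with
`readExpressionTSV()` or `readSeriesMatrix()` (GEO series-matrix
dialect), with optional probe collapsing via `collapseProbes()`.

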