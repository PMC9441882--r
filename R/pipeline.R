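#' Fit the stratification model at a fixed cluster number
#'
#' Runs the full chain on an expression dataset: high-variance-gene
#' selection, per-gene standardization, hierarchical pre-labelling,
#' equal-sized seed selection, cosine KNN graph, diffusion operators,
#' seed-derived prior probabilities and region forces, the continuous
#' max-flow solve, and thresholding. Clusters that survive the graph cut
#' are relabelled densely 1..K' in order of their first-occurring
#' sample.
#'
#' @param se a `SummarizedExperiment` (genes x samples).
#' @param k requested number of clusters (k = 1 short-circuits to a
#'   single cluster).
#' @param config a [RedisXConfig-class]; defaults to [redisxConfig()].
#' @return list with `labels` (named integer vector), `solution`
#'   ([CMFSolution-class]), `prelabel` ([PrelabelResult-class]),
#'   `graph` ([SimilarityGraph-class]) and `forces`
#'   ([RegionForces-class]). For k = 1 only `labels` is populated.
#' @examples
#' sim <- makeClusteredExpression(syntheticSpec(kPlanted = 2,
#'   samplesPerCluster = 10, nGenes = 60, nDePerCluster = 10,
#'   effect = 5, sigma = 0.5, seed = 1))
#' fit <- redisxFit(sim$dataset, k = 2, config = redisxConfig(knnK = 5))
#' table(fit$labels, sim$labels)
#' @export
redisxFit <- function(se, k, config = redisxConfig()) {
  validObject(config)
  k <- as.integer(k)
  x <- exprsMatrix(se)
  if (k < 1L) stop("k must be >= 1")
  if (ncol(x) < k) stop("k exceeds the number of samples")
  sampleIds <- colnames(x)
  if (k == 1L)
    return(list(labels = setNames(rep(1L, ncol(x)), sampleIds),
                solution = NULL, prelabel = NULL, graph = NULL,
                forces = NULL))
  nHVG <- min(config@nHVG, nrow(x))
  se2 <- zscoreGenes(selectHVG(se, nHVG))
  X <- t(exprsMatrix(se2))                      # samples x genes
  pre <- hierarchicalPrelabel(X, k, linkage = config@linkage)
  pre <- selectSeeds(X, pre, policy = config@seedPolicy,
                     seed = config@seed)
  g <- buildKnnGraph(X, K = min(config@knnK, nrow(X) - 1L))
  ops <- diffusionOperators(g, m = config@diffusionM)
  seeds <- lapply(seq_len(k), function(kk)
    which(pre@seedMask & pre@labels == kk))
  rf <- regionForces(priorProbabilities(ops, seeds,
                                        clampEps = config@probClampEps))
  alpha <- if (is.na(config@alpha))
    alphaAuto(g, config@probClampEps) else config@alpha
  prob <- cmfProblem(g, rf@F, alpha = alpha)
  sol <- solveCMF(prob, maxIter = config@pdMaxIter, tol = config@pdTol)
  labels <- relabelDense(sol@labels)
  list(labels = setNames(as.integer(labels), sampleIds),
       solution = sol, prelabel = pre, graph = g, forces = rf)
}

#' Number of non-empty clusters in a labelling
#' @param labels integer cluster labels.
#' @return number of distinct labels present.
#' @export
countNonemptyClusters <- function(labels) {
  length(unique(labels))
}

#' Select the cluster number by merge behaviour
#'
#' Because the max-flow stage merges requested clusters that the graph
#' connectivity does not support, the pipeline is run once per requested
#' k (kMin..kMax) and the number of surviving (non-empty) clusters is
#' recorded; the modal surviving count over all runs is taken as the
#' optimal number of subpopulations. Mode ties break toward the larger k
#' so genuine fine structure is not discarded, and are flagged.
#'
#' @param se a `SummarizedExperiment`.
#' @param config a [RedisXConfig-class]. `nRepeats > 1` repeats each k
#'   with shifted seeds (only meaningful under the random seed policy).
#' @return a [ClusterEvaluationResult-class].
#' @export
evaluateClusterNumber <- function(se, config = redisxConfig()) {
  validObject(config)
  n <- ncol(exprsMatrix(se))
  kMax <- config@kMax
  if (kMax > n) {
    warning("kMax lowered to the number of samples (", n, ")")
    kMax <- n
  }
  ks <- seq.int(config@kMin, kMax)
  requested <- integer(0); surviving <- integer(0)
  for (k in ks) {
    for (rep in seq_len(config@nRepeats)) {
      cfg <- config
      cfg@seed <- config@seed + (rep - 1L) * 1000L
      fit <- redisxFit(se, k, cfg)
      requested <- c(requested, k)
      surviving <- c(surviving, countNonemptyClusters(fit$labels))
    }
  }
  md <- modalCount(surviving)
  new("ClusterEvaluationResult", requestedK = requested,
      survivingCounts = surviving, optimalK = md$mode,
      tieBroken = md$tie)
}

#' Two-dimensional embedding for visualization
#'
#' Convenience wrapper: linear reduction to min(50, n - 1) principal
#' components followed by a 2-D t-distributed stochastic neighbour
#' embedding with a fixed seed (perplexity is capped for small cohorts).
#'
#' @param se a `SummarizedExperiment`.
#' @param seed RNG seed making the embedding reproducible.
#' @return n x 2 matrix of coordinates, rownames = sample identifiers.
#' @export
embed2D <- function(se, seed = 0) {
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed2D needs the Rtsne package")
  x <- exprsMatrix(se)
  n <- ncol(x)
  if (n < 3L) stop("at least 3 samples are required")
  X <- t(scale(t(x)))                  # z-score genes, guard constant rows
  X[!is.finite(X)] <- 0
  nc <- min(50L, n - 1L)
  pcs <- stats::prcomp(t(X), center = TRUE, scale. = FALSE,
                       rank. = nc)$x
  perp <- max(1, min(30, floor((n - 1) / 3)))
  coords <- withSeed(seed,
    Rtsne::Rtsne(pcs, dims = 2, perplexity = perp, pca = FALSE,
                 check_duplicates = FALSE)$Y)
  rownames(coords) <- colnames(x)
  colnames(coords) <- c("x", "y")
  coords
}
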