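# Shared fixture builders; everything is generated in code.

# Similarity graph from an explicit edge list (i, j, w).
graphFromEdges <- function(n, edges, knnK = 1L) {
  edges <- as.matrix(edges)
  W <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = rep(edges[, 3], 2), dims = c(n, n))
  new("SimilarityGraph", adjacency = W, knnK = as.integer(knnK))
}

# Two unit-weight 4-cliques joined by one weak edge (the barbell).
barbellGraph <- function(wBridge = 0.01) {
  e <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)))
  e <- cbind(e, 1)
  graphFromEdges(8, rbind(e, c(4, 5, wBridge)))
}

# Random sparse problem instance for oracle-equivalence checks.
randomProblem <- function(n, K, alpha = 1) {
  full <- t(combn(n, 2))
  keep <- runif(nrow(full)) < 0.6
  if (!any(keep)) keep[sample(nrow(full), 1)] <- TRUE
  e <- cbind(full[keep, , drop = FALSE], runif(sum(keep)))
  g <- graphFromEdges(n, e)
  cmfProblem(g, matrix(rnorm(n * K, sd = 2), n, K), alpha = alpha)
}

# Small expression TSV written to a temp file; returns the path.
writeTinyExpressionFile <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Hand-built diffusion operators with a prescribed AhatM diagonal 1 and
# chosen off-diagonal entries (for checking the prior formula).
opsWithConnectivity <- function(rVals) {
  # rVals: named list like list("1,2" = 0.9) of connectivity values
  n <- max(vapply(strsplit(names(rVals), ","), function(p)
    max(as.integer(p)), integer(1)))
  M <- diag(n)
  for (nm in names(rVals)) {
    ij <- as.integer(strsplit(nm, ",")[[1]])
    M[ij[1], ij[2]] <- M[ij[2], ij[1]] <- sqrt(rVals[[nm]])
  }
  A <- matrix(1 / n, n, n)  # any row-stochastic matrix; unused here
  new("DiffusionOperators", A = A, d = rep(1, n), Ahat = diag(n),
      AhatM = M, m = 2L)
}

wellSeparatedSpec <- function(kPlanted, seed,
                              samplesPerCluster = 40, nGenes = 500,
                              nDePerCluster = 50) {
  syntheticSpec(kPlanted = kPlanted, samplesPerCluster = samplesPerCluster,
                nGenes = nGenes, nDePerCluster = nDePerCluster,
                effect = 5, sigma = 0.5, seed = seed)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
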