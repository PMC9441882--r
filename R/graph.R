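#' Cosine similarity between two vectors
#'
#' \eqn{\langle x, y\rangle / (\|x\|\,\|y\|)}; the similarity measure
#' between patient expression profiles used throughout the graph stage.
#'
#' @param x,y non-zero numeric vectors of equal length.
#' @return scalar in [-1, 1].
#' @export
cosineSimilarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' Build the cosine K-nearest-neighbour similarity graph
#'
#' Each sample keeps edges to its `K` most cosine-similar other samples
#' (similarity ties by lower index); the edge set is symmetrized by
#' union (an edge is kept if either endpoint selects it). Negative
#' similarities — possible after per-gene standardization — are clamped
#' to 0 so the weights can serve as transition probabilities.
#'
#' @param X numeric matrix, one sample per row.
#' @param K neighbourhood size, K < nrow(X) (default 10).
#' @return a [SimilarityGraph-class].
#' @export
buildKnnGraph <- function(X, K = 10) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- as.integer(K)
  if (K >= n) stop("K must be smaller than the number of samples (", n, ")")
  if (K < 1L) stop("K must be positive")
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) stop("zero feature vector for sample ",
                            which(norms == 0)[1L])
  S <- tcrossprod(X / norms)          # cosine similarity matrix
  diag(S) <- -Inf
  ii <- integer(0); jj <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(-S[i, ], seq_len(n))[seq_len(K)]  # ties by lower index
    ii <- c(ii, rep.int(i, K)); jj <- c(jj, nb)
  }
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  keep <- !duplicated(cbind(a, b))
  a <- a[keep]; b <- b[keep]
  w <- pmax(S[cbind(a, b)], 0)        # clamp negative similarities
  W <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(w, w),
                            dims = c(n, n))
  new("SimilarityGraph", adjacency = W, knnK = K)
}

#' Write a similarity graph as a 3-column edge list
#' @param g a [SimilarityGraph-class].
#' @param path output TSV path (columns i, j, w; 1-based, i < j).
#' @return invisibly, `path`.
#' @export
writeGraphTSV <- function(g, path) {
  write.table(graphEdges(g), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Diffusion operators of a similarity graph
#'
#' Treats the graph as a Markov chain: the transition matrix
#' \eqn{A_{ij} = w_{ij} / \sum_{j'} w_{ij'}} gives the probability that a
#' random walk at sample i steps to sample j; with degrees
#' \eqn{d_{ii} = \sum_j w_{ij}}, the symmetrically normalized operator is
#' \eqn{\hat A = D^{1/2} A D^{-1/2}} and its m-th power supports the
#' m-step diffusion distances and connectivity similarities.
#'
#' @param g a [SimilarityGraph-class]; every node must have positive
#'   degree.
#' @param m number of diffusion steps (default 2; even values keep the
#'   diagonal of \eqn{\hat A^m} positive on every connected structure).
#' @return a [DiffusionOperators-class].
#' @export
diffusionOperators <- function(g, m = 2) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  W <- as.matrix(g@adjacency)
  d <- rowSums(W)
  if (any(d <= 0))
    stop("isolated node (zero total edge weight): sample ",
         which(d <= 0)[1L])
  A <- W / d
  Ahat <- W / sqrt(outer(d, d))       # = D^{1/2} A D^{-1/2}
  Ahat <- (Ahat + t(Ahat)) / 2        # kill rounding asymmetry
  new("DiffusionOperators", A = A, d = d, Ahat = Ahat,
      AhatM = matrixPower(Ahat, m), m = m)
}

#' m-step diffusion distance between two samples
#'
#' \eqn{D_m(i,j) = \sqrt{\hat A^m_{ii} + \hat A^m_{jj} - 2 \hat A^m_{ij}}}
#' (clamped at 0 before the square root); small when the two samples are
#' strongly connected through the graph.
#'
#' @param ops a [DiffusionOperators-class].
#' @param i,j sample indices.
#' @return non-negative scalar.
#' @export
diffusionDistance <- function(ops, i, j) {
  M <- ops@AhatM
  sqrt(max(0, M[i, i] + M[j, j] - 2 * M[i, j]))
}

#' Diffusion connectivity similarity between two samples
#'
#' \eqn{r_{ij} = (\hat A^m_{ij})^2 / (\hat A^m_{ii}\,\hat A^m_{jj})};
#' for even m this lies in [0, 1] with \eqn{r_{ii} = 1}.
#'
#' @param ops a [DiffusionOperators-class].
#' @param i,j sample indices.
#' @return scalar similarity.
#' @export
connectivitySimilarity <- function(ops, i, j) {
  M <- ops@AhatM
  if (M[i, i] <= 0 || M[j, j] <= 0)
    stop("zero diagonal of Ahat^m at node ",
         if (M[i, i] <= 0) i else j,
         " (odd m on bipartite structure?)")
  M[i, j]^2 / (M[i, i] * M[j, j])
}

# Full matrix of pairwise connectivity similarities.
connectivityMatrix <- function(ops) {
  M <- ops@AhatM
  dg <- diag(M)
  if (any(dg <= 0))
    stop("zero diagonal of Ahat^m at node ", which(dg <= 0)[1L],
         " (odd m on bipartite structure?)")
  M^2 / outer(dg, dg)
}

#' Prior cluster probabilities from seed connectivity
#'
#' For each non-seed sample i, the prior probability of cluster k is the
#' seed-set-averaged connectivity similarity, normalized over clusters:
#' \deqn{p_k(x_i) = \frac{|S_k|^{-1}\sum_{j \in S_k} r_{ij}}
#'   {\sum_{k'} |S_{k'}|^{-1}\sum_{j' \in S_{k'}} r_{ij'}}.}
#' Seeds get probability 1 on their own cluster and 0 elsewhere. All
#' entries are then clamped into `[clampEps, 1 - clampEps]` and each row
#' renormalized, which keeps the region forces finite. A non-seed with
#' zero connectivity to every seed receives a uniform row with a
#' warning.
#'
#' @param ops a [DiffusionOperators-class].
#' @param seeds list of disjoint non-empty integer vectors, one per
#'   cluster, giving the seed sample indices.
#' @param clampEps clamping bound in (0, 0.5).
#' @return a [RegionForces-class] with `P` filled and `F` unset.
#' @export
priorProbabilities <- function(ops, seeds, clampEps = 1e-6) {
  n <- nSamples(ops)
  K <- length(seeds)
  stopifnot(K >= 1L, clampEps > 0, clampEps < 0.5)
  sizes <- lengths(seeds)
  if (any(sizes == 0L)) stop("every seed set must be non-empty")
  allSeeds <- unlist(seeds)
  if (anyDuplicated(allSeeds)) stop("seed sets must be disjoint")
  R <- connectivityMatrix(ops)
  score <- vapply(seeds, function(s)
    rowMeans(R[, s, drop = FALSE]), numeric(n))   # n x K
  score <- matrix(score, nrow = n)
  tot <- rowSums(score)
  P <- matrix(1 / K, n, K)
  dead <- tot <= 0
  ok <- !dead
  P[ok, ] <- score[ok, , drop = FALSE] / tot[ok]
  seedAssign <- integer(n)
  for (kk in seq_len(K)) seedAssign[seeds[[kk]]] <- kk
  isSeed <- seedAssign > 0L
  P[isSeed, ] <- 0
  P[cbind(which(isSeed), seedAssign[isSeed])] <- 1
  if (any(dead & !isSeed))
    warning(sum(dead & !isSeed),
            " sample(s) with zero connectivity to every seed; uniform prior used")
  P <- pmin(pmax(P, clampEps), 1 - clampEps)
  P <- P / rowSums(P)
  new("RegionForces", P = P, F = NULL, seedAssignment = seedAssign,
      clampEps = clampEps)
}

#' Automatic cut-force balance for the max-flow stage
#'
#' The clamped prior of a seed exerts a fixed force swing of
#' \eqn{2L = 2\log((1-\epsilon)/\epsilon)} between its own and any other
#' cluster, while relabelling a node can save at most
#' \eqn{2\alpha d_i} of cut energy (\eqn{d_i} = its weighted degree).
#' With \eqn{\alpha} below \eqn{L/d_i} a seed can never be absorbed and
#' the merging that drives cluster-number selection is inoperable. The
#' automatic scale
#' \deqn{\alpha = 2L/\bar d, \quad \bar d = \mathrm{mean}_i\, d_i,}
#' lets a seed be absorbed exactly when its neighbourhood disagrees
#' unanimously and its degree is at least half the mean; seeds inside
#' genuine structure are protected by their agreeing neighbourhood, not
#' by the pin.
#'
#' @param g a [SimilarityGraph-class].
#' @param clampEps probability clamp used for the region forces.
#' @return positive scalar alpha.
#' @export
alphaAuto <- function(g, clampEps = 1e-6) {
  d <- Matrix::rowSums(g@adjacency)
  2 * log((1 - clampEps) / clampEps) / mean(d)
}

#' Region forces from prior probabilities
#'
#' Fills \eqn{f_k(x_i) = -\log p_k(x_i) + \log(1 - p_k(x_i))}, the unary
#' energy term that pulls each sample toward the clusters its prior
#' supports; clamping of P guarantees finiteness.
#'
#' @param x a [RegionForces-class] with `P` set, or a bare probability
#'   matrix with rows on the simplex.
#' @param clampEps clamping bound applied when `x` is a bare matrix.
#' @return a [RegionForces-class] with `F` filled.
#' @export
regionForces <- function(x, clampEps = 1e-6) {
  if (is.matrix(x)) {
    P <- pmin(pmax(x, clampEps), 1 - clampEps)
    P <- P / rowSums(P)
    x <- new("RegionForces", P = P, F = NULL,
             seedAssignment = integer(nrow(P)), clampEps = clampEps)
  }
  stopifnot(is(x, "RegionForces"))
  x@F <- -log(x@P) + log1p(-x@P)
  validObject(x)
  x
}
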