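#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t isSymmetric diag rowSums colSums crossprod
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Run configuration for the stratification pipeline
#'
#' Holds every tunable parameter of the pipeline with validated bounds.
#' Construct with [redisxConfig()] or load from YAML with [readRunConfig()].
#'
#' @slot nHVG number of high-variance genes retained before clustering.
#' @slot knnK neighbourhood size of the cosine KNN similarity graph.
#' @slot diffusionM number of diffusion steps (even).
#' @slot alpha regularization balancing the cut term against region forces.
#' @slot kMax largest requested cluster number in the evaluation loop.
#' @slot kMin smallest requested cluster number in the evaluation loop.
#' @slot probClampEps clamping bound keeping prior probabilities inside
#'   (0, 1) so region forces stay finite.
#' @slot pdMaxIter,pdTol primal-dual iteration cap and convergence tolerance
#'   on the mean absolute change of the assignment matrix.
#' @slot seed seed for the stochastic parts (seed subsampling, embeddings).
#' @slot deP,deLfc significance and absolute log-fold-change thresholds for
#'   differential expression.
#' @slot deAdjusted apply the p-value threshold to BH-adjusted p-values.
#' @slot linkage inter-cluster distance used for pre-labelling: "average"
#'   (mean pairwise Euclidean distance) or "ward".
#' @slot seedPolicy how CMF seeds are drawn within each pre-cluster:
#'   "medoid" (deterministic) or "random".
#' @slot nRepeats independent repeats per requested k in the evaluation loop.
#' @slot priorDf prior degrees of freedom of the variance moderation in the
#'   differential-expression test.
#' @slot moderate use empirical-Bayes variance moderation (FALSE = plain
#'   Welch test).
#' @export
setClass("RedisXConfig", representation(
  nHVG = "integer", knnK = "integer", diffusionM = "integer",
  alpha = "numeric", kMax = "integer", kMin = "integer",
  probClampEps = "numeric", pdMaxIter = "integer", pdTol = "numeric",
  seed = "integer", deP = "numeric", deLfc = "numeric",
  deAdjusted = "logical", linkage = "character", seedPolicy = "character",
  nRepeats = "integer", priorDf = "numeric", moderate = "logical"
))

setValidity("RedisXConfig", function(object) {
  msg <- character()
  chk <- function(cond, text) if (!isTRUE(cond)) msg <<- c(msg, text)
  chk(object@nHVG >= 1L, "nHVG must be a positive integer")
  chk(object@knnK >= 1L, "knnK must be a positive integer")
  chk(object@diffusionM >= 1L, "diffusionM must be positive")
  chk(object@diffusionM %% 2L == 0L, "diffusionM must be even")
  chk(is.na(object@alpha) || object@alpha > 0,
      "alpha must be positive (or NA for the automatic scale)")
  chk(object@kMax >= 1L, "kMax must be a positive integer")
  chk(object@kMin >= 1L && object@kMin <= object@kMax,
      "kMin must lie in [1, kMax]")
  chk(object@probClampEps > 0 && object@probClampEps < 0.5,
      "probClampEps must be in (0, 0.5)")
  chk(object@pdMaxIter >= 1L, "pdMaxIter must be positive")
  chk(object@pdTol > 0, "pdTol must be positive")
  chk(object@seed >= 0L, "seed must be non-negative")
  chk(object@deP > 0 && object@deP < 1, "deP must be in (0,1)")
  chk(object@deLfc >= 0, "deLfc must be non-negative")
  chk(object@linkage %in% c("average", "ward"),
      "linkage must be 'average' or 'ward'")
  chk(object@seedPolicy %in% c("medoid", "random"),
      "seedPolicy must be 'medoid' or 'random'")
  chk(object@nRepeats >= 1L, "nRepeats must be positive")
  chk(object@priorDf >= 0, "priorDf must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Symmetric cosine KNN similarity graph over samples
#'
#' Undirected weighted graph built by [buildKnnGraph()]: each sample is
#' connected to its K most cosine-similar other samples, the edge set is
#' symmetrized by union, and negative similarities are clamped to zero.
#'
#' @slot adjacency symmetric sparse n x n weight matrix, zero diagonal.
#' @slot knnK neighbourhood size used to build the graph.
#' @export
setClass("SimilarityGraph", representation(
  adjacency = "Matrix", knnK = "integer"
))

setValidity("SimilarityGraph", function(object) {
  W <- object@adjacency
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "adjacency must be square")
  if (any(Matrix::diag(W) != 0)) msg <- c(msg, "self-loops are not allowed")
  x <- W@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    msg <- c(msg, "edge weights must be finite and non-negative")
  if (!Matrix::isSymmetric(W, tol = 0))
    msg <- c(msg, "adjacency must be exactly symmetric")
  if (length(msg)) msg else TRUE
})

#' Diffusion operators of a similarity graph
#'
#' The row-stochastic transition matrix A, the degree vector d, the
#' symmetrically normalized operator Ahat = D^{1/2} A D^{-1/2}, and its
#' m-th power, as produced by [diffusionOperators()].
#'
#' @slot A row-stochastic transition matrix.
#' @slot d node degrees (row sums of the adjacency).
#' @slot Ahat symmetrically normalized operator.
#' @slot AhatM m-th matrix power of Ahat.
#' @slot m number of diffusion steps.
#' @export
setClass("DiffusionOperators", representation(
  A = "matrix", d = "numeric", Ahat = "matrix", AhatM = "matrix",
  m = "integer"
))

setValidity("DiffusionOperators", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@A) - 1) > 1e-10))
    msg <- c(msg, "rows of A must sum to 1")
  if (max(abs(object@Ahat - t(object@Ahat))) > 1e-12)
    msg <- c(msg, "Ahat must be symmetric")
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Prior probabilities and region forces for the CMF stage
#'
#' Per-sample, per-cluster prior probabilities P derived from diffusion
#' connectivity to the seed sets, and the region forces
#' F = -log(P) + log(1 - P) consumed by the max-flow solver.
#'
#' @slot P n x K prior probability matrix, rows on the simplex, entries
#'   clamped into [clampEps, 1 - clampEps].
#' @slot F n x K region force matrix (NULL until [regionForces()] is
#'   applied).
#' @slot seedAssignment per-sample cluster index of seeds, 0 for non-seeds.
#' @slot clampEps clamping bound used on P.
#' @export
setClass("RegionForces", representation(
  P = "matrix", F = "matrixOrNULL", seedAssignment = "integer",
  clampEps = "numeric"
))

setValidity("RegionForces", function(object) {
  msg <- character()
  P <- object@P
  eps <- object@clampEps
  if (any(abs(rowSums(P) - 1) > 1e-10))
    msg <- c(msg, "rows of P must sum to 1")
  tol <- eps * 0.01 + 1e-12  # renormalization after clamping shifts entries by O(K*eps^2)
  if (any(P < eps - tol) || any(P > 1 - eps + tol))
    msg <- c(msg, "P entries must lie in [clampEps, 1 - clampEps]")
  if (length(object@seedAssignment) != nrow(P))
    msg <- c(msg, "seedAssignment must have one entry per sample")
  if (!is.null(object@F)) {
    expect <- -log(P) + log1p(-P)
    if (max(abs(object@F - expect)) > 1e-8)
      msg <- c(msg, "F must equal -log(P) + log(1 - P)")
  }
  if (length(msg)) msg else TRUE
})

#' Hierarchical pre-labelling result
#'
#' Cluster pre-labels from agglomerative clustering plus, after
#' [selectSeeds()], an equal-sized seed set per cluster (the minimal
#' cluster size), whose members enter the CMF stage with prior
#' probability 1 on their own cluster.
#'
#' @slot labels per-sample cluster label in 1..k.
#' @slot k requested number of clusters.
#' @slot seedMask TRUE for samples used as CMF seeds (empty until
#'   [selectSeeds()]).
#' @slot seedsPerCluster number of seeds in every cluster.
#' @export
setClass("PrelabelResult", representation(
  labels = "integer", k = "integer", seedMask = "logical",
  seedsPerCluster = "integer"
))

setValidity("PrelabelResult", function(object) {
  msg <- character()
  lab <- object@labels
  k <- object@k
  if (any(lab < 1L | lab > k)) msg <- c(msg, "labels must lie in 1..k")
  if (!all(seq_len(k) %in% lab))
    msg <- c(msg, "every cluster 1..k must contain at least one sample")
  if (length(object@seedMask)) {
    if (length(object@seedMask) != length(lab))
      msg <- c(msg, "seedMask must have one entry per sample")
    else {
      perCluster <- vapply(seq_len(k), function(kk)
        sum(object@seedMask & lab == kk), integer(1))
      minSize <- min(tabulate(lab, nbins = k))
      if (!all(perCluster == minSize))
        msg <- c(msg, "seed count must equal the minimal cluster size in every cluster")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Continuous max-flow solution
#'
#' Relaxed simplex assignment, thresholded hard labels, the relaxed and
#' discrete energies, and convergence diagnostics of the primal-dual
#' solver.
#'
#' @slot Phi n x K relaxed assignment matrix, rows on the probability
#'   simplex.
#' @slot labels row-wise argmax labels (ties to the lowest cluster index).
#' @slot energyRelaxed relaxed total-variation energy at Phi.
#' @slot energyDiscrete discrete cut-plus-force energy at the thresholded
#'   labels.
#' @slot iterations number of primal-dual iterations performed.
#' @slot converged TRUE when the residual fell below tolerance.
#' @slot residuals mean absolute change of Phi per recorded iteration.
#' @export
setClass("CMFSolution", representation(
  Phi = "matrix", labels = "integer", energyRelaxed = "numeric",
  energyDiscrete = "numeric", iterations = "integer",
  converged = "logical", residuals = "numeric"
))

setValidity("CMFSolution", function(object) {
  msg <- character()
  Phi <- object@Phi
  if (any(Phi < -1e-8) || any(Phi > 1 + 1e-8))
    msg <- c(msg, "Phi entries must lie in [0, 1]")
  if (any(abs(rowSums(Phi) - 1) > 1e-8))
    msg <- c(msg, "Phi rows must lie on the probability simplex")
  argmax <- as.integer(max.col(Phi, ties.method = "first"))
  if (!all(object@labels == argmax))
    msg <- c(msg, "labels must be the row-wise argmax of Phi (ties to lowest index)")
  if (length(msg)) msg else TRUE
})

#' Cluster-number evaluation result
#'
#' Surviving (non-empty) cluster counts of the CMF fit for every requested
#' k, and the modal count taken as the optimal number of subpopulations.
#'
#' @slot requestedK requested cluster numbers (kMin..kMax).
#' @slot survivingCounts non-empty clusters after CMF per requested k.
#' @slot optimalK statistical mode of the surviving counts; ties broken
#'   toward the larger k.
#' @slot tieBroken TRUE if the mode was not unique.
#' @export
setClass("ClusterEvaluationResult", representation(
  requestedK = "integer", survivingCounts = "integer",
  optimalK = "integer", tieBroken = "logical"
))

setValidity("ClusterEvaluationResult", function(object) {
  msg <- character()
  if (length(object@requestedK) != length(object@survivingCounts))
    msg <- c(msg, "requestedK and survivingCounts must align")
  if (any(object@survivingCounts > object@requestedK))
    msg <- c(msg, "surviving count cannot exceed the requested k")
  if (!(object@optimalK %in% object@survivingCounts))
    msg <- c(msg, "optimalK must be one of the surviving counts")
  if (length(msg)) msg else TRUE
})

#' Specification of a planted-structure synthetic expression dataset
#'
#' Describes k planted subpopulations each carrying a block of uniquely
#' shifted genes over a shared baseline, optional healthy controls at
#' baseline, Gaussian noise, and an optional shared signature block for
#' cross-disease experiments. Construct with [syntheticSpec()].
#'
#' @slot kPlanted number of planted subpopulations.
#' @slot samplesPerCluster case samples per subpopulation.
#' @slot nControls control samples drawn at baseline.
#' @slot nGenes total genes.
#' @slot nDePerCluster genes uniquely shifted in each subpopulation.
#' @slot effect mean shift of a differentially expressed gene (log units);
#'   half of each block is shifted up, half down.
#' @slot sigma within-group noise standard deviation.
#' @slot sharedBlock genes reserved for a signature shared with a second
#'   dataset.
#' @slot seed RNG seed making the draw reproducible.
#' @export
setClass("SyntheticSpec", representation(
  kPlanted = "integer", samplesPerCluster = "integer", nControls = "integer",
  nGenes = "integer", nDePerCluster = "integer", effect = "numeric",
  sigma = "numeric", sharedBlock = "integer", seed = "integer"
))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@kPlanted < 1L) msg <- c(msg, "kPlanted must be >= 1")
  if (object@samplesPerCluster < 2L)
    msg <- c(msg, "samplesPerCluster must be >= 2")
  if (object@nControls < 0L) msg <- c(msg, "nControls must be >= 0")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (object@sharedBlock < 0L) msg <- c(msg, "sharedBlock must be >= 0")
  if (object@kPlanted * object@nDePerCluster + object@sharedBlock >
      object@nGenes)
    msg <- c(msg, "kPlanted * nDePerCluster + sharedBlock must not exceed nGenes")
  if (length(msg)) msg else TRUE
})
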