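#' @importFrom stats var sd dist loess predict pt p.adjust setNames
#'   prcomp rnorm runif quantile
#' @importFrom utils read.delim write.table head
NULL

#' Number of samples spanned by an object
#' @param x a [SimilarityGraph] or [DiffusionOperators] object.
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Hard cluster labels carried by an object
#' @param object a [PrelabelResult] or [CMFSolution].
#' @param ... ignored.
#' @return integer vector of 1-based cluster labels.
#' @export
setGeneric("clusterLabels", function(object, ...)
  standardGeneric("clusterLabels"))

#' @rdname nSamples
#' @export
setMethod("nSamples", "SimilarityGraph", function(x) nrow(x@adjacency))

#' @rdname nSamples
#' @export
setMethod("nSamples", "DiffusionOperators", function(x) nrow(x@A))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "PrelabelResult", function(object, ...)
  object@labels)

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "CMFSolution", function(object, ...)
  object@labels)

#' Edge list of a similarity graph
#'
#' @param x a [SimilarityGraph].
#' @return a data.frame with columns `i`, `j` (1-based, i < j) and
#'   weight `w`.
#' @export
graphEdges <- function(x) {
  stopifnot(is(x, "SimilarityGraph"))
  W <- as(Matrix::triu(x@adjacency), "TsparseMatrix")
  ord <- order(W@i, W@j)
  data.frame(i = W@i[ord] + 1L, j = W@j[ord] + 1L, w = W@x[ord])
}

setMethod("show", "SimilarityGraph", function(object) {
  cat("SimilarityGraph:", nSamples(object), "samples,",
      length(graphEdges(object)$w), "edges (knnK =", object@knnK, ")\n")
})

setMethod("show", "DiffusionOperators", function(object) {
  cat("DiffusionOperators:", nSamples(object), "samples, m =",
      object@m, "\n")
})

setMethod("show", "RegionForces", function(object) {
  cat("RegionForces:", nrow(object@P), "samples x", ncol(object@P),
      "clusters;", sum(object@seedAssignment > 0L), "seeds; forces",
      if (is.null(object@F)) "not yet computed\n" else "computed\n")
})

setMethod("show", "PrelabelResult", function(object) {
  cat("PrelabelResult: k =", object@k, "over", length(object@labels),
      "samples")
  if (length(object@seedMask))
    cat(";", object@seedsPerCluster, "seeds per cluster")
  cat("\n  cluster sizes:",
      paste(tabulate(object@labels, object@k), collapse = " "), "\n")
})

setMethod("show", "CMFSolution", function(object) {
  cat("CMFSolution:", nrow(object@Phi), "samples x", ncol(object@Phi),
      "clusters\n  surviving clusters:",
      length(unique(object@labels)),
      "| iterations:", object@iterations,
      "| converged:", object@converged, "\n",
      " relaxed energy:", format(object@energyRelaxed),
      "| discrete energy:", format(object@energyDiscrete), "\n")
})

setMethod("show", "ClusterEvaluationResult", function(object) {
  cat("ClusterEvaluationResult over k =",
      paste(range(object@requestedK), collapse = ".."), "\n")
  cat("  surviving counts:",
      paste(object@survivingCounts, collapse = " "), "\n")
  cat("  optimal k:", object@optimalK,
      if (object@tieBroken) "(mode tie broken toward larger k)" else "",
      "\n")
})

setMethod("show", "RedisXConfig", function(object) {
  cat("RedisXConfig: nHVG =", object@nHVG, "| knnK =", object@knnK,
      "| m =", object@diffusionM, "| alpha =", object@alpha,
      "| k in", paste(c(object@kMin, object@kMax), collapse = ".."), "\n")
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@kPlanted, "clusters x",
      object@samplesPerCluster, "samples +", object@nControls,
      "controls;", object@nGenes, "genes,", object@nDePerCluster,
      "DE genes/cluster; effect =", object@effect, ", sigma =",
      object@sigma, "\n")
})

#' Surviving-cluster counts of an evaluation result
#' @param x a [ClusterEvaluationResult].
#' @return data.frame with columns `requested_k` and `surviving_k`.
#' @export
survivingCounts <- function(x) {
  stopifnot(is(x, "ClusterEvaluationResult"))
  data.frame(requested_k = x@requestedK, surviving_k = x@survivingCounts)
}

#' Optimal cluster number of an evaluation result
#' @param x a [ClusterEvaluationResult].
#' @return integer modal surviving-cluster count.
#' @export
optimalK <- function(x) {
  stopifnot(is(x, "ClusterEvaluationResult"))
  x@optimalK
}
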