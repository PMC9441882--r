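#' Continuous max-flow min-cut problem
#'
#' Bundles the similarity graph, the n x K region-force matrix and the
#' regularization parameter alpha that balances the weighted cut against
#' the region forces.
#'
#' @slot graph a [SimilarityGraph-class].
#' @slot F n x K finite force matrix.
#' @slot alpha positive regularization parameter.
#' @export
setClass("CMFProblem", representation(
  graph = "SimilarityGraph", F = "matrix", alpha = "numeric"
))

setValidity("CMFProblem", function(object) {
  msg <- character()
  if (any(!is.finite(object@F))) msg <- c(msg, "F must be finite")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  if (nrow(object@F) != nSamples(object@graph))
    msg <- c(msg, "F must have one row per graph node")
  if (ncol(object@F) < 1L) msg <- c(msg, "K must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn CMFProblem-class constructor.
#' @param graph a [SimilarityGraph-class].
#' @param F n x K region-force matrix (see [regionForces()]).
#' @param alpha positive regularization parameter (default 1).
#' @export
cmfProblem <- function(graph, F, alpha = 1) {
  new("CMFProblem", graph = graph, F = as.matrix(F),
      alpha = as.numeric(alpha))
}

setMethod("show", "CMFProblem", function(object) {
  cat("CMFProblem:", nSamples(object@graph), "nodes x",
      ncol(object@F), "clusters, alpha =", object@alpha, "\n")
})

#' Discrete cut-plus-force energy of a hard labelling
#'
#' \deqn{E = \alpha \sum_{(i,j) \in E} \sum_k w_{ij}\,|[l_i = k] - [l_j
#' = k]| + \sum_i f_{l_i}(x_i);} each cut edge contributes
#' \eqn{2\alpha w_{ij}} because exactly two indicator columns change
#' across it.
#'
#' @param labels integer labels in 1..K.
#' @param problem a [CMFProblem-class].
#' @return scalar energy.
#' @export
discreteEnergy <- function(labels, problem) {
  K <- ncol(problem@F)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > K)) stop("label out of range 1..", K)
  e <- graphEdges(problem@graph)
  cut <- if (nrow(e)) sum(e$w * 2 * (labels[e$i] != labels[e$j])) else 0
  problem@alpha * cut +
    sum(problem@F[cbind(seq_along(labels), labels)])
}

#' Relaxed total-variation energy of a soft assignment
#' @param Phi n x K assignment matrix with rows on the simplex.
#' @param problem a [CMFProblem-class].
#' @return scalar energy
#'   \eqn{\alpha \sum_{(i,j)} w_{ij} \sum_k |\Phi_{ik} - \Phi_{jk}| +
#'   \langle \Phi, F \rangle}.
#' @export
relaxedEnergy <- function(Phi, problem) {
  e <- graphEdges(problem@graph)
  cut <- if (nrow(e))
    sum(e$w * rowSums(abs(Phi[e$i, , drop = FALSE] -
                            Phi[e$j, , drop = FALSE]))) else 0
  problem@alpha * cut + sum(Phi * problem@F)
}

# Sparse weighted edge-difference operator: one row per (edge, class
# handled implicitly); (B Phi)_{e,k} = w_e (Phi_{i,k} - Phi_{j,k}).
edgeDifferenceOperator <- function(graph) {
  e <- graphEdges(graph)
  nE <- nrow(e)
  n <- nSamples(graph)
  if (!nE) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                       x = numeric(0), dims = c(0L, n)))
  Matrix::sparseMatrix(i = c(seq_len(nE), seq_len(nE)),
                       j = c(e$i, e$j), x = c(e$w, -e$w),
                       dims = c(nE, n))
}

# Largest singular value of a sparse operator by power iteration.
# The start vector must not be constant: the constant vector spans the
# null space of an edge-difference operator.
operatorNorm <- function(B, iters = 20L) {
  n <- ncol(B)
  if (nrow(B) == 0L || n == 0L) return(0)
  v <- withSeed(0, rnorm(n))
  v <- v / sqrt(sum(v^2))
  for (t in seq_len(iters)) {
    v <- as.numeric(Matrix::crossprod(B, B %*% v))
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(0)
    v <- v / nv
  }
  sqrt(sum((as.numeric(B %*% v))^2))
}

#' Solve the relaxed continuous max-flow problem
#'
#' First-order primal-dual (Chambolle-Pock) iteration on the saddle
#' problem
#' \deqn{\min_{\Phi \in \Delta} \max_{|\Psi| \le 1} \alpha \langle \Psi,
#'   B\Phi \rangle + \langle \Phi, F \rangle,}
#' where B is the weighted edge-difference operator. The dual update is
#' an entrywise box projection onto [-1, 1]; the primal update is the
#' Euclidean projection of each row of Phi onto the probability simplex.
#' Steps tau = sigma = 0.99 / ||alpha B|| (power-iteration estimate),
#' over-relaxation theta = 1. Phi is warm-started from the priors
#' implied by F (rows of the logistic transform of -F, renormalized).
#' Convergence is declared when both the mean absolute change of Phi
#' and of Psi fall below `tol` (the primal alone can sit at a simplex
#' vertex while the dual is still charging the cut, so a primal-only
#' test can stop at a suboptimal labelling); at `maxIter` without
#' convergence the last iterate is returned with a warning.
#'
#' @param problem a [CMFProblem-class].
#' @param maxIter iteration cap (default 10000).
#' @param tol tolerance on the mean absolute change of the iterates
#'   (default 1e-6).
#' @param Phi0 optional n x K initialization with rows on the simplex.
#' @param checkFeasible assert simplex/box feasibility of every iterate
#'   (used by the property tests; slows the solver down).
#' @return a [CMFSolution-class].
#' @export
solveCMF <- function(problem, maxIter = 10000, tol = 1e-6, Phi0 = NULL,
                     checkFeasible = FALSE) {
  validObject(problem)
  F <- problem@F
  n <- nrow(F); K <- ncol(F)
  if (K == 1L) {
    Phi <- matrix(1, n, 1L)
    lab <- rep(1L, n)
    return(new("CMFSolution", Phi = Phi, labels = lab,
               energyRelaxed = relaxedEnergy(Phi, problem),
               energyDiscrete = discreteEnergy(lab, problem),
               iterations = 0L, converged = TRUE, residuals = numeric(0)))
  }
  B <- edgeDifferenceOperator(problem@graph) * problem@alpha
  if (is.null(Phi0)) {
    Phi <- 1 / (1 + exp(F))           # invert f = -log p + log(1-p)
    Phi <- Phi / rowSums(Phi)
  } else {
    Phi <- as.matrix(Phi0)
    stopifnot(nrow(Phi) == n, ncol(Phi) == K)
  }
  nE <- nrow(B)
  if (nE == 0L) {
    # no cut term: the linear program over the simplex picks the
    # minimum-force vertex in each row
    lab <- as.integer(max.col(-F, ties.method = "first"))
    Phi <- matrix(0, n, K)
    Phi[cbind(seq_len(n), lab)] <- 1
    return(new("CMFSolution", Phi = Phi, labels = lab,
               energyRelaxed = relaxedEnergy(Phi, problem),
               energyDiscrete = discreteEnergy(lab, problem),
               iterations = 0L, converged = TRUE, residuals = numeric(0)))
  }
  nrm <- operatorNorm(B)
  if (nrm == 0) nrm <- 1
  tau <- 0.99 / nrm
  sigma <- 0.99 / nrm
  Psi <- matrix(0, nE, K)
  PhiBar <- Phi
  converged <- FALSE
  iter <- 0L
  residuals <- numeric(maxIter)
  while (iter < maxIter) {
    iter <- iter + 1L
    PsiNew <- Psi + sigma * as.matrix(B %*% PhiBar)
    PsiNew[PsiNew > 1] <- 1; PsiNew[PsiNew < -1] <- -1
    PhiNew <- projectSimplexRows(
      Phi - tau * (as.matrix(Matrix::crossprod(B, PsiNew)) + F))
    if (checkFeasible) {
      stopifnot(all(abs(rowSums(PhiNew) - 1) <= 1e-8),
                all(PhiNew >= -1e-8), all(PhiNew <= 1 + 1e-8),
                all(abs(PsiNew) <= 1))
    }
    # the primal can sit at a simplex vertex while the dual is still
    # accumulating toward its box bound, so convergence requires both
    # the primal and the dual change to settle
    res <- max(mean(abs(PhiNew - Phi)), mean(abs(PsiNew - Psi)))
    residuals[iter] <- res
    PhiBar <- 2 * PhiNew - Phi
    Phi <- PhiNew
    Psi <- PsiNew
    if (res < tol) { converged <- TRUE; break }
  }
  residuals <- residuals[seq_len(iter)]
  if (!converged)
    warning("primal-dual iteration did not converge in ", maxIter,
            " iterations (last residual ",
            format(residuals[length(residuals)]), ")")
  lab <- thresholdLabels(Phi)
  new("CMFSolution", Phi = Phi, labels = lab,
      energyRelaxed = relaxedEnergy(Phi, problem),
      energyDiscrete = discreteEnergy(lab, problem),
      iterations = iter, converged = converged, residuals = residuals)
}

#' Hard labels from a soft assignment
#'
#' Row-wise argmax of Phi; ties resolve to the lowest cluster index.
#'
#' @param Phi n x K matrix with rows on the probability simplex.
#' @return integer labels in 1..K.
#' @export
thresholdLabels <- function(Phi) {
  Phi <- as.matrix(Phi)
  as.integer(max.col(Phi, ties.method = "first"))
}

#' Exhaustive discrete min-cut oracle
#'
#' Enumerates all K^n hard labelings and returns a global minimizer of
#' [discreteEnergy()] (ties to the lexicographically smallest
#' labelling). Only feasible for tiny instances; used to validate the
#' relaxed solver.
#'
#' @param problem a [CMFProblem-class] with K^n <= 2^20.
#' @return list with `labels` and `energy`.
#' @export
bruteForceMincut <- function(problem) {
  n <- nrow(problem@F); K <- ncol(problem@F)
  if (K^n > 2^20) stop("instance too large for exhaustive enumeration")
  best <- NULL; bestE <- Inf
  lab <- rep(1L, n)
  repeat {
    e <- discreteEnergy(lab, problem)
    if (e < bestE - 1e-12) { bestE <- e; best <- lab }
    # advance odometer (last index fastest -> lexicographic order)
    pos <- n
    while (pos >= 1L && lab[pos] == K) { lab[pos] <- 1L; pos <- pos - 1L }
    if (pos < 1L) break
    lab[pos] <- lab[pos] + 1L
  }
  list(labels = best, energy = bestE)
}
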