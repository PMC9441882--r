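#' Average-linkage distance between two clusters
#'
#' The mean of all pairwise Euclidean distances between the members of
#' the two clusters:
#' \deqn{d(C_i, C_j) = \frac{1}{|C_i||C_j|}\sum_{x \in C_i}\sum_{y \in
#'   C_j} \|x - y\|.}
#'
#' @param Ci,Cj numeric matrices with one sample per row (a bare vector
#'   is treated as a single sample).
#' @return non-negative scalar.
#' @examples
#' clusterDistance(c(0, 0), c(3, 4))  # 5
#' @export
clusterDistance <- function(Ci, Cj) {
  if (is.null(dim(Ci))) Ci <- matrix(Ci, nrow = 1L)
  if (is.null(dim(Cj))) Cj <- matrix(Cj, nrow = 1L)
  if (!nrow(Ci) || !nrow(Cj)) stop("clusters must be non-empty")
  if (ncol(Ci) != ncol(Cj)) stop("dimension mismatch between clusters")
  tot <- 0
  for (i in seq_len(nrow(Ci)))
    tot <- tot + sum(sqrt(colSums((t(Cj) - Ci[i, ])^2)))
  tot / (nrow(Ci) * nrow(Cj))
}

#' Agglomerative hierarchical pre-labelling
#'
#' Starts from singletons and greedily merges the two nearest clusters
#' under the average-linkage distance ([clusterDistance()]) until `k`
#' clusters remain. Fully deterministic: distance ties are broken by the
#' pair whose clusters have the smallest (then second-smallest)
#' lowest-index members. The `"ward"` linkage delegates to
#' \code{\link[stats]{hclust}} (`ward.D2`). Clusters are numbered 1..k by
#' their lowest-index member.
#'
#' @param X numeric matrix, one sample per row (features in columns).
#' @param k requested number of clusters, 1 <= k <= nrow(X).
#' @param linkage `"average"` (default) or `"ward"`.
#' @return a [PrelabelResult-class] with labels set and seed fields
#'   empty.
#' @export
hierarchicalPrelabel <- function(X, k, linkage = "average") {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]")
  if (linkage == "ward") {
    hc <- stats::hclust(stats::dist(X), method = "ward.D2")
    lab <- relabelDense(stats::cutree(hc, k = k))
    return(new("PrelabelResult", labels = as.integer(lab), k = k,
               seedMask = logical(0), seedsPerCluster = NA_integer_))
  }
  if (linkage != "average") stop("unknown linkage: ", linkage)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  size <- rep(1L, n)
  low <- seq_len(n)            # lowest-index member per active slot
  active <- rep(TRUE, n)
  member <- as.list(seq_len(n))
  while (sum(active) > k) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    a <- pmin(low[idx[cand[, 1L]]], low[idx[cand[, 2L]]])
    b <- pmax(low[idx[cand[, 1L]]], low[idx[cand[, 2L]]])
    pick <- order(a, b)[1L]
    i <- idx[cand[pick, 1L]]; j <- idx[cand[pick, 2L]]
    # average-linkage Lance-Williams update into slot i
    oth <- setdiff(idx, c(i, j))
    if (length(oth)) {
      newd <- (size[i] * D[i, oth] + size[j] * D[j, oth]) /
        (size[i] + size[j])
      D[i, oth] <- newd; D[oth, i] <- newd
    }
    member[[i]] <- c(member[[i]], member[[j]])
    size[i] <- size[i] + size[j]
    low[i] <- min(low[i], low[j])
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }
  slots <- which(active)
  slots <- slots[order(low[slots])]
  lab <- integer(n)
  for (kk in seq_along(slots)) lab[member[[slots[kk]]]] <- kk
  new("PrelabelResult", labels = lab, k = k,
      seedMask = logical(0), seedsPerCluster = NA_integer_)
}

#' Select equal-sized seed sets from pre-labels
#'
#' Every cluster contributes the same number of seeds — the minimal
#' cluster size — so no cluster dominates the prior. The `"medoid"`
#' policy picks, within each cluster, the samples with smallest summed
#' Euclidean distance to their co-members (ties by sample index) and is
#' fully deterministic; `"random"` samples uniformly without replacement
#' under `seed`.
#'
#' @param X numeric matrix, one sample per row.
#' @param pre a [PrelabelResult-class] with labels set.
#' @param policy `"medoid"` (default) or `"random"`.
#' @param seed RNG seed for the random policy.
#' @return the input [PrelabelResult-class] with `seedMask` and
#'   `seedsPerCluster` filled.
#' @export
selectSeeds <- function(X, pre, policy = c("medoid", "random"), seed = 0) {
  policy <- match.arg(policy)
  X <- as.matrix(X)
  lab <- pre@labels
  stopifnot(nrow(X) == length(lab))
  sizes <- tabulate(lab, pre@k)
  m <- min(sizes)
  mask <- logical(length(lab))
  for (kk in seq_len(pre@k)) {
    members <- which(lab == kk)
    if (policy == "medoid") {
      if (length(members) == 1L) {
        chosen <- members
      } else {
        sub <- X[members, , drop = FALSE]
        dd <- as.matrix(stats::dist(sub))
        score <- rowSums(dd)
        chosen <- members[order(score, members)[seq_len(m)]]
      }
    } else {
      chosen <- withSeed(seed + kk,
                         sample(members, m, replace = FALSE))
    }
    mask[chosen] <- TRUE
  }
  new("PrelabelResult", labels = lab, k = pre@k, seedMask = mask,
      seedsPerCluster = m)
}
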