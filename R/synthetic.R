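#' Specification of a planted-structure synthetic dataset
#'
#' See [SyntheticSpec-class] for the meaning of each field. The defaults
#' emulate a well-separated microarray-style cohort: Gaussian log-scale
#' intensities, cluster-specific blocks of differentially expressed
#' genes (half shifted up, half down) over a shared baseline, and
#' controls at baseline.
#'
#' @param kPlanted,samplesPerCluster,nControls,nGenes,nDePerCluster
#'   planted design; see [SyntheticSpec-class].
#' @param effect,sigma,sharedBlock,seed see [SyntheticSpec-class].
#' @return a validated [SyntheticSpec-class].
#' @export
syntheticSpec <- function(kPlanted = 3, samplesPerCluster = 40,
                          nControls = 0, nGenes = 500,
                          nDePerCluster = 50, effect = 5, sigma = 0.5,
                          sharedBlock = 0, seed = 0) {
  new("SyntheticSpec", kPlanted = as.integer(kPlanted),
      samplesPerCluster = as.integer(samplesPerCluster),
      nControls = as.integer(nControls), nGenes = as.integer(nGenes),
      nDePerCluster = as.integer(nDePerCluster),
      effect = as.numeric(effect), sigma = as.numeric(sigma),
      sharedBlock = as.integer(sharedBlock), seed = as.integer(seed))
}

#' Generate a planted-structure expression dataset
#'
#' Baseline per-gene means are drawn from Normal(0, 1) and shared by all
#' samples; each planted cluster shifts its own block of
#' `nDePerCluster` genes by +/- `effect` (first half up, second half
#' down — deterministic so fixtures are reproducible); i.i.d.
#' Normal(0, sigma) noise is added; controls are drawn at baseline.
#' Gene blocks are disjoint across clusters, and the first
#' `sharedBlock` genes after the cluster blocks are reserved for
#' [makePairedDatasets()]. Fully reproducible under `spec@seed`.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with `dataset` (a `SummarizedExperiment` whose colData
#'   carries a `group` column), `labels` (named true cluster labels of
#'   the case samples), `controlIds`, and `deGenes` (list of planted DE
#'   gene identifiers per cluster, with attribute `"direction"`).
#' @export
makeClusteredExpression <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, makeClusteredExpressionImpl(spec))
}

makeClusteredExpressionImpl <- function(spec, sharedGenes = NULL,
                                        sharedSigns = NULL,
                                        sharedCluster = 0L) {
  k <- spec@kPlanted
  nCase <- k * spec@samplesPerCluster
  n <- nCase + spec@nControls
  geneIds <- sprintf("gene%05d", seq_len(spec@nGenes))
  sampleIds <- c(sprintf("case%03d", seq_len(nCase)),
                 if (spec@nControls)
                   sprintf("ctrl%03d", seq_len(spec@nControls)))
  labels <- rep(seq_len(k), each = spec@samplesPerCluster)
  baseline <- rnorm(spec@nGenes)
  mu <- matrix(baseline, spec@nGenes, n)
  deGenes <- vector("list", k)
  offset <- 0L
  for (kk in seq_len(k)) {
    idx <- offset + seq_len(spec@nDePerCluster)
    offset <- offset + spec@nDePerCluster
    nUp <- ceiling(spec@nDePerCluster / 2)
    shift <- rep(c(spec@effect, -spec@effect),
                 c(nUp, spec@nDePerCluster - nUp))
    cols <- which(labels == kk)
    mu[idx, cols] <- mu[idx, cols] + shift
    dg <- geneIds[idx]
    attr(dg, "direction") <- ifelse(shift > 0, "up", "down")
    deGenes[[kk]] <- dg
  }
  if (!is.null(sharedGenes)) {
    cols <- which(labels == sharedCluster)
    mu[sharedGenes, cols] <- mu[sharedGenes, cols] + sharedSigns
  }
  values <- mu + matrix(rnorm(spec@nGenes * n, sd = spec@sigma),
                        spec@nGenes, n)
  dimnames(values) <- list(geneIds, sampleIds)
  group <- rep(c("case", "control"), c(nCase, spec@nControls))
  se <- expressionDataset(values,
                          sampleMeta = data.frame(group = group))
  list(dataset = se,
       labels = setNames(as.integer(labels), sampleIds[seq_len(nCase)]),
       controlIds = sampleIds[-seq_len(nCase)][seq_len(spec@nControls)],
       deGenes = deGenes)
}

#' Generate two datasets sharing one signature block
#'
#' For cross-disease homogeneity experiments: the designated cluster of
#' each dataset carries the *same* shared signature — the same
#' `sharedBlock` gene identifiers with the same signed shifts (first
#' half up) — while every other planted block is disjoint between the
#' two datasets. Both specs must have `sharedBlock > 0` (and equal).
#'
#' @param specA,specB [SyntheticSpec-class] objects with matching
#'   `sharedBlock` and `nGenes`.
#' @param sharedClusterPair length-2 integer: which cluster of A and of
#'   B carries the shared signature (default both 1).
#' @return list with `a` and `b` (each as returned by
#'   [makeClusteredExpression()]) plus `sharedGenes` and
#'   `sharedClusterPair`.
#' @export
makePairedDatasets <- function(specA, specB, sharedClusterPair = c(1L, 1L)) {
  validObject(specA); validObject(specB)
  if (specA@sharedBlock <= 0L || specB@sharedBlock <= 0L)
    stop("both specs need sharedBlock > 0")
  if (specA@sharedBlock != specB@sharedBlock ||
      specA@nGenes != specB@nGenes)
    stop("the two specs must agree on nGenes and sharedBlock")
  sharedClusterPair <- as.integer(sharedClusterPair)
  stopifnot(length(sharedClusterPair) == 2L,
            sharedClusterPair[1L] %in% seq_len(specA@kPlanted),
            sharedClusterPair[2L] %in% seq_len(specB@kPlanted))
  nShared <- specA@sharedBlock
  # shared genes sit after the larger of the two cluster-block regions
  start <- max(specA@kPlanted * specA@nDePerCluster,
               specB@kPlanted * specB@nDePerCluster)
  if (start + nShared > specA@nGenes)
    stop("sharedBlock does not fit after the cluster blocks")
  sharedIdx <- start + seq_len(nShared)
  nUp <- ceiling(nShared / 2)
  signs <- rep(c(specA@effect, -specA@effect), c(nUp, nShared - nUp))
  a <- withSeed(specA@seed,
                makeClusteredExpressionImpl(specA, sharedGenes = sharedIdx,
                                            sharedSigns = signs,
                                            sharedCluster = sharedClusterPair[1L]))
  b <- withSeed(specB@seed,
                makeClusteredExpressionImpl(specB, sharedGenes = sharedIdx,
                                            sharedSigns = signs,
                                            sharedCluster = sharedClusterPair[2L]))
  sharedGenes <- sprintf("gene%05d", sharedIdx)
  attr(sharedGenes, "direction") <- ifelse(signs > 0, "up", "down")
  list(a = a, b = b, sharedGenes = sharedGenes,
       sharedClusterPair = sharedClusterPair)
}
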