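#' Restrict two expression datasets to their shared genes
#'
#' Both outputs carry exactly the intersection of the gene identifiers,
#' in identical lexicographic order; the sample sets are unchanged. Used
#' before comparing two cohorts profiled on different platforms.
#'
#' @param a,b `SummarizedExperiment` expression datasets.
#' @return list with elements `a` and `b`, gene-aligned.
#' @export
intersectGenes <- function(a, b) {
  xa <- exprsMatrix(a); xb <- exprsMatrix(b)
  shared <- sort(intersect(rownames(xa), rownames(xb)))
  if (!length(shared)) stop("no genes shared between the two datasets")
  list(a = a[shared, ], b = b[shared, ])
}

#' Select the top high-variance genes
#'
#' Keeps the `n` genes with largest across-sample variance (unbiased,
#' n - 1 divisor); ties are broken toward the lexicographically smaller
#' gene identifier, and the output preserves the input's relative gene
#' order.
#'
#' @param se a `SummarizedExperiment`.
#' @param n number of genes to retain (default 5000).
#' @return a `SummarizedExperiment` with `n` genes.
#' @export
selectHVG <- function(se, n = 5000) {
  x <- exprsMatrix(se)
  n <- as.integer(n)
  if (n < 1L || n > nrow(x))
    stop("n must lie in [1, number of genes] (", nrow(x), ")")
  v <- rowVars(x)
  ord <- order(-v, rownames(x))   # variance desc, then gene id asc
  keep <- sort(ord[seq_len(n)])   # preserve original gene order
  se[keep, ]
}

# Per-row variance with the n-1 divisor.
rowVars <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1L)
}

#' Standardize each gene across samples
#'
#' Centers every gene to mean 0 and scales to standard deviation 1
#' (n - 1 divisor). A zero-variance gene cannot be scaled: its row is
#' set to all zeros and a warning is raised.
#'
#' @param se a `SummarizedExperiment`.
#' @return a `SummarizedExperiment` with standardized expression.
#' @export
zscoreGenes <- function(se) {
  x <- exprsMatrix(se)
  mu <- rowMeans(x)
  sdv <- sqrt(rowVars(x))
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all zeros: ",
            paste(head(rownames(x)[flat], 5L), collapse = ", "))
    sdv[flat] <- 1
  }
  z <- (x - mu) / sdv
  z[flat, ] <- 0
  SummarizedExperiment::assay(se, 1L) <- z
  se
}

#' Mean-variance trend across genes
#'
#' Computes the per-gene mean and square-root standard deviation and fits
#' a local linear regression (tricube weights) of sqrt-sd on mean,
#' evaluated at the sorted gene means — the standard diagnostic of the
#' mean-variance relationship of log-scale expression data.
#'
#' @param se a `SummarizedExperiment` with at least 10 genes.
#' @param span local regression span in (0, 1].
#' @return list with `geneMeans`, `geneSqrtSd` (input gene order) and
#'   `trend`, a two-column matrix of (mean, fitted sqrt-sd) pairs ordered
#'   by mean.
#' @export
meanVarianceTrend <- function(se, span = 0.5) {
  x <- exprsMatrix(se)
  if (nrow(x) < 10L) stop("at least 10 genes are required")
  stopifnot(span > 0, span <= 1)
  mu <- rowMeans(x)
  s <- sqrt(sqrt(rowVars(x)))
  fit <- stats::loess(s ~ mu, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  ord <- order(mu)
  trend <- cbind(mean = mu[ord],
                 sqrtSd = predict(fit, newdata = data.frame(mu = mu[ord])))
  rownames(trend) <- NULL
  list(geneMeans = mu, geneSqrtSd = s, trend = trend)
}
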