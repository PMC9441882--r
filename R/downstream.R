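#' Per-cluster differential expression against controls
#'
#' For every discovered cluster and every gene, compares cluster samples
#' against the shared control group: the log-fold change is the mean
#' difference (data are already log-scale), the p-value comes from a
#' two-sided unequal-variance (Welch) t statistic, optionally with
#' empirical-Bayes variance moderation — per-group gene variances are
#' shrunk toward a prior (the 10%-trimmed mean of all gene variances)
#' with `priorDf` prior degrees of freedom, which stabilizes small
#' cohorts. P-values are Benjamini-Hochberg adjusted within each
#' cluster, and rows are filtered to `p < deP` (raw, or adjusted when
#' `deAdjusted`) and `|logFC| > deLfc`.
#'
#' @param se a `SummarizedExperiment`.
#' @param labels named integer cluster labels of the case samples.
#' @param controlIds sample identifiers of the control group (disjoint
#'   from the labelled cases; at least 2).
#' @param config a [RedisXConfig-class] supplying `deP`, `deLfc`,
#'   `deAdjusted`, `priorDf` and `moderate`.
#' @return data.frame with columns `gene_id`, `cluster`, `log_fc`,
#'   `p_value`, `p_adj`, `direction`.
#' @export
dePerCluster <- function(se, labels, controlIds,
                         config = redisxConfig()) {
  x <- exprsMatrix(se)
  caseIds <- names(labels)
  if (is.null(caseIds)) stop("labels must be named by sample identifier")
  if (length(intersect(caseIds, controlIds)))
    stop("controls must be disjoint from the clustered cases")
  if (!all(c(caseIds, controlIds) %in% colnames(x)))
    stop("labels/controls reference samples absent from the dataset")
  if (length(controlIds) < 2L) stop("need at least 2 control samples")
  ctrl <- x[, controlIds, drop = FALSE]
  out <- list()
  for (kk in sort(unique(as.integer(labels)))) {
    ids <- caseIds[labels == kk]
    if (length(ids) < 2L)
      stop("cluster ", kk, " has fewer than 2 samples")
    grp <- x[, ids, drop = FALSE]
    tt <- welchModerated(grp, ctrl, priorDf = config@priorDf,
                         moderate = config@moderate)
    padj <- p.adjust(tt$p, method = "BH")
    keepP <- if (config@deAdjusted) padj < config@deP else tt$p < config@deP
    keep <- keepP & abs(tt$lfc) > config@deLfc
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        gene_id = rownames(x)[keep], cluster = kk,
        log_fc = tt$lfc[keep], p_value = tt$p[keep], p_adj = padj[keep],
        direction = ifelse(tt$lfc[keep] > 0, "up", "down"),
        row.names = NULL)
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), cluster = integer(0),
                      log_fc = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), direction = character(0)))
  do.call(rbind, out)
}

# Row-wise Welch test of g1 vs g2 (genes in rows), optionally with
# variance moderation toward the trimmed-mean prior variance.
welchModerated <- function(g1, g2, priorDf = 4, moderate = TRUE) {
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- rowVars(g1); v2 <- rowVars(g2)
  df1 <- n1 - 1; df2 <- n2 - 1
  if (moderate && priorDf > 0) {
    v0 <- mean(c(v1, v2), trim = 0.1)
    v1 <- (priorDf * v0 + df1 * v1) / (priorDf + df1)
    v2 <- (priorDf * v0 + df2 * v2) / (priorDf + df2)
    df1 <- df1 + priorDf; df2 <- df2 + priorDf
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  # Welch-Satterthwaite degrees of freedom with the (moderated) variances
  df <- se2^2 / ((v1 / n1)^2 / df1 + (v2 / n2)^2 / df2)
  p <- 2 * pt(-abs(tstat), df = df)
  list(lfc = m1 - m2, t = tstat, p = p)
}

#' Drop genes significant in more than one cluster
#'
#' Keeps only (gene, cluster) rows whose gene is differentially
#' expressed in exactly one cluster — the non-overlapping signature
#' genes of each subpopulation.
#'
#' @param degs a data.frame as returned by [dePerCluster()].
#' @return the filtered data.frame.
#' @export
excludeOverlapping <- function(degs) {
  if (!nrow(degs)) return(degs)
  nClust <- table(degs$gene_id)
  degs[degs$gene_id %in% names(nClust)[nClust == 1L], , drop = FALSE]
}

#' Maximal Clique Centrality hub ranking
#'
#' Scores every node of a simple undirected graph as
#' \eqn{MCC(v) = \sum_{C \ni v} (|C| - 1)!} over all maximal cliques C
#' containing v (exact Bron-Kerbosch enumeration with pivoting); an
#' isolated node scores 1. Higher scores mark better-connected hub
#' genes. Returns the `topN` nodes by score, ties broken by node
#' identifier.
#'
#' @param edges two-column data.frame/matrix of undirected edges (node
#'   identifiers), or a path to a 2-column TSV with a header.
#' @param topN number of top-ranked nodes to return (default all).
#' @param nodes optional full node set (so isolated nodes can be
#'   scored); defaults to the nodes present in `edges`.
#' @return data.frame with columns `node_id`, `mcc_score`, `rank`.
#' @export
mccScores <- function(edges, topN = NULL, nodes = NULL) {
  if (is.character(edges) && length(edges) == 1L && file.exists(edges))
    edges <- read.delim(edges, header = TRUE, sep = "\t",
                        colClasses = "character")
  edges <- as.data.frame(edges)
  stopifnot(ncol(edges) >= 2L)
  em <- cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
  em <- em[em[, 1L] != em[, 2L], , drop = FALSE]   # drop self-loops
  verts <- sort(unique(c(as.character(em), as.character(nodes))))
  if (!length(verts)) stop("empty graph")
  g <- if (nrow(em))
    igraph::simplify(igraph::graph_from_edgelist(em, directed = FALSE))
  else igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(verts, igraph::V(g)$name)),
                            name = setdiff(verts, igraph::V(g)$name))
  nClique <- igraph::count_max_cliques(g, min = 1)
  if (nClique >= 3e6)
    stop("graph has ", nClique,
         " maximal cliques; subset it before MCC scoring")
  cliques <- igraph::max_cliques(g, min = 1)
  score <- setNames(numeric(length(verts)), verts)
  for (cl in cliques) {
    nm <- igraph::V(g)$name[as.integer(cl)]
    score[nm] <- score[nm] + factorial(length(cl) - 1L)
  }
  ord <- order(-score, names(score))
  out <- data.frame(node_id = names(score)[ord],
                    mcc_score = unname(score[ord]),
                    rank = seq_along(score), row.names = NULL)
  if (!is.null(topN)) out <- out[seq_len(min(topN, nrow(out))), ]
  out
}

#' Write a differential-expression table as TSV
#' @param degs data.frame from [dePerCluster()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDEGTable <- function(degs, path) {
  write.table(degs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
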