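#' Construct an expression dataset
#'
#' Wraps a gene x sample matrix of log-scale expression values in a
#' [SummarizedExperiment::SummarizedExperiment] (assay `"exprs"`),
#' validating identifier uniqueness and finiteness.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param geneIds,sampleIds unique identifiers; default to the dimnames
#'   of `values`.
#' @param sampleMeta data.frame of per-sample metadata (one row per
#'   sample), e.g. a `group` column with values `case`/`control`.
#' @return a `SummarizedExperiment`.
#' @examples
#' se <- expressionDataset(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))))
#' @export
expressionDataset <- function(values, geneIds = rownames(values),
                              sampleIds = colnames(values),
                              sampleMeta = NULL) {
  values <- as.matrix(values)
  if (is.null(geneIds) || is.null(sampleIds))
    stop("gene and sample identifiers are required")
  geneIds <- as.character(geneIds); sampleIds <- as.character(sampleIds)
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifier: ",
         geneIds[duplicated(geneIds)][1L])
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifier: ",
         sampleIds[duplicated(sampleIds)][1L])
  if (nrow(values) != length(geneIds) || ncol(values) != length(sampleIds))
    stop("matrix shape does not match the identifier lists")
  if (any(!is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(geneIds, sampleIds)
  if (is.null(sampleMeta))
    sampleMeta <- S4Vectors::DataFrame(row.names = sampleIds)
  else {
    sampleMeta <- S4Vectors::DataFrame(sampleMeta, row.names = sampleIds)
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = sampleMeta)
}

#' Read a tab-separated expression table
#'
#' Expects a header line `gene_id<TAB>sample1<TAB>...` followed by one
#' gene per row; every cell must parse as a number.
#'
#' @param path path to the TSV file.
#' @return a `SummarizedExperiment` with genes in file order.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (ncol(tab) < 2L) stop("expression table needs a gene column and at least one sample")
  sampleIds <- colnames(tab)[-1L]
  geneIds <- tab[[1L]]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifier in header: ",
         sampleIds[duplicated(sampleIds)][1L])
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifier: ", geneIds[duplicated(geneIds)][1L])
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(geneIds, sampleIds))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric cell at gene '%s' (row %d), sample '%s' (column %d)",
      geneIds[bad[1L]], bad[1L], sampleIds[bad[2L]], bad[2L] + 1L))
  }
  expressionDataset(vals)
}

#' Write an expression dataset as TSV
#'
#' Inverse of [readExpressionTSV()]; full `%.17g` precision so a
#' round-trip reproduces the values.
#'
#' @param se a `SummarizedExperiment`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeExpressionTSV <- function(se, path) {
  x <- exprsMatrix(se)
  df <- data.frame(gene_id = rownames(x),
                   formatC(x, format = "g", digits = 17),
                   check.names = FALSE)
  colnames(df) <- c("gene_id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect: metadata lines starting with `!`,
#' and an expression table between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` whose first column is `ID_REF`. Probe
#' identifiers are kept as gene identifiers; see [collapseProbes()] for
#' mapping probes to gene symbols. Selected `!Sample_*` metadata lines
#' (title, characteristics, and any other per-sample fields) are stored
#' in the column data.
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @return a `SummarizedExperiment`.
#' @export
readSeriesMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("missing or malformed series_matrix_table delimiters")
  unquote <- function(x) gsub('^"|"$', "", x)
  tabLines <- lines[(beg + 1L):(end - 1L)]
  cells <- strsplit(tabLines, "\t", fixed = TRUE)
  ncell <- lengths(cells)
  if (length(unique(ncell)) != 1L)
    stop("column count mismatch inside the series-matrix table (line ",
         which(ncell != ncell[1L])[1L], " of the table)")
  header <- unquote(cells[[1L]])
  if (header[1L] != "ID_REF") stop("series-matrix table must start with ID_REF")
  sampleIds <- header[-1L]
  body <- cells[-1L]
  geneIds <- unquote(vapply(body, `[[`, character(1), 1L))
  vals <- suppressWarnings(t(vapply(
    body, function(r) as.numeric(unquote(r[-1L])),
    numeric(length(sampleIds)))))
  if (length(sampleIds) == 1L) vals <- matrix(vals, ncol = 1L)
  if (any(is.na(vals))) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell in series-matrix table at probe '%s', sample '%s'",
                 geneIds[bad[1L]], sampleIds[bad[2L]]))
  }
  dimnames(vals) <- list(geneIds, sampleIds)
  # per-sample "!Sample_*" metadata lines
  metaLines <- grep("^!Sample_", lines[seq_len(beg - 1L)], value = TRUE)
  meta <- list()
  for (ln in metaLines) {
    parts <- unquote(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    key <- sub("^!Sample_", "", parts[1L])
    if (length(parts) - 1L != length(sampleIds)) next
    key <- make.unique(c(names(meta), key))[length(meta) + 1L]
    meta[[key]] <- parts[-1L]
  }
  sampleMeta <- if (length(meta))
    data.frame(meta, check.names = FALSE) else NULL
  expressionDataset(vals, sampleMeta = sampleMeta)
}

#' Collapse probe-level rows to gene symbols
#'
#' Applies a user-supplied two-column probe-to-gene mapping; probes
#' mapping to the same gene are collapsed by the per-sample median.
#' Unmapped probes are dropped.
#'
#' @param se a `SummarizedExperiment` keyed by probe identifiers.
#' @param mapping data.frame (or path to a two-column TSV with a header)
#'   with probe identifiers in the first column and gene symbols in the
#'   second.
#' @return a `SummarizedExperiment` keyed by gene symbols.
#' @export
collapseProbes <- function(se, mapping) {
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read.delim(mapping, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  stopifnot(ncol(mapping) >= 2L)
  x <- exprsMatrix(se)
  gene <- mapping[[2L]][match(rownames(x), mapping[[1L]])]
  keep <- !is.na(gene) & nzchar(gene)
  if (!any(keep)) stop("no probe matched the mapping")
  x <- x[keep, , drop = FALSE]
  gene <- gene[keep]
  out <- rowsum(x, gene, reorder = TRUE) # start from sums; fix medians below
  genes <- sort(unique(gene))
  for (g in genes[tabulate(match(gene, genes)) > 1L])
    out[g, ] <- apply(x[gene == g, , drop = FALSE], 2L, stats::median)
  n1 <- genes[tabulate(match(gene, genes)) == 1L]
  out[n1, ] <- x[match(n1, gene), , drop = FALSE]
  expressionDataset(out, sampleMeta = SummarizedExperiment::colData(se))
}

#' Write per-sample cluster labels as TSV
#'
#' Two columns, `sample_id` and `cluster`, with clusters serialized as
#' 1-based integers.
#'
#' @param labels named integer vector (names = sample identifiers) or an
#'   unnamed vector accompanied by `sampleIds`.
#' @param path output path.
#' @param sampleIds sample identifiers when `labels` is unnamed.
#' @return invisibly, `path`.
#' @export
writeLabelsTSV <- function(labels, path, sampleIds = names(labels)) {
  if (length(labels) && is.null(sampleIds))
    stop("sample identifiers are required")
  df <- data.frame(sample_id = as.character(sampleIds),
                   cluster = as.integer(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cluster-label TSV written by [writeLabelsTSV()]
#' @param path path to the labels file.
#' @return named integer vector of cluster labels.
#' @export
readLabelsTSV <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer"))
  setNames(df$cluster, df$sample_id)
}

#' Pipeline configuration
#'
#' All parameters of the stratification pipeline with their defaults:
#' 5000 high-variance genes, a K = 10 cosine KNN graph, m = 2 diffusion
#' steps, requested cluster numbers 1..20, and a 1e-6 probability
#' clamp. The default `alpha = NA` selects the automatic scale
#' \eqn{2\log((1-\epsilon)/\epsilon)/\bar d} (with \eqn{\bar d} the mean
#' weighted degree of the similarity graph), which makes the cut term
#' commensurate with the clamped seed forces so the cluster-merging
#' mechanism can operate; see [alphaAuto()].
#'
#' @param nHVG,knnK,diffusionM,alpha,kMax,kMin,probClampEps,pdMaxIter,pdTol
#'   see [RedisXConfig-class].
#' @param seed,deP,deLfc,deAdjusted,linkage,seedPolicy,nRepeats,priorDf,moderate
#'   see [RedisXConfig-class].
#' @return a validated [RedisXConfig-class] object.
#' @examples
#' cfg <- redisxConfig(knnK = 8, alpha = 0.5)
#' @export
redisxConfig <- function(nHVG = 5000, knnK = 10, diffusionM = 2,
                         alpha = NA, kMax = 20, kMin = 1,
                         probClampEps = 1e-6, pdMaxIter = 10000,
                         pdTol = 1e-6, seed = 0, deP = 0.05,
                         deLfc = 0.05, deAdjusted = FALSE,
                         linkage = "average", seedPolicy = "medoid",
                         nRepeats = 1, priorDf = 4, moderate = TRUE) {
  new("RedisXConfig",
      nHVG = as.integer(nHVG), knnK = as.integer(knnK),
      diffusionM = as.integer(diffusionM), alpha = as.numeric(alpha),
      kMax = as.integer(kMax), kMin = as.integer(kMin),
      probClampEps = as.numeric(probClampEps),
      pdMaxIter = as.integer(pdMaxIter), pdTol = as.numeric(pdTol),
      seed = as.integer(seed), deP = as.numeric(deP),
      deLfc = as.numeric(deLfc), deAdjusted = as.logical(deAdjusted),
      linkage = as.character(linkage),
      seedPolicy = as.character(seedPolicy),
      nRepeats = as.integer(nRepeats), priorDf = as.numeric(priorDf),
      moderate = as.logical(moderate))
}

#' Load a pipeline configuration from YAML
#'
#' Every key is optional and falls back to the [redisxConfig()] default;
#' unknown keys raise an error. Numeric bounds are enforced at load time.
#'
#' @param path path to a YAML file.
#' @return a validated [RedisXConfig-class] object.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(redisxConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(redisxConfig, vals)
}
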