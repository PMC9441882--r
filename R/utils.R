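# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Euclidean projection of each row of X onto the probability simplex
# (sort-based algorithm; deterministic).
projectSimplexRows <- function(X) {
  n <- nrow(X); K <- ncol(X)
  if (K == 1L) return(matrix(1, n, 1L))
  U <- matrix(0, n, K)
  for (i in seq_len(n)) U[i, ] <- sort(X[i, ], decreasing = TRUE)
  css <- t(apply(U, 1L, cumsum)) - 1
  j <- matrix(seq_len(K), n, K, byrow = TRUE)
  cond <- U - css / j > 0
  rho <- max.col(cond, ties.method = "last")  # largest j with condition TRUE
  theta <- css[cbind(seq_len(n), rho)] / rho
  pmax(X - theta, 0)
}

# Statistical mode; ties resolved toward the largest value.
# Returns list(mode = integer, tie = logical).
modalCount <- function(x) {
  tab <- table(x)
  best <- max(tab)
  winners <- as.integer(names(tab)[tab == best])
  list(mode = max(winners), tie = length(winners) > 1L)
}

# Dense matrix power by repeated multiplication (m is small).
matrixPower <- function(M, m) {
  out <- diag(nrow(M))
  for (i in seq_len(m)) out <- out %*% M
  out
}

# Extract and sanity-check the expression assay of a SummarizedExperiment.
exprsMatrix <- function(se) {
  stopifnot(is(se, "SummarizedExperiment"))
  x <- SummarizedExperiment::assay(se, 1L)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers in the expression matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in the expression matrix")
  if (any(!is.finite(x)))
    stop("expression matrix contains non-finite values")
  x
}

# Relabel clusters densely 1..K' in order of first appearance.
relabelDense <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}
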