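test_that("average-linkage distance matches the hand-computed values", {
  expect_equal(clusterDistance(c(0, 0), c(3, 4)), 5)
  expect_equal(clusterDistance(matrix(c(0, 0), 1),
                               rbind(c(3, 0), c(5, 0))), 4)  # (3+5)/2
  expect_equal(clusterDistance(c(1, 2), c(1, 2)), 0)
  expect_error(clusterDistance(matrix(0, 0, 2), c(1, 2)), "non-empty")
  expect_error(clusterDistance(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("agglomeration splits well-separated groups and handles edge k", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  pre <- hierarchicalPrelabel(X, 2)
  expect_equal(pre@labels, c(1L, 1L, 2L, 2L))
  expect_equal(hierarchicalPrelabel(X, 4)@labels, 1:4)
  expect_equal(hierarchicalPrelabel(X, 1)@labels, rep(1L, 4))
  expect_error(hierarchicalPrelabel(X, 5), "k must lie")
})

test_that("agglomeration is deterministic and nests across k", {
  set.seed(3)
  X <- matrix(rnorm(40 * 5), 40, 5)
  a <- hierarchicalPrelabel(X, 6)@labels
  b <- hierarchicalPrelabel(X, 6)@labels
  expect_identical(a, b)
  # k' < k labelling must be a coarsening of the k labelling
  coarse <- hierarchicalPrelabel(X, 3)@labels
  for (kk in unique(a))
    expect_length(unique(coarse[a == kk]), 1L)
})

test_that("naive definition agrees with the Lance-Williams implementation", {
  # recompute the final k-cluster partition's merge quality by brute
  # force: the implementation's partition must be reachable by greedy
  # merges under the printed average-linkage formula
  set.seed(4)
  X <- matrix(rnorm(12 * 2), 12, 2)
  lab <- hierarchicalPrelabel(X, 3)@labels
  # naive greedy agglomeration, recomputing every pair from scratch
  clusters <- as.list(seq_len(12))
  while (length(clusters) > 3) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- clusterDistance(X[clusters[[i]], , drop = FALSE],
                           X[clusters[[j]], , drop = FALSE])
      if (d < best[1]) best <- c(d, i, j)
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  naive <- integer(12)
  for (i in seq_along(clusters)) naive[clusters[[i]]] <- i
  expect_equal(ari(naive, lab), 1)
})

test_that("ward linkage option produces a valid alternative labelling", {
  set.seed(5)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  pre <- hierarchicalPrelabel(X, 2, linkage = "ward")
  expect_equal(pre@labels, rep(1:2, each = 10))
})

test_that("seed selection is equal-sized, deterministic for medoids", {
  set.seed(6)
  X <- rbind(matrix(rnorm(10, 0, .1), 5, 2),
             matrix(rnorm(6, 5, .1), 3, 2),
             matrix(rnorm(14, 10, .1), 7, 2))
  pre <- hierarchicalPrelabel(X, 3)
  sel <- selectSeeds(X, pre, "medoid")
  expect_equal(sel@seedsPerCluster, 3L)  # min cluster size
  perCluster <- table(pre@labels[sel@seedMask])
  expect_true(all(perCluster == 3L))
  # seeds carry their own cluster's label by construction
  expect_identical(sel@labels, pre@labels)
  # medoid determinism; random reproducibility under a fixed seed
  expect_identical(selectSeeds(X, pre, "medoid")@seedMask, sel@seedMask)
  r1 <- selectSeeds(X, pre, "random", seed = 9)@seedMask
  r2 <- selectSeeds(X, pre, "random", seed = 9)@seedMask
  expect_identical(r1, r2)
})

test_that("the medoid is the sample minimizing summed distance to co-members", {
  X <- rbind(c(0, 0), c(1, 0), c(10, 0))
  pre <- new("PrelabelResult", labels = rep(1L, 3), k = 1L,
             seedMask = logical(0), seedsPerCluster = NA_integer_)
  sel <- selectSeeds(X, pre, "medoid")
  # summed distances are 11, 10, 19 -> only seed when m = 3 is all;
  # force m = 1 by a second singleton cluster
  X2 <- rbind(X, c(100, 0))
  pre2 <- new("PrelabelResult", labels = c(1L, 1L, 1L, 2L), k = 2L,
              seedMask = logical(0), seedsPerCluster = NA_integer_)
  sel2 <- selectSeeds(X2, pre2, "medoid")
  expect_identical(which(sel2@seedMask & pre2@labels == 1L), 2L)
  # all-singleton clusters: every sample is a seed
  pre3 <- new("PrelabelResult", labels = 1:3, k = 3L,
              seedMask = logical(0), seedsPerCluster = NA_integer_)
  expect_true(all(selectSeeds(X, pre3, "medoid")@seedMask))
})
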