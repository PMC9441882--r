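test_that("cosine similarity matches closed forms and rejects zero vectors", {
  expect_equal(cosineSimilarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosineSimilarity(c(0, 0), c(1, 0)), "zero vector")
})

test_that("KNN graph keeps within-group edges and excludes self-loops", {
  # K = n - 1 gives the complete graph
  X3 <- diag(3)
  g3 <- buildKnnGraph(X3, 2)
  expect_equal(nrow(graphEdges(g3)), 3L)
  # two orthogonal groups of identical vectors, K = 1: no cross edges
  X <- rbind(matrix(rep(c(1, 0), 3), 3, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 3), 3, 2, byrow = TRUE))
  g <- buildKnnGraph(X, 1)
  e <- graphEdges(g)
  expect_true(all((e$i <= 3) == (e$j <= 3)))
  expect_true(all(e$i != e$j))
  expect_error(buildKnnGraph(X, 6), "smaller")
})

test_that("negative similarities are clamped to zero weight", {
  X <- rbind(c(1, 0), c(-1, 0.01), c(1, 0.01))
  g <- buildKnnGraph(X, 2)
  expect_true(all(graphEdges(g)$w >= 0))
})

test_that("diffusion operators on the 2-node graph follow hand algebra", {
  g <- graphFromEdges(2, cbind(1, 2, 1))
  ops <- diffusionOperators(g, 2)
  expect_equal(ops@A, matrix(c(0, 1, 1, 0), 2))
  expect_equal(ops@Ahat, matrix(c(0, 1, 1, 0), 2))
  expect_equal(ops@AhatM, diag(2))                 # Ahat^2 = I
  expect_equal(diffusionDistance(ops, 1, 2), sqrt(2))
  expect_equal(diffusionDistance(ops, 1, 1), 0)
  expect_equal(connectivitySimilarity(ops, 1, 2), 0)
  expect_equal(connectivitySimilarity(ops, 1, 1), 1)
})

test_that("star graph normalization gives Ahat(center, leaf) = 1/sqrt(3)", {
  g <- graphFromEdges(4, cbind(1, 2:4, 1))
  ops <- diffusionOperators(g, 2)
  expect_equal(ops@Ahat[1, 2], 1 / sqrt(3))
  expect_true(all(abs(rowSums(ops@A) - 1) < 1e-10))
  expect_error(diffusionOperators(graphFromEdges(3, cbind(1, 2, 1)), 2),
               "isolated node.*3")
})

test_that("diffusion invariants hold on random graphs (even m)", {
  set.seed(11)
  for (t in 1:20) {
    n <- sample(4:12, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    g <- buildKnnGraph(X, sample(2:(n - 1), 1))
    ops <- try(diffusionOperators(g, 2), silent = TRUE)
    if (inherits(ops, "try-error")) next  # isolated node: legitimately refused
    expect_true(all(abs(rowSums(ops@A) - 1) < 1e-10))
    expect_lt(max(abs(ops@Ahat - t(ops@Ahat))), 1e-12)
    expect_true(all(abs(eigen(ops@Ahat, only.values = TRUE)$values) <= 1 + 1e-10))
    R <- redisx:::connectivityMatrix(ops)
    expect_true(all(R >= -1e-12 & R <= 1 + 1e-12))
    expect_equal(unname(diag(R)), rep(1, n))
    # symmetry of the diffusion distance
    expect_equal(diffusionDistance(ops, 1, n), diffusionDistance(ops, n, 1))
    expect_gte(diffusionDistance(ops, 1, n), 0)
  }
})

test_that("duplicated samples with identical connections have r = 1", {
  # nodes 1 and 2 are twins: identical edge patterns to nodes 3 and 4
  g <- graphFromEdges(4, rbind(c(1, 3, 0.5), c(2, 3, 0.5),
                               c(1, 4, 0.2), c(2, 4, 0.2)))
  ops <- diffusionOperators(g, 2)
  expect_equal(connectivitySimilarity(ops, 1, 2), 1)
})

test_that("prior probabilities follow the seed-averaged connectivity rule", {
  # single seeds a=1, b=2; non-seed 3 with r(3,1)=0.9, r(3,2)=0.3 -> p1 = 0.75
  ops <- opsWithConnectivity(list("3,1" = 0.9, "3,2" = 0.3))
  rf <- priorProbabilities(ops, list(1L, 2L), clampEps = 1e-6)
  expect_equal(rf@P[3, 1], 0.75, tolerance = 1e-9)
  # seed rows are one-hot before clamping: (1-eps, eps) after
  expect_equal(rf@P[1, ], c(1 - 1e-6, 1e-6), tolerance = 1e-9)
  # equidistant non-seed -> (0.5, 0.5)
  ops2 <- opsWithConnectivity(list("3,1" = 0.4, "3,2" = 0.4))
  rf2 <- priorProbabilities(ops2, list(1L, 2L))
  expect_equal(rf2@P[3, ], c(0.5, 0.5))
  # rows sum to one
  expect_equal(rowSums(rf@P), rep(1, 3))
})

test_that("a non-seed disconnected from every seed gets a uniform prior", {
  # nodes 3 and 4 have zero connectivity to the seeds 1 and 2
  M <- diag(4); M[1, 2] <- M[2, 1] <- sqrt(0.5)
  ops <- new("DiffusionOperators", A = matrix(0.25, 4, 4), d = rep(1, 4),
             Ahat = diag(4), AhatM = M, m = 2L)
  expect_warning(rf <- priorProbabilities(ops, list(1L, 2L)),
                 "zero connectivity")
  expect_equal(rf@P[4, ], c(0.5, 0.5))
})

test_that("cluster-permutation equivariance of priors and forces", {
  ops <- opsWithConnectivity(list("4,1" = 0.8, "4,2" = 0.2, "4,3" = 0.5,
                                  "5,1" = 0.1, "5,2" = 0.6, "5,3" = 0.3))
  seeds <- list(1L, 2L, 3L)
  rf <- regionForces(priorProbabilities(ops, seeds))
  perm <- c(3L, 1L, 2L)
  rfp <- regionForces(priorProbabilities(ops, seeds[perm]))
  expect_equal(rfp@P, rf@P[, perm])
  expect_equal(rfp@F, rf@F[, perm])
})

test_that("region forces follow -log(p) + log(1-p) and decrease in p", {
  rf <- regionForces(matrix(c(0.5, 0.5), 1, 2), clampEps = 1e-6)
  expect_equal(rf@F[1, 1], 0)
  p <- c(1e-6, 0.1, 0.5, 0.9, 1 - 1e-6)
  f <- -log(p) + log(1 - p)
  expect_true(all(diff(f) < 0))
  expect_equal(f[5], -log(1 - 1e-6) + log(1e-6))  # approx -13.8155
  expect_equal(f[5], log(1e-6), tolerance = 1e-5)
})
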