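test_that("discrete energy counts each cut edge twice plus region forces", {
  g <- graphFromEdges(2, cbind(1, 2, 1))
  prob <- cmfProblem(g, matrix(0, 2, 2), alpha = 1)
  expect_equal(discreteEnergy(c(1L, 2L), prob), 2)
  expect_equal(discreteEnergy(c(1L, 1L), prob), 0)
  expect_error(discreteEnergy(c(1L, 3L), prob), "out of range")
  # single node, no edges: pure force
  g1 <- graphFromEdges(1, matrix(numeric(0), 0, 3))
  prob1 <- cmfProblem(g1, matrix(c(0.3, -0.5), 1, 2))
  expect_equal(discreteEnergy(2L, prob1), -0.5)
})

test_that("brute-force oracle enumerates the hand-checked instances", {
  g <- graphFromEdges(2, cbind(1, 2, 1))
  agree <- cmfProblem(g, rbind(c(0, 10), c(0, 10)))
  bf <- bruteForceMincut(agree)
  expect_equal(bf$labels, c(1L, 1L))
  expect_equal(bf$energy, 0)
  conflict <- cmfProblem(g, rbind(c(0, 10), c(10, 0)))
  bf2 <- bruteForceMincut(conflict)
  expect_equal(bf2$labels, c(1L, 2L))
  expect_equal(bf2$energy, 2)     # cut 2 beats force 10
  single <- cmfProblem(graphFromEdges(1, matrix(numeric(0), 0, 3)),
                       matrix(c(3, 1, 2, 0), 1, 4))
  expect_equal(bruteForceMincut(single)$labels, 4L)
})

test_that("thresholding is row argmax with ties to the lowest index", {
  expect_equal(thresholdLabels(rbind(c(0.2, 0.5, 0.3))), 2L)
  expect_equal(thresholdLabels(rbind(c(0.5, 0.5))), 1L)
  expect_equal(thresholdLabels(diag(3)[, 3:1]), c(3L, 2L, 1L))
})

test_that("zero forces yield the uncut single-label solution", {
  g <- barbellGraph()
  prob <- cmfProblem(g, matrix(0, 8, 2))
  sol <- solveCMF(prob)
  expect_equal(sol@energyDiscrete, 0)
  expect_equal(length(unique(sol@labels)), 1L)
})

test_that("a single node's solution picks the minimum-force cluster", {
  prob <- cmfProblem(graphFromEdges(1, matrix(numeric(0), 0, 3)),
                     matrix(c(1, -2, 5), 1, 3))
  sol <- solveCMF(prob)
  expect_equal(sol@labels, 2L)
  expect_equal(sol@Phi[1, 2], 1)
})

test_that("the barbell splits exactly at the weak bridge under strong seeds", {
  g <- barbellGraph(0.01)
  P <- matrix(0.5, 8, 2)
  P[1, ] <- c(1, 0); P[8, ] <- c(0, 1)       # one strong seed per side
  rf <- regionForces(P, clampEps = 1e-6)
  prob <- cmfProblem(g, rf@F, alpha = 1)
  sol <- solveCMF(prob)
  expect_equal(sol@labels, rep(1:2, each = 4))
  bf <- bruteForceMincut(prob)
  expect_equal(sol@energyDiscrete, bf$energy, tolerance = 1e-9)
})

test_that("thresholded CMF matches the brute-force oracle on random instances", {
  set.seed(13)
  for (t in 1:60) {
    prob <- randomProblem(n = sample(2:8, 1), K = sample(2:3, 1))
    sol <- suppressWarnings(solveCMF(prob, maxIter = 20000, tol = 1e-10))
    bf <- bruteForceMincut(prob)
    expect_lt(sol@energyDiscrete - bf$energy, 1e-6)
    # relaxation lower-bounds the discrete optimum
    expect_gte(sol@energyDiscrete, sol@energyRelaxed - 1e-6)
  }
})

test_that("iterates stay feasible: simplex rows and box-bounded duals", {
  set.seed(17)
  for (t in 1:10) {
    prob <- randomProblem(n = sample(4:10, 1), K = sample(2:4, 1))
    sol <- suppressWarnings(
      solveCMF(prob, maxIter = 2000, tol = 1e-8, checkFeasible = TRUE))
    expect_true(all(abs(rowSums(sol@Phi) - 1) <= 1e-8))
    expect_true(all(sol@Phi >= -1e-8 & sol@Phi <= 1 + 1e-8))
  }
})

test_that("scaling alpha and the forces together preserves the labelling", {
  set.seed(19)
  prob <- randomProblem(6, 3)
  sol <- suppressWarnings(solveCMF(prob, maxIter = 20000, tol = 1e-10))
  scaled <- cmfProblem(prob@graph, prob@F * 2.5, alpha = prob@alpha * 2.5)
  sol2 <- suppressWarnings(solveCMF(scaled, maxIter = 20000, tol = 1e-10))
  expect_equal(discreteEnergy(sol2@labels, prob),
               discreteEnergy(sol@labels, prob), tolerance = 1e-9)
})

test_that("the solver is bit-stable across repeated runs", {
  set.seed(23)
  prob <- randomProblem(8, 3)
  a <- suppressWarnings(solveCMF(prob, maxIter = 3000))
  b <- suppressWarnings(solveCMF(prob, maxIter = 3000))
  expect_identical(a@labels, b@labels)
  expect_identical(a@Phi, b@Phi)
})

test_that("unsupported clusters end empty (the merging mechanism)", {
  # two tight cliques, K = 3 requested, but seeds only support 2 groups:
  # cluster 3's force column is repulsive everywhere
  g <- barbellGraph(0.01)
  P <- matrix(c(0.45, 0.45, 0.1), 8, 3, byrow = TRUE)
  P[1, ] <- c(0.98, 0.01, 0.01); P[8, ] <- c(0.01, 0.98, 0.01)
  rf <- regionForces(P)
  sol <- solveCMF(cmfProblem(g, rf@F, alpha = 1))
  expect_lt(length(unique(sol@labels)), 3L)
})
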