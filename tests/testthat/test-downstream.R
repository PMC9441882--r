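nullMatrix <- function(nGenes, n1, n2, seed = 31) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(nGenes * (n1 + n2)), nGenes,
                dimnames = list(sprintf("g%04d", seq_len(nGenes)),
                                sprintf("s%03d", seq_len(n1 + n2))))
    x
  })
}

test_that("null simulation keeps the type-I error near nominal", {
  x <- nullMatrix(1000, 20, 20)
  se <- expressionDataset(x)
  labels <- setNames(rep(1L, 20), colnames(x)[1:20])
  controls <- colnames(x)[21:40]
  cfg <- redisxConfig(deLfc = 0)             # count all p < 0.05 rejections
  degs <- dePerCluster(se, labels, controls, cfg)
  expect_lt(abs(nrow(degs) / 1000 - 0.05), 0.02)
  # the plain Welch switch is calibrated too
  degsW <- dePerCluster(se, labels, controls,
                        redisxConfig(deLfc = 0, moderate = FALSE))
  expect_lt(abs(nrow(degsW) / 1000 - 0.05), 0.02)
})

test_that("a strongly shifted gene is detected with the right direction", {
  x <- nullMatrix(200, 20, 20, seed = 32) * 0.5
  x["g0001", 1:20] <- x["g0001", 1:20] + 2     # effect/sigma = 4
  x["g0002", 1:20] <- x["g0002", 1:20] - 2
  se <- expressionDataset(x)
  labels <- setNames(rep(1L, 20), colnames(x)[1:20])
  degs <- dePerCluster(se, labels, colnames(x)[21:40])
  expect_true(all(c("g0001", "g0002") %in% degs$gene_id))
  expect_equal(degs$direction[degs$gene_id == "g0001"], "up")
  expect_equal(degs$direction[degs$gene_id == "g0002"], "down")
  # equal means -> logFC 0 -> filtered out regardless of p
  y <- rbind(gZ = rep(c(1, 2), 20))
  colnames(y) <- colnames(x)
  seZ <- expressionDataset(y)
  expect_equal(nrow(dePerCluster(seZ, labels, colnames(x)[21:40])), 0L)
})

test_that("direction is consistent with the sign of the fold change", {
  sim <- makeClusteredExpression(syntheticSpec(kPlanted = 2,
    samplesPerCluster = 15, nControls = 15, nGenes = 120,
    nDePerCluster = 20, effect = 3, sigma = 0.5, seed = 33))
  degs <- dePerCluster(sim$dataset, sim$labels, sim$controlIds)
  expect_true(all(degs$direction == ifelse(degs$log_fc > 0, "up", "down")))
  expect_true(all(degs$p_adj >= degs$p_value - 1e-12))
  expect_true(all(degs$p_adj <= 1))
})

test_that("cross-cluster overlapping genes are excluded entirely", {
  degs <- data.frame(
    gene_id = c("G", "G", "H", "I"), cluster = c(1L, 2L, 3L, 1L),
    log_fc = 1, p_value = 0.01, p_adj = 0.02, direction = "up")
  out <- excludeOverlapping(degs)
  expect_false("G" %in% out$gene_id)
  expect_setequal(out$gene_id, c("H", "I"))
  empty <- degs[0, ]
  expect_equal(nrow(excludeOverlapping(empty)), 0L)
})

test_that("guards reject overlapping controls and undersized groups", {
  x <- nullMatrix(20, 4, 4, seed = 34)
  se <- expressionDataset(x)
  labels <- setNames(c(1L, 1L, 2L), colnames(x)[1:3])
  expect_error(dePerCluster(se, labels, colnames(x)[3:6]), "disjoint")
  expect_error(dePerCluster(se, labels, colnames(x)[5:8]), "fewer than 2")
})

test_that("moderated p-values agree with limma on a shared design", {
  # independent cross-check of the moderation idea: on the same data the
  # rank ordering of evidence should essentially match limma's
  x <- nullMatrix(300, 10, 10, seed = 35)
  x[1:30, 1:10] <- x[1:30, 1:10] + 1.5
  tt <- redisx:::welchModerated(x[, 1:10], x[, 11:20])
  design <- cbind(1, rep(c(1, 0), each = 10))
  fit <- limma::eBayes(limma::lmFit(x, design))
  pl <- fit$p.value[, 2]
  expect_gt(cor(rank(tt$p), rank(pl), method = "spearman"), 0.95)
  expect_gt(length(intersect(order(tt$p)[1:30], order(pl)[1:30])), 25)
})

test_that("MCC scores match factorial sums on canonical graphs", {
  tri <- data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"))
  out <- mccScores(tri)
  expect_equal(out$mcc_score, rep(2, 3))          # (3-1)! once each
  path <- data.frame(a = c("a", "b"), b = c("b", "c"))
  outP <- mccScores(path)
  expect_equal(setNames(outP$mcc_score, outP$node_id)[c("a", "b", "c")],
               c(a = 1, b = 2, c = 1))
  # two disjoint triangles, topN = 3: scores 2 with id tie-break
  two <- rbind(tri, data.frame(a = c("x", "y", "z"), b = c("y", "z", "x")))
  top3 <- mccScores(two, topN = 3)
  expect_equal(top3$node_id, c("a", "b", "c"))
  expect_equal(top3$mcc_score, rep(2, 3))
})

test_that("MCC is invariant to edge order and relabeling; isolated nodes score 1", {
  set.seed(36)
  e <- data.frame(a = sample(letters[1:8], 20, TRUE),
                  b = sample(letters[1:8], 20, TRUE))
  e <- e[e$a != e$b, ]
  out1 <- mccScores(e)
  out2 <- mccScores(e[sample(nrow(e)), 2:1])       # shuffled, flipped
  expect_equal(out1, out2)
  # relabeled graph gives the same multiset of scores
  map <- setNames(LETTERS[1:8], letters[1:8])
  out3 <- mccScores(data.frame(a = map[e$a], b = map[e$b]))
  expect_equal(sort(out3$mcc_score), sort(out1$mcc_score))
  iso <- mccScores(data.frame(a = "a", b = "b"), nodes = c("a", "b", "lonely"))
  expect_equal(iso$mcc_score[iso$node_id == "lonely"], 1)
})
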