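test_that("samplePairs respects classes, partitions and determinism", {
  web <- fromEdgeList(data.frame(from = c("a", "a", "b", "c"),
                                 to = c("x", "y", "x", "z")),
                      partition = list(c("a", "b", "c"), c("x", "y", "z")))
  all9 <- samplePairs(web, nPos = 4, nNeg = 5, seed = 1)
  expect_equal(nrow(all9), 9L)                    # exhaustive 3x3 case
  expect_equal(sum(all9$Aij), 4L)
  expect_true(all(all9$node_i %in% c("a", "b", "c")))
  expect_true(all(all9$node_j %in% c("x", "y", "z")))

  expect_error(samplePairs(web, nPos = 5, nNeg = 1), "linked pairs")
  expect_error(samplePairs(web, nPos = 1, nNeg = 6), "unlinked")

  s1 <- samplePairs(web, 2, 2, seed = 7)
  s2 <- samplePairs(web, 2, 2, seed = 7)
  expect_identical(s1, s2)
  draws <- vapply(1:20, function(s)
    paste(capture.output(samplePairs(web, 2, 2, seed = s)), collapse = ""),
    character(1))
  expect_gt(length(unique(draws)), 1L)
})

test_that("buildBsi produces 18 features with the exact difference identity", {
  p4 <- pathGraph(c("a", "b", "c", "d"))
  bsi <- buildBsi(list(p4 = p4), nPos = 2, nNeg = 2, seed = 3)
  expect_equal(nrow(bsi), 4L)
  expect_identical(setdiff(names(bsi),
                           c("network_id", "node_i", "node_j", "Aij")),
                   bsiFeatureNames())
  expect_length(bsiFeatureNames(), 18L)
  expect_true(all(bsi$node_i != bsi$node_j))
  expect_true(all(is.finite(as.matrix(bsi[, bsiFeatureNames()]))))

  # dSh_k recomputed independently from the node profile table, every row
  prof <- nodeEntropies(p4)
  shMat <- as.matrix(prof[, paste0("Sh_", 0:5)])
  rownames(shMat) <- prof$node_id
  for (k in 0:5)
    expect_equal(bsi[[paste0("dSh_", k)]],
                 unname(shMat[bsi$node_i, k + 1] - shMat[bsi$node_j, k + 1]),
                 tolerance = 1e-14)
  # labels match adjacency of the source network
  a <- adjacency(p4)
  expect_equal(bsi$Aij, unname(as.integer(a[cbind(bsi$node_i, bsi$node_j)] != 0)))
})

test_that("base pool trains across topology families and is seed-stable", {
  web <- generateBipartiteBen(8, 8, 0.3, seed = 5)
  bsi <- buildBsi(list(w = web), seed = 5)
  topos <- list(parseTopology("LNN 16:16-1:1"),
                parseTopology("MLP 18:18-8-1:1"),
                parseTopology("MLP 18:18-8-13-1:1"))
  pool <- suppressWarnings(trainBasePool(bsi, topos, seed = 2, epochs = 20))
  expect_length(pool, 3L)
  expect_identical(vapply(pool, function(c) c$kind, character(1)),
                   c("glm", "nnet", "mlp"))
  for (clf in pool) {
    s <- predictBase(clf, bsi)
    expect_true(all(s >= 0 & s <= 1))
  }
  pool2 <- suppressWarnings(trainBasePool(bsi, topos, seed = 2, epochs = 20))
  expect_equal(predictBase(pool[[2]], bsi), predictBase(pool2[[2]], bsi))
})

test_that("buildMt row count, feature count and meta-label semantics", {
  web <- generateBipartiteBen(6, 6, 0.3, seed = 9)
  bsi <- buildBsi(list(w = web), seed = 9)
  topoA <- parseTopology("LNN 16:16-1:1")
  topoB <- parseTopology("MLP 14:14-10-1:1")
  perfect <- noisyOracleClassifier(topoA, pCorrect = 1, seed = 1)
  anti <- noisyOracleClassifier(topoB, pCorrect = 0, seed = 1)
  mt <- buildMt(bsi, list(perfect, anti))
  expect_equal(nrow(mt), nrow(bsi) * 2L)
  expect_length(mtFeatureNames(), 24L)
  expect_true(all(mtFeatureNames() %in% names(mt)))
  expect_equal(mt$P_ann_Aij[mt$ann_id == topoA@name], rep(1L, nrow(bsi)))
  expect_equal(mt$P_ann_Aij[mt$ann_id == topoB@name], rep(0L, nrow(bsi)))
  # the topology descriptor block is constant per classifier
  expect_equal(unique(mt$annSh_0[mt$ann_id == topoA@name]),
               unname(descriptors(topoA)[1]))
})

test_that("mean meta-label per classifier equals its bsi accuracy", {
  web <- generateBipartiteBen(7, 9, 0.3, seed = 12)
  bsi <- buildBsi(list(w = web), seed = 12)
  pool <- suppressWarnings(trainBasePool(bsi,
    list(parseTopology("LNN 17:17-1:1"), parseTopology("MLP 15:15-12-1:1")),
    seed = 4, epochs = 20))
  mt <- buildMt(bsi, pool)
  for (clf in pool) {
    preds <- as.integer(predictBase(clf, bsi) >= 0.5)
    acc <- accuracy(confusionStats(bsi$Aij, preds)) / 100
    expect_equal(mean(mt$P_ann_Aij[mt$ann_id == clf$topology@name]), acc,
                 tolerance = 1e-12)
  }
})

test_that("splitDataset is disjoint, exhaustive, stratified, deterministic", {
  tbl <- syntheticMtTable(100, seed = 8)
  tbl$P_ann_Aij <- rep(c(0L, 1L), each = 50)
  sp <- splitDataset(tbl, 0.75, seed = 1)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$test), 25L)
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0L)
  expect_equal(sum(sp$train$P_ann_Aij), 38L, tolerance = 1)  # ~balanced
  sp2 <- splitDataset(tbl, 0.75, seed = 1)
  expect_identical(sp$train, sp2$train)
  expect_error(splitDataset(tbl, 1.0), "between 0 and 1")
  expect_error(splitDataset(tbl, 0), "between 0 and 1")
})
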