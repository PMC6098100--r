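test_that("markov matrix rows are degree-normalized, isolated nodes self-loop", {
  p3 <- pathGraph()
  tr <- markovMatrix(p3)@transition
  expect_equal(tr["a", ], c(a = 0, b = 1, c = 0))
  expect_equal(tr["b", ], c(a = 0.5, b = 0, c = 0.5))
  expect_equal(tr["c", ], c(a = 0, b = 1, c = 0))

  k3 <- completeGraph(3)
  trk <- markovMatrix(k3)@transition
  expect_true(all(abs(trk[row(trk) != col(trk)] - 0.5) < 1e-12))

  iso <- EcoNetwork(matrix(0, 1, 1), "only")
  m <- markovMatrix(iso)
  expect_equal(unname(m@transition), matrix(1, 1, 1))
  expect_equal(m@initial, 1)
})

test_that("walk distributions match frozen hand enumeration and stationarity", {
  p3 <- pathGraph()
  m <- markovMatrix(p3)
  expect_equal(walkDistribution(m, 0), c(a = 1, b = 1, c = 1) / 3)
  # all length-1 walks: from a (prob 1/3) -> b; from b -> a or c (1/6 each);
  # from c -> b; enumerated by hand and by the brute-force oracle
  expect_equal(walkDistribution(m, 1), c(a = 1/6, b = 2/3, c = 1/6))
  expect_equal(walkDistribution(m, 1), bruteWalkDistribution(p3, 1))
  expect_error(walkDistribution(m, -1), "nonnegative")

  k3 <- markovMatrix(completeGraph(3))
  for (k in 0:5)
    expect_equal(unname(walkDistribution(k3, k)), rep(1/3, 3))
})

test_that("matrix-power walks equal brute-force enumeration on small graphs", {
  set.seed(11)
  graphs <- list()
  # exhaustive: every labeled undirected graph on 2..4 nodes
  for (n in 2:4) {
    up <- which(upper.tri(matrix(0, n, n)))
    for (code in 0:(2^length(up) - 1)) {
      a <- matrix(0, n, n)
      a[up] <- as.integer(intToBits(code))[seq_along(up)]
      graphs[[length(graphs) + 1L]] <- EcoNetwork(a + t(a),
                                                  paste0("n", 1:n))
    }
  }
  # sampled 5- and 6-node graphs (sparse and dense)
  for (r in 1:30) graphs[[length(graphs) + 1L]] <- randomGraph(5, 0.4)
  for (r in 1:15) graphs[[length(graphs) + 1L]] <- randomGraph(6, 0.5)
  for (g in graphs) {
    m <- markovMatrix(g)
    for (k in c(0L, 1L, 3L, 5L)) {
      expect_equal(walkDistribution(m, k), bruteWalkDistribution(g, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("row-stochasticity is preserved under matrix powers", {
  set.seed(5)
  for (r in 1:20) {
    g <- randomGraph(sample(3:8, 1), runif(1, 0.2, 0.8))
    tr <- markovMatrix(g)@transition
    pk <- diag(nrow(tr))
    for (k in 1:5) {
      pk <- pk %*% tr
      expect_true(all(abs(rowSums(pk) - 1) < 1e-10))
    }
  }
})

test_that("node entropies match hand values on path and triangle", {
  k3 <- completeGraph(3)
  prof <- nodeEntropies(k3)
  for (k in 0:5)
    expect_equal(prof[[paste0("Sh_", k)]], rep(log2(3) / 3, 3))

  p3 <- pathGraph()
  prof1 <- nodeEntropies(p3, kMax = 1)
  # frozen from the k=1 distribution (1/6, 2/3, 1/6): -p log2 p termwise
  expect_equal(prof1$Sh_1, c((1/6) * log2(6), (2/3) * log2(3/2),
                             (1/6) * log2(6)), tolerance = 1e-12)
  expect_equal(prof1$Sh_1,
               unname(bruteEntropyTerms(bruteWalkDistribution(p3, 1))))

  single <- EcoNetwork(matrix(0, 1, 1), "s")
  expect_equal(nodeEntropies(single)$Sh_0, 0)   # certainty: zero entropy
})

test_that("graph and mean entropies: sums, bounds and closed forms", {
  p3 <- pathGraph()
  expect_equal(graphEntropy(p3, 1),
               (2/3) * log2(3/2) + 2 * (1/6) * log2(6), tolerance = 1e-12)
  expect_equal(meanNodeEntropy(p3, 1), graphEntropy(p3, 1) / 3)

  # K_n: uniform stationary at every k, Sh_k(G) = log2(n) exactly
  for (n in c(3, 5, 7)) {
    kn <- completeGraph(n)
    for (k in c(0, 2, 5))
      expect_equal(graphEntropy(kn, k), log2(n), tolerance = 1e-12)
  }
  # regular connected graph (cycle): same closed form
  for (k in 0:5) expect_equal(graphEntropy(cycleGraph(6), k), log2(6))

  # bound Sh_k(G) <= log2(n) on arbitrary graphs
  set.seed(9)
  for (r in 1:20) {
    g <- randomGraph(sample(3:7, 1), runif(1, 0.2, 0.9))
    for (k in 0:5)
      expect_lte(graphEntropy(g, k), log2(numNodes(g)) + 1e-12)
  }
})

test_that("entropies are invariant under node relabeling", {
  set.seed(21)
  for (r in 1:10) {
    g <- randomGraph(6, 0.5)
    perm <- sample.int(6)
    a <- adjacency(g)[perm, perm]
    gp <- EcoNetwork(a, nodeIds(g)[perm])
    for (k in c(1, 3, 5)) {
      expect_equal(graphEntropy(g, k), graphEntropy(gp, k),
                   tolerance = 1e-12)
      expect_equal(sort(nodeEntropies(g, kMax = k)[[paste0("Sh_", k)]]),
                   sort(nodeEntropies(gp, kMax = k)[[paste0("Sh_", k)]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("log base and row-entropy variants behave as documented", {
  p3 <- pathGraph()
  bits <- nodeEntropies(p3, kMax = 2)
  nats <- nodeEntropies(p3, kMax = 2, logBase = exp(1))
  expect_equal(as.matrix(bits[, -1]) * log(2), as.matrix(nats[, -1]),
               tolerance = 1e-12)
  # row variant at k=0 is all zeros (identity matrix rows are certain)
  rowProf <- nodeEntropies(p3, kMax = 1, method = "row")
  expect_equal(rowProf$Sh_0, rep(0, 3))
  expect_equal(rowProf$Sh_1, c(0, 1, 0))    # node b: two equally likely steps
})
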