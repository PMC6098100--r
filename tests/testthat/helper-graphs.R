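# Small graph constructors and independent oracles shared across tests.

pathGraph <- function(labels = c("a", "b", "c")) {
  n <- length(labels)
  fromEdgeList(data.frame(from = labels[-n], to = labels[-1]))
}

completeGraph <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  fromEdgeList(data.frame(from = paste0("n", idx[, 1]),
                          to = paste0("n", idx[, 2])))
}

cycleGraph <- function(n) {
  labs <- paste0("n", seq_len(n))
  fromEdgeList(data.frame(from = labs, to = labs[c(2:n, 1)]))
}

starGraph <- function(nLeaves) {
  fromEdgeList(data.frame(from = rep("hub", nLeaves),
                          to = paste0("leaf", seq_len(nLeaves))))
}

# Random undirected graph on n labeled nodes (isolated nodes allowed).
randomGraph <- function(n, pEdge = 0.5) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- rbinom(length(up), 1, pEdge)
  a <- a + t(a)
  EcoNetwork(a, nodeIds = paste0("n", seq_len(n)))
}

# Independent oracle for the k-step walk distribution: explicit recursive
# enumeration of every walk of length k, weighted by the uniform start
# probability 1/n and the per-step transition probabilities (isolated nodes
# stay put). Never uses matrix powers.
bruteWalkDistribution <- function(net, k) {
  a <- adjacency(net)
  n <- nrow(a)
  rs <- rowSums(a)
  p <- numeric(n)
  recurse <- function(node, prob, depth) {
    if (depth == k) { p[node] <<- p[node] + prob; return(invisible()) }
    if (rs[node] == 0) { recurse(node, prob, depth + 1L); return(invisible()) }
    for (m in which(a[node, ] > 0))
      recurse(m, prob * a[node, m] / rs[node], depth + 1L)
  }
  for (s in seq_len(n)) recurse(s, 1 / n, 0L)
  stats::setNames(p, nodeIds(net))
}

# Hand entropy of a probability vector, -sum p log2 p termwise.
bruteEntropyTerms <- function(p) ifelse(p > 0, -p * log2(p), 0)

# Exhaustive pairwise-concordance AUROC oracle (ties count half).
bruteAuroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) for (sn in neg)
    total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
  total / (length(pos) * length(neg))
}

# A synthetic mt-style table: 24 iid standard-normal features with labels
# from a known linear rule (or random when w is NULL).
syntheticMtTable <- function(n, w = NULL, intercept = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 24), n, 24, dimnames = list(NULL, mtFeatureNames()))
  y <- if (is.null(w)) rbinom(n, 1, 0.5)
       else as.integer(as.numeric(x %*% w) + intercept >= 0)
  data.frame(x, P_ann_Aij = y, check.names = FALSE)
}

# Deliberately strong/weak base classifiers honouring the pool contract:
# they peek at the observed Aij and return it (or its complement) with a
# seeded per-row flip rate, so their per-topology correctness rate is known.
noisyOracleClassifier <- function(topo, pCorrect, seed) {
  force(pCorrect); force(seed)
  structure(list(topology = topo,
                 predictScore = function(data) {
                   set.seed(seed)
                   flip <- rbinom(nrow(data), 1, 1 - pCorrect)
                   ifelse(flip == 1, 1 - data$Aij, data$Aij)
                 }),
            class = "netnetBaseClassifier")
}
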