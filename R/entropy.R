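#' Markov matrix of a network
#'
#' Builds the random-walk model underlying the Markov-Shannon entropy
#' centralities: the transition probability from node i to node j is
#' \eqn{p_{ij} = w_{ij} / \sum_m w_{im}}, i.e. each adjacency row normalized
#' by its sum (degree for unweighted webs). Rows of isolated nodes are given
#' a self-loop (\eqn{p_{ii} = 1}) so the matrix stays row-stochastic without
#' dropping nodes. The initial distribution \eqn{{}^0p} is uniform 1/n.
#'
#' @param net an [EcoNetwork-class].
#' @param useWeights use edge weights when present (TRUE) or the binarized
#'   adjacency (FALSE).
#' @param kMax intended maximum walk length (metadata; default 5).
#' @return a [MarkovChainModel-class].
#' @examples
#' p3 <- fromEdgeList(data.frame(from = c("a", "b"), to = c("b", "c")))
#' markovMatrix(p3)@transition
#' @export
markovMatrix <- function(net, useWeights = TRUE, kMax = 5L) {
  stopifnot(is(net, "EcoNetwork"))
  n <- numNodes(net)
  if (n < 1L) stop("network must have at least one node")
  a <- adjacency(net)
  if (!useWeights) a <- (a != 0) * 1
  if (any(a < 0)) stop("negative weight in adjacency")
  rs <- rowSums(a)
  tr <- a
  pos <- rs > 0
  tr[pos, ] <- a[pos, , drop = FALSE] / rs[pos]
  if (any(!pos)) {
    tr[!pos, ] <- 0
    diag(tr)[!pos] <- 1        # isolated-node convention: absorbing self-loop
  }
  new("MarkovChainModel", transition = tr, initial = rep(1 / n, n),
      kMax = as.integer(kMax))
}

#' k-step walk distribution
#'
#' \eqn{{}^kP = {}^0P \, ({}^1\Pi)^k}: the probability of occupying each node
#' after a walk of length k started from the initial distribution. `k = 0`
#' returns the initial vector unchanged.
#'
#' @param model a [MarkovChainModel-class].
#' @param k nonnegative integer walk length.
#' @return a named probability vector summing to 1.
#' @export
walkDistribution <- function(model, k) {
  stopifnot(is(model, "MarkovChainModel"))
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("k must be a nonnegative integer")
  p <- model@initial
  tr <- model@transition
  for (step in seq_len(k)) p <- as.vector(p %*% tr)
  names(p) <- rownames(tr)
  p
}

#' Markov-Shannon entropy centralities per node
#'
#' For each walk order k = 0..`kMax`, the entropy contribution of node j is
#' \eqn{Sh_{kj} = -\, {}^kp_j \log({}^kp_j)} (with \eqn{0 \log 0 := 0}), so
#' that the graph entropy \eqn{Sh_k(G) = \sum_j Sh_{kj}} decomposes exactly
#' over nodes. Sh_0 describes the isolated node under the initial
#' distribution, Sh_1 its direct neighbourhood, Sh_2 second neighbours, and
#' so on. An alternative reading — the entropy of row j of \eqn{\Pi^k},
#' i.e. the uncertainty of a walker leaving node j — is available with
#' `method = "row"` but is not the default.
#'
#' @param net an [EcoNetwork-class].
#' @param kMax maximum walk order (default 5, giving 6 values per node).
#' @param logBase 2 (bits, the default) or `exp(1)` (nats).
#' @param useWeights passed to [markovMatrix()].
#' @param method "walk" (default; occupancy-contribution entropies) or "row"
#'   (per-row entropy of the k-step transition matrix).
#' @return a data.frame with columns `node_id`, `Sh_0` .. `Sh_<kMax>`, one
#'   row per node in network order.
#' @examples
#' k3 <- fromEdgeList(data.frame(from = c("a", "a", "b"),
#'                               to   = c("b", "c", "c")))
#' nodeEntropies(k3)   # every node: (1/3) log2 3 at every k
#' @export
nodeEntropies <- function(net, kMax = 5L, logBase = 2, useWeights = TRUE,
                          method = c("walk", "row")) {
  method <- match.arg(method)
  model <- markovMatrix(net, useWeights = useWeights, kMax = kMax)
  n <- numNodes(net)
  ks <- 0:kMax
  sh <- matrix(0, n, length(ks),
               dimnames = list(nodeIds(net), paste0("Sh_", ks)))
  plogp <- function(p) ifelse(p > 0, -p * log(p, base = logBase), 0)
  if (method == "walk") {
    p <- model@initial
    for (k in ks) {
      sh[, k + 1L] <- plogp(p)
      p <- as.vector(p %*% model@transition)
    }
  } else {
    pk <- diag(n)
    for (k in ks) {
      sh[, k + 1L] <- rowSums(plogp(pk))
      pk <- pk %*% model@transition
    }
  }
  data.frame(node_id = nodeIds(net), sh, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Graph entropy of order k
#'
#' \eqn{Sh_k(G) = \sum_j Sh_{kj}}, the Shannon entropy of the k-step walk
#' distribution; bounded by \eqn{\log n}, attained iff the distribution is
#' uniform (e.g. on any regular connected graph for every k).
#'
#' @inheritParams nodeEntropies
#' @param k walk order.
#' @return a scalar.
#' @export
graphEntropy <- function(net, k, logBase = 2, useWeights = TRUE) {
  prof <- nodeEntropies(net, kMax = k, logBase = logBase,
                        useWeights = useWeights)
  sum(prof[[paste0("Sh_", k)]])
}

#' Mean node entropy of order k
#'
#' `graphEntropy(net, k) / n`; the descriptor used to summarize a whole
#' network (in particular an ANN topology) by a single value per k.
#'
#' @inheritParams graphEntropy
#' @return a scalar.
#' @export
meanNodeEntropy <- function(net, k, logBase = 2, useWeights = TRUE) {
  graphEntropy(net, k, logBase = logBase, useWeights = useWeights) /
    numNodes(net)
}

#' Export a node entropy table to CSV
#'
#' @param net an [EcoNetwork-class].
#' @param path output CSV path.
#' @inheritParams nodeEntropies
#' @return the profile data.frame, invisibly.
#' @export
writeEntropyTable <- function(net, path, kMax = 5L, logBase = 2,
                              useWeights = TRUE) {
  prof <- nodeEntropies(net, kMax = kMax, logBase = logBase,
                        useWeights = useWeights)
  utils::write.csv(prof, path, row.names = FALSE)
  invisible(prof)
}
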