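#' @import methods
NULL

#' EcoNetwork: a species interaction network
#'
#' Central container for a biological ecosystem network (BEN) or any other
#' graph the entropy engine consumes (including neuron graphs of ANN
#' topologies). Holds the adjacency matrix \eqn{A} with entries
#' \eqn{A_{ij} \ge 0} (1/0 for unweighted webs), the ordered node labels, and
#' an optional bipartite partition (e.g. plants vs pollinators, hosts vs
#' parasites) under which every edge must cross guilds.
#'
#' @slot nodeIds character vector of node labels, in internal order.
#' @slot adjacency numeric n x n matrix, dimnames = nodeIds. Symmetric when
#'   the network is undirected; zero diagonal (self-loops are rejected).
#' @slot weighted logical; TRUE when any edge weight differs from 1.
#' @slot directed logical; BENs are undirected by default.
#' @slot partition list of length 0 (unipartite) or 2 (two disjoint character
#'   vectors covering all nodes; rows = first guild, columns = second guild).
#'
#' @seealso [readPajek()], [fromEdgeList()], [generateBipartiteBen()]
#' @export
setClass("EcoNetwork",
  representation(
    nodeIds   = "character",
    adjacency = "matrix",
    weighted  = "logical",
    directed  = "logical",
    partition = "list"
  ),
  prototype(
    nodeIds = character(0),
    adjacency = matrix(numeric(0), 0, 0),
    weighted = FALSE,
    directed = FALSE,
    partition = list()
  )
)

setValidity("EcoNetwork", function(object) {
  a <- object@adjacency
  n <- length(object@nodeIds)
  msgs <- character(0)
  if (!is.numeric(a) && n > 0L) msgs <- c(msgs, "adjacency must be numeric")
  if (nrow(a) != n || ncol(a) != n)
    msgs <- c(msgs, "adjacency must be square with one row per node")
  if (anyDuplicated(object@nodeIds))
    msgs <- c(msgs, "node labels must be unique")
  if (n > 0L) {
    if (any(!is.finite(a))) msgs <- c(msgs, "adjacency entries must be finite")
    else {
      if (any(a < 0)) msgs <- c(msgs, "adjacency entries must be >= 0")
      if (any(diag(a) != 0)) msgs <- c(msgs, "self-loops are not allowed")
      if (!object@directed && !isTRUE(all.equal(a, t(a))))
        msgs <- c(msgs, "undirected network requires a symmetric adjacency")
    }
  }
  p <- object@partition
  if (length(p) != 0L && length(p) != 2L)
    msgs <- c(msgs, "partition must be empty or a list of two node sets")
  if (length(p) == 2L) {
    if (length(intersect(p[[1L]], p[[2L]])) > 0L)
      msgs <- c(msgs, "partition sets must be disjoint")
    if (!setequal(c(p[[1L]], p[[2L]]), object@nodeIds))
      msgs <- c(msgs, "partition must cover exactly the node set")
    else {
      ii <- match(p[[1L]], object@nodeIds)
      if (length(ii) && any(a[ii, ii, drop = FALSE] != 0))
        msgs <- c(msgs, "edges within the first partition set are not allowed")
      jj <- match(p[[2L]], object@nodeIds)
      if (length(jj) && any(a[jj, jj, drop = FALSE] != 0))
        msgs <- c(msgs, "edges within the second partition set are not allowed")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EcoNetwork from an adjacency matrix
#'
#' @param adjacency numeric square matrix of nonnegative edge weights.
#' @param nodeIds node labels; defaults to rownames or "v1", "v2", ...
#' @param directed logical; FALSE (default) symmetrizes nothing but requires
#'   symmetry.
#' @param partition optional list of two disjoint label vectors for bipartite
#'   webs.
#' @return an [EcoNetwork-class] object.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
#' EcoNetwork(a, nodeIds = c("a", "b", "c"))
#' @export
EcoNetwork <- function(adjacency, nodeIds = NULL, directed = FALSE,
                       partition = list()) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  n <- nrow(adjacency)
  if (is.null(nodeIds)) {
    nodeIds <- rownames(adjacency)
    if (is.null(nodeIds)) nodeIds <- if (n) paste0("v", seq_len(n)) else character(0)
  }
  nodeIds <- as.character(nodeIds)
  dimnames(adjacency) <- list(nodeIds, nodeIds)
  weighted <- n > 0L && any(adjacency[adjacency != 0] != 1)
  new("EcoNetwork", nodeIds = nodeIds, adjacency = adjacency,
      weighted = weighted, directed = directed,
      partition = if (length(partition)) list(as.character(partition[[1L]]),
                                              as.character(partition[[2L]]))
                  else list())
}

#' MarkovChainModel: random-walk model over a network
#'
#' Row-stochastic transition matrix \eqn{{}^1\Pi} derived from the adjacency
#' (each row of A divided by its sum; isolated nodes get a self-loop row so
#' the matrix stays stochastic) together with the initial probability vector
#' \eqn{{}^0p} (uniform 1/n).
#'
#' @slot transition n x n row-stochastic matrix.
#' @slot initial length-n probability vector.
#' @slot kMax maximum walk length the model is intended for (default 5).
#' @seealso [markovMatrix()], [walkDistribution()]
#' @export
setClass("MarkovChainModel",
  representation(transition = "matrix", initial = "numeric", kMax = "integer"),
  prototype(kMax = 5L)
)

setValidity("MarkovChainModel", function(object) {
  msgs <- character(0)
  tr <- object@transition
  n <- nrow(tr)
  if (ncol(tr) != n) msgs <- c(msgs, "transition must be square")
  if (length(object@initial) != n)
    msgs <- c(msgs, "initial vector length must match transition dimension")
  if (n > 0L) {
    if (any(tr < 0)) msgs <- c(msgs, "transition entries must be >= 0")
    if (any(abs(rowSums(tr) - 1) > 1e-12))
      msgs <- c(msgs, "every transition row must sum to 1")
    if (any(object@initial < 0) || abs(sum(object@initial) - 1) > 1e-12)
      msgs <- c(msgs, "initial must be a probability vector")
  }
  if (length(msgs)) msgs else TRUE
})

#' AnnTopology: parsed layered neural-network topology
#'
#' A feed-forward classifier topology seen as a graph: neurons are nodes and
#' every pair of consecutive layers is completely connected (no bias nodes,
#' no skip connections). `descriptors` holds the package-computed
#' \eqn{{}^{ANN}Sh_k} values (mean node entropy for k = 0..5);
#' `printedDescriptors` optionally carries externally published values for
#' the same topology (a fixture, never recomputed).
#'
#' @slot name display string, e.g. "MLP 18:18-8-13-1:1".
#' @slot kind "MLP", "LNN" or "FC".
#' @slot layerSizes integer vector, input layer through output layer.
#' @slot descriptors numeric(6), mean Sh_k for k = 0..5 (this package's
#'   uniform-initial, base-2 convention).
#' @slot printedDescriptors numeric(6) of published values, or NA when absent.
#' @slot auroc published AUROC annotation for the trained topology (NA when
#'   absent); carried as metadata only.
#' @seealso [parseTopology()], [annDescriptors()], [annRegistry()]
#' @export
setClass("AnnTopology",
  representation(
    name = "character", kind = "character", layerSizes = "integer",
    descriptors = "numeric", printedDescriptors = "numeric", auroc = "numeric"
  ),
  prototype(descriptors = rep(NA_real_, 6L),
            printedDescriptors = rep(NA_real_, 6L), auroc = NA_real_)
)

setValidity("AnnTopology", function(object) {
  msgs <- character(0)
  if (length(object@layerSizes) < 2L)
    msgs <- c(msgs, "a topology needs at least an input and an output layer")
  if (any(object@layerSizes < 1L))
    msgs <- c(msgs, "layer sizes must be positive")
  if (length(object@descriptors) != 6L)
    msgs <- c(msgs, "descriptors must have length 6 (k = 0..5)")
  if (any(!is.na(object@descriptors) & object@descriptors < 0))
    msgs <- c(msgs, "descriptors must be >= 0")
  if (length(object@printedDescriptors) != 6L)
    msgs <- c(msgs, "printedDescriptors must have length 6")
  if (!(object@kind %in% c("MLP", "LNN", "FC")))
    msgs <- c(msgs, "kind must be MLP, LNN or FC")
  if (length(msgs)) msgs else TRUE
})

#' LinearNetNetModel: linear discriminant meta-classifier
#'
#' The linear Net-Net score over the 24 mt features plus intercept:
#' \deqn{S = \sum_k a_k Sh_{ki} + \sum_k b_k Sh_{kj} + \sum_k c_k \Delta Sh_{kij}
#'       + \sum_k d_k {}^{ANN}Sh_k + e_0}
#' with classification \eqn{P({}^{ANN}A_{ij}) = 1} iff \eqn{S \ge 0}.
#'
#' @slot coefI numeric(6), coefficients on Sh_k of node i (a_k).
#' @slot coefJ numeric(6), coefficients on Sh_k of node j (b_k).
#' @slot coefD numeric(6), coefficients on the differences Delta Sh_k (c_k).
#' @slot coefAnn numeric(6), coefficients on the ANN descriptors (d_k).
#' @slot intercept the free term e_0.
#' @slot fittedStats list with n, chisq, p (and wilksLambda / ridge when
#'   fitted in-package).
#' @seealso [fitLda()], [referenceNetNetModel()], [scoreRecords()]
#' @export
setClass("LinearNetNetModel",
  representation(coefI = "numeric", coefJ = "numeric", coefD = "numeric",
                 coefAnn = "numeric", intercept = "numeric",
                 fittedStats = "list"),
  prototype(fittedStats = list())
)

setValidity("LinearNetNetModel", function(object) {
  msgs <- character(0)
  for (s in c("coefI", "coefJ", "coefD", "coefAnn"))
    if (length(slot(object, s)) != 6L)
      msgs <- c(msgs, paste(s, "must have length 6"))
  if (length(object@intercept) != 1L)
    msgs <- c(msgs, "intercept must be a scalar")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionStats: 2x2 confusion matrix with derived rates
#'
#' Counts tp/tn/fp/fn plus specificity, sensitivity and accuracy as
#' percentages via [specificity()], [sensitivity()] and [accuracy()].
#' Positive class at the meta level = "topology classified the pair
#' correctly"; at the base level = "link present".
#'
#' @slot tp,tn,fp,fn nonnegative counts.
#' @seealso [confusionStats()]
#' @export
setClass("ConfusionStats",
  representation(tp = "numeric", tn = "numeric", fp = "numeric", fn = "numeric")
)

setValidity("ConfusionStats", function(object) {
  counts <- c(object@tp, object@tn, object@fp, object@fn)
  msgs <- character(0)
  if (length(counts) != 4L || any(counts < 0))
    msgs <- c(msgs, "tp, tn, fp, fn must be scalar nonnegative counts")
  if (sum(counts) == 0) msgs <- c(msgs, "confusion matrix must be nonempty")
  if (length(msgs)) msgs else TRUE
})
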