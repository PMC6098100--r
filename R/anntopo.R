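#' Parse an ANN topology string
#'
#' Two notations are understood:
#' \itemize{
#'   \item The Statistica-style form `"KIND in:l1-l2-...-lm:out"`, e.g.
#'     `"MLP 18:18-8-13-1:1"` or `"LNN 16:16-1:1"`. The numbers between the
#'     colons are the layer sizes; the `in:` prefix and `:out` suffix are
#'     redundant annotations of the first and last layer and must match.
#'   \item The hidden-layer form `"a-b-c"` describing only hidden layers, with
#'     tokens drawn from plain integers or the expressions `n`, `n*2`,
#'     `n:2` (= floor(n/2)) and `n:4` (= floor(n/4)); requires `n` (when an
#'     expression is used) plus `inputSize` and `outputSize`. Example:
#'     `"n-n*2-n"` with `n = 200`, input 18, output 1 gives layers
#'     18-200-400-200-1.
#' }
#' Networks with no hidden layer are "LNN" (linear), one or more hidden
#' layers "MLP"; hidden-layer-form topologies are tagged "FC".
#'
#' @param spec topology string.
#' @param n substitution value for the symbol `n` in hidden-layer form.
#' @param inputSize,outputSize explicit input/output layer sizes
#'   (hidden-layer form only).
#' @param computeDescriptors also populate the Sh_k descriptor slot via
#'   [annDescriptors()] (default TRUE).
#' @return an [AnnTopology-class].
#' @examples
#' parseTopology("MLP 18:18-8-13-1:1")
#' parseTopology("n-n*2-n", n = 200, inputSize = 18, outputSize = 1,
#'               computeDescriptors = FALSE)
#' @export
parseTopology <- function(spec, n = NULL, inputSize = NULL, outputSize = NULL,
                          computeDescriptors = TRUE) {
  spec <- trimws(spec)
  m <- regmatches(spec,
         regexec("^(MLP|LNN|FC)\\s*(\\d+):([-0-9]+):(\\d+)$", spec))[[1L]]
  if (length(m)) {
    kind <- m[2L]
    layers <- suppressWarnings(as.integer(strsplit(m[4L], "-")[[1L]]))
    if (anyNA(layers) || any(layers < 1L))
      stop("unparseable or zero-size layer in topology: ", spec)
    if (as.integer(m[3L]) != layers[1L])
      stop("input-size prefix ", m[3L], " does not match first layer ",
           layers[1L], " in: ", spec)
    if (as.integer(m[5L]) != layers[length(layers)])
      stop("output-size suffix ", m[5L], " does not match last layer in: ",
           spec)
    topo <- new("AnnTopology", name = spec, kind = kind, layerSizes = layers)
  } else {
    if (is.null(inputSize) || is.null(outputSize))
      stop("hidden-layer form needs inputSize and outputSize: ", spec)
    tokens <- strsplit(spec, "-")[[1L]]
    evalTok <- function(tok) {
      tok <- trimws(tok)
      if (grepl("^\\d+$", tok)) return(as.integer(tok))
      if (is.null(n)) stop("token '", tok, "' needs n")
      switch(tok,
             "n"   = as.integer(n),
             "n*2" = as.integer(n) * 2L,
             "n:2" = as.integer(floor(n / 2)),
             "n:4" = as.integer(floor(n / 4)),
             stop("unparseable token '", tok, "' in topology: ", spec))
    }
    hidden <- vapply(tokens, evalTok, integer(1L), USE.NAMES = FALSE)
    if (any(hidden < 1L)) stop("zero-size layer in topology: ", spec)
    layers <- c(as.integer(inputSize), hidden, as.integer(outputSize))
    topo <- new("AnnTopology",
                name = sprintf("FC %d:%s:%d", inputSize,
                               paste(layers, collapse = "-"), outputSize),
                kind = "FC", layerSizes = layers)
  }
  if (computeDescriptors)
    topo@descriptors <- annDescriptors(topo)
  topo
}

#' Neuron graph of a topology
#'
#' ANNs are themselves networks — neurons as nodes, weights as links — so the
#' same entropy machinery applies. The graph is undirected and unweighted:
#' every pair of consecutive layers is completely connected (complete
#' bipartite blocks), with no bias nodes, no intra-layer edges and no skip
#' connections.
#'
#' @param topo an [AnnTopology-class].
#' @return an [EcoNetwork-class] with `sum(layerSizes)` nodes and
#'   `sum(layerSizes[-1] * layerSizes[-m])` edges.
#' @export
topologyGraph <- function(topo) {
  stopifnot(is(topo, "AnnTopology"))
  sizes <- topo@layerSizes
  offsets <- c(0L, cumsum(sizes))
  total <- sum(sizes)
  labels <- unlist(lapply(seq_along(sizes), function(l)
    paste0("L", l, "_", seq_len(sizes[l]))))
  adj <- matrix(0, total, total)
  for (l in seq_len(length(sizes) - 1L)) {
    rows <- offsets[l] + seq_len(sizes[l])
    cols <- offsets[l + 1L] + seq_len(sizes[l + 1L])
    adj[rows, cols] <- 1
    adj[cols, rows] <- 1
  }
  EcoNetwork(adj, nodeIds = labels)
}

#' Whole-topology entropy descriptors
#'
#' \eqn{{}^{ANN}Sh_k} for k = 0..5: the mean of the node entropies Sh_k over
#' all neurons of the topology's graph, under the package's convention
#' (uniform initial vector, base-2 logarithm).
#'
#' @param topo an [AnnTopology-class].
#' @param logBase 2 (default) or `exp(1)`.
#' @return named numeric(6), `annSh_0` .. `annSh_5`.
#' @export
annDescriptors <- function(topo, logBase = 2) {
  g <- topologyGraph(topo)
  prof <- nodeEntropies(g, kMax = 5L, logBase = logBase)
  vals <- colMeans(prof[, paste0("Sh_", 0:5)])
  stats::setNames(as.numeric(vals), paste0("annSh_", 0:5))
}

#' Registry of the ten reference ANN topologies
#'
#' The ten base classifier topologies used in the original Net-Net study
#' (seven MLPs with one or two hidden layers, three linear networks),
#' together with the descriptor values published for them. Those published
#' values were produced by the MI-NODES descriptor software, whose initial
#' probability convention is not documented and is not reproduced by this
#' package's uniform-initial convention — they are therefore carried verbatim
#' as a fixture in `printedDescriptors` and never recomputed, while
#' `descriptors` holds this package's own values for the same graphs.
#'
#' @param computeDescriptors also compute this package's descriptors for each
#'   topology (default TRUE).
#' @return a list of 10 [AnnTopology-class] objects, in published order.
#' @examples
#' reg <- annRegistry(computeDescriptors = FALSE)
#' reg[[8]]   # LNN 16:16-1:1
#' @export
annRegistry <- function(computeDescriptors = TRUE) {
  path <- system.file("extdata", "ann_registry.csv", package = "NetNetML",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(r) {
    topo <- parseTopology(tab$topology[r],
                          computeDescriptors = computeDescriptors)
    topo@printedDescriptors <- as.numeric(tab[r, paste0("sh", 0:5)])
    topo@auroc <- tab$auroc[r]
    topo
  })
}
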