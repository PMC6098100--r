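#' Canonical feature column names
#'
#' The bsi (species-pair) table carries 18 features in k-major order:
#' `Sh_0_i..Sh_5_i`, `Sh_0_j..Sh_5_j`, `dSh_0..dSh_5` (the differences
#' `Sh_k_i - Sh_k_j`). The mt (meta-training) table appends the six topology
#' descriptors `annSh_0..annSh_5` for 24 features.
#'
#' @return character vector of column names.
#' @export
bsiFeatureNames <- function() {
  k <- 0:5
  c(paste0("Sh_", k, "_i"), paste0("Sh_", k, "_j"), paste0("dSh_", k))
}

#' @rdname bsiFeatureNames
#' @export
mtFeatureNames <- function() c(bsiFeatureNames(), paste0("annSh_", 0:5))

# Candidate (i, j) pairs of a network: for bipartite webs i runs over the
# first guild (rows) and j over the second (columns), fixing the sign of the
# dSh features; for unipartite webs i is the lower node index so mirrored
# duplicates never occur.
.candidatePairs <- function(net) {
  a <- adjacency(net)
  ids <- nodeIds(net)
  if (length(partition(net)) == 2L) {
    pi <- match(partition(net)[[1L]], ids)
    pj <- match(partition(net)[[2L]], ids)
    grid <- expand.grid(i = pi, j = pj, KEEP.OUT.ATTRS = FALSE)
  } else {
    idx <- which(upper.tri(a), arr.ind = TRUE)
    grid <- data.frame(i = idx[, 1L], j = idx[, 2L])
  }
  grid$label <- as.integer(a[cbind(grid$i, grid$j)] != 0)
  grid
}

#' Sample species pairs from a network
#'
#' Uniform sampling without replacement of `nPos` linked and `nNeg` unlinked
#' node pairs (class-balanced 1:1 by default in [buildBsi()]). In bipartite
#' webs node i always comes from the first guild and node j from the second.
#'
#' @param net an [EcoNetwork-class].
#' @param nPos,nNeg number of linked / unlinked pairs to draw.
#' @param seed RNG seed; the same seed reproduces the same sample.
#' @return data.frame with columns `node_i`, `node_j`, `Aij`.
#' @export
samplePairs <- function(net, nPos, nNeg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- .candidatePairs(net)
  pos <- which(grid$label == 1L)
  neg <- which(grid$label == 0L)
  if (nPos > length(pos))
    stop("requested ", nPos, " linked pairs but only ", length(pos),
         " available")
  if (nNeg > length(neg))
    stop("requested ", nNeg, " unlinked pairs but only ", length(neg),
         " available")
  take <- c(pos[sample.int(length(pos), nPos)],
            neg[sample.int(length(neg), nNeg)])
  ids <- nodeIds(net)
  data.frame(node_i = ids[grid$i[take]], node_j = ids[grid$j[take]],
             Aij = grid$label[take], stringsAsFactors = FALSE)
}

#' Build the bsi species-pair dataset
#'
#' One row per sampled pair: provenance columns (`network_id`, `node_i`,
#' `node_j`), the 18 entropy features of [bsiFeatureNames()] computed from
#' the pair's own network, and the link label `Aij` last. The feature
#' invariant `dSh_k = Sh_k_i - Sh_k_j` holds exactly for every row.
#'
#' @param nets a named list of [EcoNetwork-class] objects (names become
#'   `network_id`; unnamed lists get `net1`, `net2`, ...).
#' @param nPos,nNeg pairs per network (recycled across networks). Defaults:
#'   all links, and as many non-links (balanced classes).
#' @param seed RNG seed.
#' @param logBase entropy log base (default 2).
#' @return a data.frame (the bsi table).
#' @examples
#' web <- generateBipartiteBen(6, 6, 0.3, seed = 1)
#' bsi <- buildBsi(list(web = web), nPos = 5, nNeg = 5, seed = 1)
#' dim(bsi)
#' @export
buildBsi <- function(nets, nPos = NULL, nNeg = nPos, seed = NULL,
                     logBase = 2) {
  if (is(nets, "EcoNetwork")) nets <- list(nets)
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    names(nets) <- paste0("net", seq_along(nets))
  if (!is.null(seed)) set.seed(seed)
  nPosV <- if (is.null(nPos)) rep(NA_integer_, length(nets))
           else rep_len(as.integer(nPos), length(nets))
  nNegV <- if (is.null(nNeg)) rep(NA_integer_, length(nets))
           else rep_len(as.integer(nNeg), length(nets))
  rows <- lapply(seq_along(nets), function(w) {
    net <- nets[[w]]
    grid <- .candidatePairs(net)
    np <- nPosV[w]; nn <- nNegV[w]
    if (is.na(np)) np <- sum(grid$label == 1L)
    if (is.na(nn)) nn <- min(np, sum(grid$label == 0L))
    pairs <- samplePairs(net, np, nn)
    prof <- nodeEntropies(net, kMax = 5L, logBase = logBase)
    shMat <- as.matrix(prof[, paste0("Sh_", 0:5)])
    rownames(shMat) <- prof$node_id
    shI <- shMat[pairs$node_i, , drop = FALSE]
    shJ <- shMat[pairs$node_j, , drop = FALSE]
    feat <- cbind(shI, shJ, shI - shJ)
    colnames(feat) <- bsiFeatureNames()
    cbind(data.frame(network_id = names(nets)[w], node_i = pairs$node_i,
                     node_j = pairs$node_j, stringsAsFactors = FALSE),
          as.data.frame(feat), Aij = pairs$Aij)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Train one base classifier for a topology
#'
#' Base classifiers learn `Aij` from the 18 bsi features, using the hidden
#' layer sizes of their own topology: no hidden layer (LNN) maps to logistic
#' regression, one hidden layer to [nnet::nnet], two or more to the
#' in-package [mlpTrain()]. A classifier that fails to converge is retained
#' with a warning (its predictions remain defined).
#'
#' @param topo an [AnnTopology-class].
#' @param bsi a bsi table from [buildBsi()].
#' @param seed RNG seed.
#' @param epochs training epochs / maxit scale (default 100).
#' @return an object of class `"netnetBaseClassifier"`.
#' @export
trainBaseClassifier <- function(topo, bsi, seed = NULL, epochs = 100L) {
  stopifnot(is(topo, "AnnTopology"))
  x <- as.matrix(bsi[, bsiFeatureNames()])
  y <- bsi$Aij
  hidden <- topo@layerSizes[-c(1L, length(topo@layerSizes))]
  if (!is.null(seed)) set.seed(seed)
  if (length(hidden) == 0L) {
    df <- data.frame(y = y, x)
    model <- suppressWarnings(stats::glm(y ~ ., data = df,
                                         family = stats::binomial()))
    if (!model$converged)
      warning("logistic base classifier for ", topo@name,
              " did not converge; retained")
    kind <- "glm"
  } else if (length(hidden) == 1L) {
    model <- nnet::nnet(x, y, size = hidden[1L], decay = 1e-4,
                        maxit = as.integer(epochs) * 2L, trace = FALSE)
    if (isTRUE(model$convergence == 1L))
      warning("nnet base classifier for ", topo@name,
              " hit maxit without converging; retained")
    kind <- "nnet"
  } else {
    model <- mlpTrain(x, y, hidden = hidden, epochs = as.integer(epochs),
                      seed = if (is.null(seed)) NULL else seed)
    kind <- "mlp"
  }
  structure(list(topology = topo, kind = kind, model = model),
            class = "netnetBaseClassifier")
}

#' Score a bsi-style table with a base classifier
#'
#' @param clf a `"netnetBaseClassifier"` (or any list with a `predictScore`
#'   function, which custom classifiers may supply to honour the contract).
#' @param data a table containing the [bsiFeatureNames()] columns.
#' @return numeric scores in \[0, 1\].
#' @export
predictBase <- function(clf, data) {
  if (!is.null(clf$predictScore)) return(clf$predictScore(data))
  x <- as.matrix(data[, bsiFeatureNames()])
  switch(clf$kind,
         glm  = as.numeric(stats::predict(clf$model,
                  newdata = as.data.frame(x), type = "response")),
         nnet = as.numeric(stats::predict(clf$model, x)),
         mlp  = mlpPredict(clf$model, x),
         stop("unknown base classifier kind: ", clf$kind))
}

#' Train the pool of base classifiers
#'
#' @param bsi a bsi table.
#' @param topologies list of [AnnTopology-class] (default: the ten-entry
#'   [annRegistry()]).
#' @param seed RNG seed; classifier t gets seed + t for reproducibility.
#' @param epochs per-classifier training epochs.
#' @param trainFraction fraction of bsi rows used for training (default 1:
#'   the whole table).
#' @return list of `"netnetBaseClassifier"` objects in topology order.
#' @export
trainBasePool <- function(bsi, topologies = annRegistry(), seed = 1L,
                          epochs = 100L, trainFraction = 1) {
  train <- bsi
  if (trainFraction < 1) {
    sp <- splitDataset(bsi, fraction = trainFraction, seed = seed)
    train <- sp$train
  }
  lapply(seq_along(topologies), function(t)
    trainBaseClassifier(topologies[[t]], train, seed = seed + t,
                        epochs = epochs))
}

#' Build the mt meta-training dataset
#'
#' Every bsi pair is scored by every pool classifier, so the row count is
#' always `nrow(bsi) * length(pool)`. Each row carries the pair's 18
#' features, the classifier's six topology descriptors, and the meta-label
#' `P_ann_Aij`: 1 when the classifier's thresholded prediction equals the
#' observed `Aij`, 0 otherwise.
#'
#' @param bsi a bsi table.
#' @param pool list of base classifiers from [trainBasePool()] (each must
#'   expose a `topology` and be scorable by [predictBase()]).
#' @param threshold score cut-point for "predicts a link" (default 0.5).
#' @param useDescriptors "computed" (this package's convention, default) or
#'   "printed" (the published registry values, where available).
#' @return a data.frame (the mt table) with 24 feature columns, provenance
#'   columns (`network_id`, `node_i`, `node_j`, `ann_id`), `Aij`, the raw
#'   `score`, and `P_ann_Aij` last.
#' @export
buildMt <- function(bsi, pool, threshold = 0.5,
                    useDescriptors = c("computed", "printed")) {
  useDescriptors <- match.arg(useDescriptors)
  stopifnot(nrow(bsi) > 0L, length(pool) > 0L)
  blocks <- lapply(pool, function(clf) {
    topo <- clf$topology
    desc <- if (useDescriptors == "printed" &&
                !all(is.na(topo@printedDescriptors)))
      topo@printedDescriptors else topo@descriptors
    if (all(is.na(desc))) desc <- annDescriptors(topo)
    scores <- predictBase(clf, bsi)
    pred <- as.integer(scores >= threshold)
    annFeat <- matrix(desc, nrow(bsi), 6L, byrow = TRUE,
                      dimnames = list(NULL, paste0("annSh_", 0:5)))
    cbind(bsi[, c("network_id", "node_i", "node_j")],
          ann_id = topo@name,
          bsi[, bsiFeatureNames()],
          as.data.frame(annFeat),
          Aij = bsi$Aij,
          score = scores,
          P_ann_Aij = as.integer(pred == bsi$Aij))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Disjoint and exhaustive; class proportions preserved within one row per
#' stratum. Strata are the combinations of the label column (`P_ann_Aij`
#' when present, else `Aij`) with `network_id` when present.
#'
#' @param tbl a bsi or mt table (any data.frame works; stratification uses
#'   whichever of the columns above exist).
#' @param fraction train share in (0, 1), default 0.75.
#' @param seed RNG seed.
#' @return list with elements `train` and `test`.
#' @export
splitDataset <- function(tbl, fraction = 0.75, seed = NULL) {
  if (!is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(seed)
  labCol <- if ("P_ann_Aij" %in% names(tbl)) "P_ann_Aij"
            else if ("Aij" %in% names(tbl)) "Aij" else NULL
  strata <- rep("all", nrow(tbl))
  if (!is.null(labCol)) strata <- paste(strata, tbl[[labCol]])
  if ("network_id" %in% names(tbl)) strata <- paste(strata, tbl$network_id)
  groups <- split(seq_len(nrow(tbl)), strata)
  # floor per stratum, then top up by largest fractional remainder so the
  # overall train share matches round(n * fraction) within 1 row per stratum
  want <- vapply(groups, length, integer(1)) * fraction
  take <- floor(want)
  short <- round(nrow(tbl) * fraction) - sum(take)
  if (short > 0) {
    extra <- order(want - take, decreasing = TRUE)[seq_len(short)]
    take[extra] <- take[extra] + 1L
  }
  trainIdx <- unlist(lapply(seq_along(groups), function(g)
    groups[[g]][sample.int(length(groups[[g]]), take[g])]), use.names = FALSE)
  list(train = tbl[sort(trainIdx), , drop = FALSE],
       test = tbl[setdiff(seq_len(nrow(tbl)), trainIdx), , drop = FALSE])
}
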