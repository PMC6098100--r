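#' Accessors for EcoNetwork objects
#'
#' @param x an [EcoNetwork-class].
#' @return `nodeIds`: character vector of labels; `adjacency`: the numeric
#'   matrix A; `isWeighted`, `isDirected`: logical flags; `partition`: list of
#'   two label vectors (empty list when unipartite); `numNodes`, `numEdges`:
#'   integer counts (undirected edges counted once).
#' @name EcoNetwork-accessors
NULL

#' @rdname EcoNetwork-accessors
#' @export
setMethod("nodeIds", "EcoNetwork", function(x) x@nodeIds)

#' @rdname EcoNetwork-accessors
#' @export
setMethod("adjacency", "EcoNetwork", function(x) x@adjacency)

#' @rdname EcoNetwork-accessors
#' @export
setMethod("isWeighted", "EcoNetwork", function(x) x@weighted)

#' @rdname EcoNetwork-accessors
#' @export
setMethod("isDirected", "EcoNetwork", function(x) x@directed)

#' @rdname EcoNetwork-accessors
#' @export
setMethod("partition", "EcoNetwork", function(x) x@partition)

#' @rdname EcoNetwork-accessors
#' @export
setMethod("numNodes", "EcoNetwork", function(x) length(x@nodeIds))

#' @rdname EcoNetwork-accessors
#' @export
setMethod("numEdges", "EcoNetwork", function(x) {
  m <- sum(x@adjacency != 0)
  as.integer(if (x@directed) m else m / 2)
})

setMethod("show", "EcoNetwork", function(object) {
  cat(sprintf("EcoNetwork: %d nodes, %d %s%s edges\n",
              numNodes(object), numEdges(object),
              if (object@directed) "directed" else "undirected",
              if (object@weighted) " weighted" else ""))
  if (length(object@partition) == 2L)
    cat(sprintf("  bipartite: %d x %d\n", length(object@partition[[1L]]),
                length(object@partition[[2L]])))
  if (numNodes(object) > 0L) {
    shown <- utils::head(object@nodeIds, 6L)
    cat("  nodes:", paste(shown, collapse = ", "),
        if (numNodes(object) > 6L) "..." else "", "\n")
  }
  invisible(NULL)
})

#' Accessors for AnnTopology objects
#'
#' @param x an [AnnTopology-class].
#' @return `layerSizes`: integer vector input..output; `descriptors`: the six
#'   package-computed mean entropies Sh_0..Sh_5; `printedDescriptors`: the six
#'   published values carried as a fixture (NA when none).
#' @name AnnTopology-accessors
NULL

#' @rdname AnnTopology-accessors
#' @export
setMethod("layerSizes", "AnnTopology", function(x) x@layerSizes)

#' @rdname AnnTopology-accessors
#' @export
setMethod("descriptors", "AnnTopology", function(x) x@descriptors)

#' @rdname AnnTopology-accessors
#' @export
setMethod("printedDescriptors", "AnnTopology", function(x) x@printedDescriptors)

setMethod("show", "AnnTopology", function(object) {
  cat(sprintf("AnnTopology \"%s\" (%s): layers [%s], %d neurons\n",
              object@name, object@kind,
              paste(object@layerSizes, collapse = ", "),
              sum(object@layerSizes)))
  if (!all(is.na(object@descriptors)))
    cat("  Sh_0..Sh_5:", paste(sprintf("%.3f", object@descriptors),
                               collapse = " "), "\n")
  invisible(NULL)
})

#' Accessors for ConfusionStats
#'
#' Percentages on the 0-100 scale: specificity = 100 tn / (tn + fp),
#' sensitivity = 100 tp / (tp + fn), accuracy = 100 (tp + tn) / total.
#'
#' @param x a [ConfusionStats-class].
#' @return a numeric percentage.
#' @name ConfusionStats-accessors
NULL

#' @rdname ConfusionStats-accessors
#' @export
setMethod("sensitivity", "ConfusionStats",
          function(x) 100 * x@tp / (x@tp + x@fn))

#' @rdname ConfusionStats-accessors
#' @export
setMethod("specificity", "ConfusionStats",
          function(x) 100 * x@tn / (x@tn + x@fp))

#' @rdname ConfusionStats-accessors
#' @export
setMethod("accuracy", "ConfusionStats",
          function(x) 100 * (x@tp + x@tn) / (x@tp + x@tn + x@fp + x@fn))

setMethod("show", "ConfusionStats", function(object) {
  cat("ConfusionStats (rows: observed, columns: predicted; positive = 1)\n")
  m <- matrix(c(object@tn, object@fp, object@fn, object@tp), 2, 2,
              byrow = TRUE,
              dimnames = list(c("obs 0", "obs 1"), c("pred 0", "pred 1")))
  print(m)
  cat(sprintf("  Sp = %.1f  Sn = %.1f  Ac = %.1f\n",
              specificity(object), sensitivity(object), accuracy(object)))
  invisible(NULL)
})

#' Accessors for LinearNetNetModel
#'
#' @param x a [LinearNetNetModel-class].
#' @return `modelCoefficients`: named numeric(25) in the canonical layout
#'   a_0..a_5, b_0..b_5, c_0..c_5, d_0..d_5, e0; `fittedStats`: list of fit
#'   statistics (n, chisq, p, ...).
#' @name LinearNetNetModel-accessors
NULL

#' @rdname LinearNetNetModel-accessors
#' @export
setMethod("modelCoefficients", "LinearNetNetModel", function(x) {
  k <- 0:5
  stats::setNames(
    c(x@coefI, x@coefJ, x@coefD, x@coefAnn, x@intercept),
    c(paste0("a_", k), paste0("b_", k), paste0("c_", k), paste0("d_", k), "e0"))
})

#' @rdname LinearNetNetModel-accessors
#' @export
setMethod("fittedStats", "LinearNetNetModel", function(x) x@fittedStats)

setMethod("show", "LinearNetNetModel", function(object) {
  cf <- modelCoefficients(object)
  nz <- cf[cf != 0]
  cat(sprintf("LinearNetNetModel: %d nonzero coefficients (of 24) + intercept\n",
              sum(names(nz) != "e0")))
  print(round(nz, 4))
  fs <- object@fittedStats
  if (length(fs))
    cat("  stats:", paste(names(fs), vapply(fs, function(v)
      paste(format(v), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  invisible(NULL)
})
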