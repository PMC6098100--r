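#' Generate a synthetic bipartite ecological web
#'
#' Emulates the interaction webs (plant-pollinator, host-parasite, ...) the
#' method targets: two guilds of species with a tunable expected link
#' density (connectance) and degree heterogeneity. Each row species i gets a
#' log-normal propensity u_i and each column species j a propensity v_j
#' (log-sd = `heterogeneity`); the link probability for (i, j) is
#' proportional to u_i v_j, rescaled so the mean equals `connectance`.
#' `heterogeneity = 0` collapses to a bipartite Erdos-Renyi web. Webs with
#' isolated species are redrawn until every species has at least one link;
#' hitting the retry cap (an infeasible configuration, e.g. connectance too
#' low) is an error.
#'
#' @param nRows,nCols species counts per guild.
#' @param connectance expected link density in (0, 1);
#'   `nRows * nCols * connectance` must be >= 1.
#' @param heterogeneity degree-skew parameter >= 0 (log-normal sd).
#' @param seed RNG seed; the same seed reproduces the web byte-identically.
#' @param maxRetries redraw cap for the no-isolated-species constraint
#'   (default 100).
#' @return an [EcoNetwork-class] with partition rows `R1..` / columns `C1..`.
#' @examples
#' web <- generateBipartiteBen(10, 10, 0.2, seed = 7)
#' numEdges(web)
#' @export
generateBipartiteBen <- function(nRows, nCols, connectance,
                                 heterogeneity = 0, seed = NULL,
                                 maxRetries = 100L) {
  stopifnot(nRows >= 1L, nCols >= 1L, heterogeneity >= 0)
  if (!is.finite(connectance) || connectance <= 0 || connectance >= 1)
    stop("connectance must lie strictly between 0 and 1")
  if (nRows * nCols * connectance < 1)
    stop("infeasible config: expected link count below 1")
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(maxRetries)) {
    u <- if (heterogeneity > 0) stats::rlnorm(nRows, 0, heterogeneity)
         else rep(1, nRows)
    v <- if (heterogeneity > 0) stats::rlnorm(nCols, 0, heterogeneity)
         else rep(1, nCols)
    p <- outer(u, v)
    p <- pmin(p * connectance / mean(p), 1)
    links <- matrix(stats::rbinom(nRows * nCols, 1L, p), nRows, nCols)
    if (all(rowSums(links) > 0) && all(colSums(links) > 0)) {
      rowIds <- paste0("R", seq_len(nRows))
      colIds <- paste0("C", seq_len(nCols))
      n <- nRows + nCols
      adj <- matrix(0, n, n)
      adj[seq_len(nRows), nRows + seq_len(nCols)] <- links
      adj[nRows + seq_len(nCols), seq_len(nRows)] <- t(links)
      return(EcoNetwork(adj, nodeIds = c(rowIds, colIds),
                        partition = list(rowIds, colIds)))
    }
  }
  stop("infeasible config: no isolated-species-free web after ", maxRetries,
       " draws (connectance too low?)")
}

#' Deterministic fixture suite of small networks
#'
#' A fixed set of small graphs exercising every structural case the entropy
#' engine must handle — a path, a star (K_{1,5}), a triangle, K_{2,2}, and
#' two random bipartite webs (one homogeneous, one degree-skewed) — together
#' with their node entropy tables as computed by [nodeEntropies()].
#' Regeneration under the same seed is bit-identical, so the returned
#' descriptor tables serve as regression goldens.
#'
#' @param seed RNG seed for the two random webs (default 42).
#' @return list with `networks` (named list of [EcoNetwork-class]) and
#'   `descriptors` (named list of node entropy data.frames).
#' @export
makeFixtureSuite <- function(seed = 42L) {
  nets <- list(
    path4 = fromEdgeList(data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "d"))),
    star5 = fromEdgeList(data.frame(from = rep("hub", 5),
                                    to = paste0("leaf", 1:5))),
    k3 = fromEdgeList(data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c"))),
    k22 = fromEdgeList(data.frame(from = c("a", "a", "b", "b"),
                                  to = c("x", "y", "x", "y")),
                       partition = list(c("a", "b"), c("x", "y"))),
    web_uniform = generateBipartiteBen(8, 10, 0.25, heterogeneity = 0,
                                       seed = seed),
    web_skewed = generateBipartiteBen(12, 15, 0.3, heterogeneity = 0.8,
                                      seed = seed + 1L)
  )
  list(networks = nets, descriptors = lapply(nets, nodeEntropies))
}
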