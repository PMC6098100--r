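#' Read a network from a Pajek .net file
#'
#' Parses the common Pajek dialect used by ecological network repositories:
#' a `*Vertices N` section (vertex lines `id "label" [x y z]`, all optional
#' trailing coordinates ignored), followed by `*Edges` and/or `*Arcs`
#' sections with lines `i j [weight]`. Section keywords are case-insensitive;
#' lines starting with `%` are comments. Vertex ids are 1-based in the file
#' and mapped to internal order; all public output uses labels.
#'
#' `*Edges` lines create symmetric entries. `*Arcs` lines are directed; when
#' `directed = FALSE` (the default for BENs, where a trophic interaction is
#' treated as present/absent) the arc matrix is symmetrized by the maximum of
#' the two directions.
#'
#' @param path path to a .net file.
#' @param directed keep arc direction? Default FALSE.
#' @param keepWeights if FALSE, any third column is ignored and all edges get
#'   weight 1.
#' @return an [EcoNetwork-class].
#' @examples
#' f <- tempfile(fileext = ".net")
#' writeLines(c("*Vertices 3", "1 \"a\"", "2 \"b\"", "3 \"c\"",
#'              "*Edges", "1 2", "2 3"), f)
#' net <- readPajek(f)
#' adjacency(net)
#' @export
readPajek <- function(path, directed = FALSE, keepWeights = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  strip <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))
  n <- NULL
  labels <- character(0)
  adj <- NULL
  arcs <- FALSE            # whether any *Arcs entries were seen
  section <- "none"
  for (ln in seq_along(lines)) {
    raw <- strip(lines[ln])
    if (raw == "" || startsWith(raw, "%")) next
    low <- tolower(raw)
    if (startsWith(low, "*vertices")) {
      parts <- strsplit(raw, "\\s+")[[1L]]
      n <- suppressWarnings(as.integer(parts[2L]))
      if (length(parts) < 2L || is.na(n) || n < 0L)
        stop("line ", ln, ": malformed *Vertices count")
      labels <- if (n > 0L) paste0("v", seq_len(n)) else character(0)
      adj <- matrix(0, n, n)
      section <- "vertices"
      next
    }
    if (startsWith(low, "*edges") || startsWith(low, "*arcs")) {
      if (is.null(n)) stop("line ", ln, ": edge section before *Vertices")
      section <- if (startsWith(low, "*arcs")) "arcs" else "edges"
      next
    }
    if (startsWith(raw, "*")) { section <- "skip"; next }
    if (section == "vertices") {
      m <- regmatches(raw, regexec('^(\\d+)\\s*(?:"([^"]*)"|(\\S+))?', raw))[[1L]]
      id <- suppressWarnings(as.integer(m[2L]))
      if (is.na(id) || id < 1L || id > n)
        stop("line ", ln, ": vertex id out of range 1..", n)
      lab <- if (m[3L] != "") m[3L] else if (m[4L] != "") m[4L] else labels[id]
      labels[id] <- lab
    } else if (section %in% c("edges", "arcs")) {
      parts <- strsplit(raw, "[[:space:],]+")[[1L]]
      if (length(parts) < 2L) stop("line ", ln, ": malformed edge line")
      i <- suppressWarnings(as.integer(parts[1L]))
      j <- suppressWarnings(as.integer(parts[2L]))
      if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > n || j > n)
        stop("line ", ln, ": edge references unknown vertex id (n = ", n, ")")
      if (i == j) stop("line ", ln, ": self-loop rejected")
      w <- 1
      if (length(parts) >= 3L && keepWeights) {
        w <- suppressWarnings(as.numeric(parts[3L]))
        if (is.na(w)) stop("line ", ln, ": non-numeric weight")
        if (w < 0) stop("line ", ln, ": negative weight")
      }
      if (section == "edges") {
        adj[i, j] <- w; adj[j, i] <- w
      } else {
        adj[i, j] <- w
        arcs <- TRUE
      }
    }
  }
  if (is.null(n)) stop("no *Vertices section found in ", path)
  if (anyDuplicated(labels))
    labels <- make.unique(labels, sep = "_")
  if (arcs && !directed) adj <- pmax(adj, t(adj))
  EcoNetwork(adj, nodeIds = labels, directed = directed)
}

#' Write a network to a Pajek .net file
#'
#' Inverse of [readPajek()]: `readPajek(writePajek(net, f))` reproduces the
#' adjacency matrix exactly. Undirected networks are written as `*Edges`
#' (each edge once), directed ones as `*Arcs`.
#'
#' @param net an [EcoNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePajek <- function(net, path) {
  stopifnot(is(net, "EcoNetwork"))
  n <- numNodes(net)
  out <- c(sprintf("*Vertices %d", n),
           if (n) sprintf('%d "%s"', seq_len(n), nodeIds(net)))
  a <- adjacency(net)
  fmtw <- function(w) ifelse(w == 1, "", paste0(" ", format(w, digits = 15)))
  if (isDirected(net)) {
    idx <- which(a != 0, arr.ind = TRUE)
    out <- c(out, "*Arcs",
             if (nrow(idx)) sprintf("%d %d%s", idx[, 1L], idx[, 2L],
                                    fmtw(a[idx])))
  } else {
    idx <- which(a != 0 & upper.tri(a), arr.ind = TRUE)
    out <- c(out, "*Edges",
             if (nrow(idx)) sprintf("%d %d%s", idx[, 1L], idx[, 2L],
                                    fmtw(a[idx])))
  }
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write to ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Build a network from an edge list
#'
#' @param edges a data.frame/matrix with 2 or 3 columns (from, to, optional
#'   weight), or a list of length-2/3 vectors. Node order in the result is
#'   first-appearance order.
#' @param partition optional list of two label vectors declaring a bipartite
#'   structure; nodes without edges may appear only here.
#' @param directed logical, default FALSE.
#' @return an [EcoNetwork-class].
#' @details Self-loops are rejected. A repeated pair with the same weight is
#'   tolerated; contradictory weights for the same pair are an error.
#' @examples
#' fromEdgeList(data.frame(from = c("a", "b"), to = c("b", "c")))
#' @export
fromEdgeList <- function(edges, partition = NULL, directed = FALSE) {
  if (is.list(edges) && !is.data.frame(edges))
    edges <- do.call(rbind, lapply(edges, function(e)
      data.frame(from = e[[1L]], to = e[[2L]],
                 weight = if (length(e) >= 3L) as.numeric(e[[3L]]) else 1)))
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2L) stop("edge list needs at least two columns")
  from <- as.character(edges[[1L]])
  to <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(from))
  w[is.na(w)] <- 1
  if (any(w < 0)) stop("negative weight in edge list")
  if (any(from == to)) stop("self-loop rejected: ", from[which(from == to)[1L]])
  labels <- unique(c(if (!is.null(partition)) unlist(partition), rbind(from, to)))
  n <- length(labels)
  adj <- matrix(0, n, n, dimnames = list(labels, labels))
  for (r in seq_along(from)) {
    i <- match(from[r], labels); j <- match(to[r], labels)
    prev <- adj[i, j]
    if (prev != 0 && prev != w[r])
      stop("contradictory duplicate weight for edge ", from[r], "-", to[r])
    adj[i, j] <- w[r]
    if (!directed) adj[j, i] <- w[r]
  }
  part <- if (is.null(partition)) list() else partition
  EcoNetwork(adj, nodeIds = labels, directed = directed, partition = part)
}

#' Read a 2-3 column edge list file (tab or comma separated)
#'
#' @param path text file, one edge per line, `from<sep>to[<sep>weight]`;
#'   lines starting with `#` are skipped.
#' @inheritParams fromEdgeList
#' @return an [EcoNetwork-class].
#' @export
readEdgeList <- function(path, partition = NULL, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "[\t,]+")
  edges <- lapply(parts, function(p) as.list(trimws(p)))
  fromEdgeList(edges, partition = partition, directed = directed)
}
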