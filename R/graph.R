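#' Construct a simple graph from an adjacency matrix
#'
#' @param adjacency square numeric matrix; symmetrized entries are coerced to
#'   0/1 and the diagonal is cleared.
#' @return a \linkS4class{SimpleGraph}.
#' @examples
#' g <- simpleGraph(matrix(c(0, 1, 1, 0), 2, 2))
#' numEdges(g)
#' @export
simpleGraph <- function(adjacency) {
  a <- (as.matrix(adjacency) != 0) * 1L
  storage.mode(a) <- "integer"
  a <- pmax(a, t(a))  # symmetrize
  diag(a) <- 0L
  dimnames(a) <- NULL
  new("SimpleGraph", adjacency = a)
}

#' Construct a simple graph from an edge list
#'
#' @param n number of vertices.
#' @param edges two-column matrix of 1-based vertex indices (may be empty).
#' @return a \linkS4class{SimpleGraph}; duplicate edges and self-loops are
#'   dropped.
#' @export
edgeListGraph <- function(n, edges) {
  n <- as.integer(n)
  a <- matrix(0L, n, n)
  if (length(edges) > 0) {
    e <- matrix(as.integer(edges), ncol = 2)
    if (any(e < 1 | e > n)) stop("edge endpoints out of range", call. = FALSE)
    keep <- e[, 1] != e[, 2]
    e <- e[keep, , drop = FALSE]
    a[e] <- 1L
    a[e[, 2:1, drop = FALSE]] <- 1L
  }
  new("SimpleGraph", adjacency = a)
}

#' @rdname numVertices
#' @export
setMethod("numVertices", "SimpleGraph", function(x) nrow(x@adjacency))

#' @rdname numEdges
#' @export
setMethod("numEdges", "SimpleGraph",
          function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "SimpleGraph", function(x) x@adjacency)

#' Edge list of a graph
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @return two-column integer matrix of edges (i < j), 1-based.
#' @export
edgeList <- function(g) {
  a <- adjacencyMatrix(g)
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  dimnames(idx) <- NULL
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Convert to an igraph object
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @return an \pkg{igraph} graph.
#' @export
asIgraph <- function(g) {
  igraph::graph_from_adjacency_matrix(adjacencyMatrix(g), mode = "undirected")
}

#' Edge density between two disjoint vertex sets
#'
#' Computes d(X, Y) = e(X, Y) / (|X| |Y|), the fraction of present edges
#' among all pairs with one endpoint in each set.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param X,Y disjoint non-empty integer vertex sets (1-based).
#' @return density in [0, 1].
#' @examples
#' g <- edgeListGraph(4, rbind(c(1, 3), c(2, 4)))
#' pairDensity(g, c(1, 2), c(3, 4))
#' @export
pairDensity <- function(g, X, Y) {
  X <- .assertVertexSet(g, X, "X")
  Y <- .assertVertexSet(g, Y, "Y")
  if (length(intersect(X, Y)) > 0)
    stop("X and Y must be disjoint", call. = FALSE)
  sum(g@adjacency[X, Y, drop = FALSE]) / (length(X) * length(Y))
}
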