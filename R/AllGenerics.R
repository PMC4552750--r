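#' @import methods
NULL

#' Number of vertices
#'
#' @param x a \linkS4class{SimpleGraph} or \linkS4class{VertexPartition}.
#' @return integer scalar.
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Number of edges
#'
#' @param x a \linkS4class{SimpleGraph}.
#' @return integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Dense adjacency matrix
#'
#' @param x a \linkS4class{SimpleGraph}.
#' @return symmetric 0/1 integer matrix with zero diagonal.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Non-junk clusters of a partition
#'
#' @param x a \linkS4class{VertexPartition}.
#' @return list of integer vectors (1-based vertex indices).
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' Junk cluster of a partition
#'
#' The junk cluster P0 holds vertices excluded so that the proper clusters
#' can be kept equal-sized; it takes part in no regularity checks or metrics.
#'
#' @param x a \linkS4class{VertexPartition}.
#' @return integer vector of vertex indices (possibly empty).
#' @export
setGeneric("junkVertices", function(x) standardGeneric("junkVertices"))

#' Number of non-junk clusters
#'
#' @param x a \linkS4class{VertexPartition}.
#' @return integer scalar.
#' @export
setGeneric("numClusters", function(x) standardGeneric("numClusters"))

#' Common size of the non-junk clusters
#'
#' @param x a \linkS4class{VertexPartition}.
#' @return integer scalar (0 for a partition with no clusters).
#' @export
setGeneric("clusterSize", function(x) standardGeneric("clusterSize"))

#' Normalized-cut spectral clustering
#'
#' @param x a \linkS4class{ReducedGraph} or a symmetric non-negative weight
#'   matrix.
#' @param nClusters number of clusters requested (>= 2).
#' @param seed integer seed controlling the k-means stage.
#' @return integer label vector in \code{1..nClusters}, one per node.
#' @export
setGeneric("ncutCluster",
           function(x, nClusters, seed) standardGeneric("ncutCluster"))
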