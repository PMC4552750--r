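#' Simple undirected graph
#'
#' Thin S4 wrapper around a dense symmetric 0/1 adjacency matrix. All graphs
#' handled by the package (connectivity graphs from thresholded correlations,
#' stochastic-block-model fixtures, random bipartite graphs) are simple and
#' unweighted, and the regularity machinery repeatedly needs submatrix edge
#' counts, so a dense representation is deliberate.
#'
#' @slot adjacency symmetric integer matrix of 0/1 with zero diagonal.
#' @export
setClass("SimpleGraph", representation(adjacency = "matrix"))

setValidity("SimpleGraph", function(object) {
  a <- object@adjacency
  if (!is.numeric(a)) return("adjacency must be numeric")
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (nrow(a) > 0) {
    if (any(a != 0 & a != 1)) return("adjacency entries must be 0/1")
    if (any(a != t(a))) return("adjacency must be symmetric")
    if (any(diag(a) != 0)) return("self-loops are not allowed")
  }
  TRUE
})

#' Voxel activity matrix
#'
#' Voxels-by-timepoints real matrix with optional per-voxel coordinates and
#' ground-truth ROI labels (used as truth when scoring clustering accuracy).
#'
#' @slot values numeric matrix, voxels in rows, timepoints in columns.
#' @slot coords numeric matrix with 3 columns (x, y, z) and one row per voxel,
#'   or a 0-row matrix when absent.
#' @slot roiLabels integer vector of per-voxel ROI labels, or length 0 when
#'   absent.
#' @export
setClass("ActivityMatrix",
         representation(values = "matrix", coords = "matrix",
                        roiLabels = "integer"))

setValidity("ActivityMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (anyNA(v)) return("values must not contain missing entries")
  if (nrow(object@coords) > 0 &&
      (nrow(object@coords) != nrow(v) || ncol(object@coords) != 3))
    return("coords must be n_voxels x 3")
  if (length(object@roiLabels) > 0 && length(object@roiLabels) != nrow(v))
    return("roiLabels must have one entry per voxel")
  TRUE
})

#' Parameters of the regularity partitioning algorithm
#'
#' @slot eps regularity tolerance in (0, 1); a bipartite pair (X, Y) is
#'   eps-regular when every pair of subsets A, B with |A| > eps|X|,
#'   |B| > eps|Y| has density within eps of d(X, Y).
#' @slot l refinement fan-out: the initial number of clusters and the factor
#'   by which the cluster count can grow each round.
#' @slot h minimum admissible cluster size; refinement stops before clusters
#'   would shrink below h.
#' @slot maxIterations hard iteration safeguard.
#' @export
setClass("RegularityParams",
         representation(eps = "numeric", l = "integer", h = "integer",
                        maxIterations = "integer"))

setValidity("RegularityParams", function(object) {
  if (length(object@eps) != 1 || object@eps <= 0 || object@eps >= 1)
    return("eps must be a single value in (0, 1)")
  if (object@l < 2L) return("l must be >= 2")
  if (object@h < 1L) return("h must be >= 1")
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  TRUE
})

#' Equitable vertex partition with a junk cluster
#'
#' Holds the junk cluster P0 plus k equal-size clusters P1..Pk, all 1-based
#' vertex index vectors over a common vertex set.
#'
#' @slot junk integer vector: the junk cluster P0 (possibly empty).
#' @slot clusters list of integer vectors: the equal-size clusters P1..Pk.
#' @slot n total number of vertices.
#' @export
setClass("VertexPartition",
         representation(junk = "integer", clusters = "list", n = "integer"))

setValidity("VertexPartition", function(object) {
  all_v <- c(object@junk, unlist(object@clusters))
  if (length(all_v) != object@n) return("partition must cover all vertices")
  if (anyDuplicated(all_v)) return("clusters and junk must be disjoint")
  if (length(all_v) > 0 && (min(all_v) < 1 || max(all_v) > object@n))
    return("vertex indices out of range")
  sizes <- lengths(object@clusters)
  if (length(sizes) > 0) {
    if (any(sizes < 1)) return("clusters must be non-empty")
    if (length(unique(sizes)) != 1) return("clusters must have equal size")
  }
  TRUE
})

#' Verdict of a bipartite regularity check
#'
#' Either declares a cluster pair eps-regular, or carries a certificate
#' (certA, certB) witnessing irregularity: subsets with |certA| > eps|X|,
#' |certB| > eps|Y| and |d(X, Y) - d(certA, certB)| >= eps. Certificates are
#' verified against this inequality before they are emitted, so a verdict
#' with \code{regular = FALSE} is always a true witness; \code{regular = TRUE}
#' is heuristic (absence of a found certificate).
#'
#' @slot pair integer pair of cluster indices (i, j).
#' @slot regular logical scalar.
#' @slot certA,certB integer vertex vectors (empty when regular).
#' @slot density density d(X, Y) of the checked pair.
#' @slot certDensity density d(certA, certB) (NA when regular).
#' @slot eps the tolerance the check was run at.
#' @export
setClass("RegularityVerdict",
         representation(pair = "integer", regular = "logical",
                        certA = "integer", certB = "integer",
                        density = "numeric", certDensity = "numeric",
                        eps = "numeric"))

setValidity("RegularityVerdict", function(object) {
  if (length(object@regular) != 1) return("regular must be a scalar")
  if (!object@regular) {
    if (length(object@certA) == 0 || length(object@certB) == 0)
      return("an irregular verdict must carry a certificate")
    if (is.na(object@certDensity))
      return("certificate density missing")
    if (abs(object@density - object@certDensity) < object@eps)
      return("certificate does not witness an eps deviation")
  }
  TRUE
})

#' History of a regularity partitioning run
#'
#' The refinement loop naturally produces a family of partitions with
#' decreasing cluster size (and, empirically, low modularity); the whole
#' family is kept because the co-affinity analysis consumes it.
#'
#' @slot partitions list of \linkS4class{VertexPartition}, initial to final.
#' @slot verdicts list (one element per round) of lists of
#'   \linkS4class{RegularityVerdict} covering that round's cluster pairs.
#' @slot irregularPairs integer vector: irregular-pair count per round.
#' @slot haltReason one of "regular", "size_limit", "iteration_limit".
#' @slot params the \linkS4class{RegularityParams} used.
#' @export
setClass("PartitionHistory",
         representation(partitions = "list", verdicts = "list",
                        irregularPairs = "integer", haltReason = "character",
                        params = "RegularityParams"))

setValidity("PartitionHistory", function(object) {
  if (length(object@partitions) == 0) return("history must be non-empty")
  if (!object@haltReason %in% c("regular", "size_limit", "iteration_limit"))
    return("unknown halt reason")
  if (length(object@irregularPairs) != length(object@partitions))
    return("one irregular-pair count per round required")
  TRUE
})

#' Co-affinity matrix over a family of partitions
#'
#' Entry (i, j) is the frequency with which vertices i and j share a non-junk
#' cluster across the partition family; diagonal fixed at 1 by convention.
#'
#' @slot c symmetric numeric matrix with entries in [0, 1].
#' @slot familySize number of partitions the frequencies were taken over.
#' @export
setClass("CoAffinityMatrix",
         representation(c = "matrix", familySize = "integer"))

setValidity("CoAffinityMatrix", function(object) {
  m <- object@c
  if (nrow(m) != ncol(m)) return("co-affinity matrix must be square")
  if (any(m < -1e-12 | m > 1 + 1e-12)) return("entries must lie in [0, 1]")
  if (any(abs(m - t(m)) > 1e-12)) return("co-affinity matrix must be symmetric")
  if (nrow(m) > 0 && any(abs(diag(m) - 1) > 1e-12))
    return("diagonal must be 1")
  if (object@familySize < 1L) return("familySize must be >= 1")
  TRUE
})

#' Reduced graph over regularity clusters
#'
#' One node per non-junk cluster of a partition; edge weights are pairwise
#' densities d(Vi, Vj), either for all pairs (the practical small-eps mode)
#' or only for regular pairs with density above a floor d.
#'
#' @slot weights symmetric numeric matrix in [0, 1], zero diagonal.
#' @slot densityFloor the density floor d used to admit edges (0 when
#'   \code{connectAll} mode was used).
#' @slot connectAll logical: whether all pairs were connected.
#' @export
setClass("ReducedGraph",
         representation(weights = "matrix", densityFloor = "numeric",
                        connectAll = "logical"))

setValidity("ReducedGraph", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (any(w < -1e-12 | w > 1 + 1e-12)) return("weights must lie in [0, 1]")
  if (any(abs(w - t(w)) > 1e-12)) return("weights must be symmetric")
  TRUE
})

#' @describeIn SimpleGraph-class compact display.
#' @param object a SimpleGraph.
#' @export
setMethod("show", "SimpleGraph", function(object) {
  cat(sprintf("SimpleGraph with %d vertices and %d edges\n",
              numVertices(object), numEdges(object)))
})

#' @describeIn ActivityMatrix-class compact display.
#' @param object an ActivityMatrix.
#' @export
setMethod("show", "ActivityMatrix", function(object) {
  cat(sprintf("ActivityMatrix: %d voxels x %d timepoints%s%s\n",
              nrow(object@values), ncol(object@values),
              if (nrow(object@coords) > 0) ", with coordinates" else "",
              if (length(object@roiLabels) > 0)
                sprintf(", %d ROIs", length(unique(object@roiLabels)))
              else ""))
})

#' @describeIn VertexPartition-class compact display.
#' @param object a VertexPartition.
#' @export
setMethod("show", "VertexPartition", function(object) {
  cat(sprintf("VertexPartition: %d clusters of size %d, junk %d, n = %d\n",
              numClusters(object), clusterSize(object),
              length(object@junk), object@n))
})

#' @describeIn PartitionHistory-class compact display.
#' @param object a PartitionHistory.
#' @export
setMethod("show", "PartitionHistory", function(object) {
  final <- object@partitions[[length(object@partitions)]]
  cat(sprintf(
    "PartitionHistory: %d round(s), halt = %s; final: %d clusters of size %d\n",
    length(object@partitions), object@haltReason,
    numClusters(final), clusterSize(final)))
})

#' @describeIn RegularityVerdict-class compact display.
#' @param object a RegularityVerdict.
#' @export
setMethod("show", "RegularityVerdict", function(object) {
  if (object@regular) {
    cat(sprintf("Pair (%d, %d): eps-regular (d = %.4f, eps = %g)\n",
                object@pair[1], object@pair[2], object@density, object@eps))
  } else {
    cat(sprintf(
      "Pair (%d, %d): irregular; certificate |A'| = %d, |B'| = %d, |d - d'| = %.4f\n",
      object@pair[1], object@pair[2], length(object@certA),
      length(object@certB), abs(object@density - object@certDensity)))
  }
})

#' @describeIn CoAffinityMatrix-class compact display.
#' @param object a CoAffinityMatrix.
#' @export
setMethod("show", "CoAffinityMatrix", function(object) {
  cat(sprintf("CoAffinityMatrix: %d vertices over a family of %d partition(s)\n",
              nrow(object@c), object@familySize))
})

#' @describeIn ReducedGraph-class compact display.
#' @param object a ReducedGraph.
#' @export
setMethod("show", "ReducedGraph", function(object) {
  cat(sprintf("ReducedGraph: %d cluster-nodes, %s mode\n",
              nrow(object@weights),
              if (object@connectAll) "connect-all"
              else sprintf("density-floor (d = %g)", object@densityFloor)))
})
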