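#' Reduced graph over regularity clusters
#'
#' One node per non-junk cluster; pairwise weights are the densities
#' d(Vi, Vj). In \code{connectAll} mode (the practical choice when eps is
#' small) every pair is connected with its density; otherwise only pairs
#' that are regular according to \code{verdicts} and have density strictly
#' above the floor \code{d} receive weight.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param part a \linkS4class{VertexPartition}.
#' @param verdicts list of \linkS4class{RegularityVerdict} covering the
#'   cluster pairs (required when \code{connectAll = FALSE}).
#' @param d density floor in [0, 1).
#' @param connectAll logical; default TRUE.
#' @return a \linkS4class{ReducedGraph}.
#' @export
reducedGraph <- function(g, part, verdicts = list(), d = 0,
                         connectAll = TRUE) {
  if (d < 0 || d >= 1) stop("density floor d must be in [0, 1)",
                            call. = FALSE)
  k <- numClusters(part)
  w <- matrix(0, k, k)
  for (i in seq_len(max(k - 1, 0))) for (j in (i + 1):k)
    w[i, j] <- w[j, i] <-
      pairDensity(g, part@clusters[[i]], part@clusters[[j]])
  if (!connectAll) {
    regular <- matrix(FALSE, k, k)
    for (v in verdicts) {
      regular[v@pair[1], v@pair[2]] <- v@regular
      regular[v@pair[2], v@pair[1]] <- v@regular
    }
    w[!(regular & w > d)] <- 0
  }
  new("ReducedGraph", weights = w, densityFloor = as.numeric(d),
      connectAll = isTRUE(connectAll))
}

#' Weight matrix of a reduced graph
#' @param rg a \linkS4class{ReducedGraph}.
#' @return symmetric numeric matrix.
#' @export
reducedWeights <- function(rg) rg@weights

# Normalized-cut spectral clustering on a symmetric non-negative weight
# matrix: symmetric normalized Laplacian, bottom k eigenvectors,
# row-normalized embedding, seeded k-means.
.ncut <- function(W, nClusters, seed) {
  n <- nrow(W)
  k <- as.integer(nClusters)
  if (k < 2) stop("nClusters must be >= 2", call. = FALSE)
  if (k > n) stop("nClusters exceeds node count", call. = FALSE)
  if (k == n) return(seq_len(n))
  if (sum(W) == 0) stop("zero-weight graph cannot be clustered",
                        call. = FALSE)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix((W > 0) * 1, mode = "undirected"))
  if (comp$no > k) {
    # more components than requested clusters: group whole components,
    # largest components keep their own label
    ord <- order(-comp$csize)
    lab <- match(comp$membership, ord)
    lab[lab > k] <- k
    return(as.integer(lab))
  }
  deg <- rowSums(W)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  lsym <- diag(n) - (dinv * W) * rep(dinv, each = n)
  lsym <- (lsym + t(lsym)) / 2
  emb <- eigen(lsym, symmetric = TRUE)$vectors[, n:(n - k + 1), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(rn > 0, rn, 1)
  km <- .withSeed(seed, tryCatch(
    stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100),
    error = function(e)
      stats::kmeans(emb + stats::rnorm(length(emb), sd = 1e-9),
                    centers = k, nstart = 10, iter.max = 100)))
  as.integer(km$cluster)
}

#' @rdname ncutCluster
#' @export
setMethod("ncutCluster", signature(x = "ReducedGraph"),
          function(x, nClusters, seed = 1) .ncut(x@weights, nClusters, seed))

#' @rdname ncutCluster
#' @export
setMethod("ncutCluster", signature(x = "matrix"),
          function(x, nClusters, seed = 1) {
            if (any(x != t(x)) || any(x < 0))
              stop("weight matrix must be symmetric and non-negative",
                   call. = FALSE)
            .ncut(x, nClusters, seed)
          })

#' Map reduced-node labels back to vertices
#'
#' Every vertex inherits the label of its regularity cluster; junk vertices
#' stay unlabeled (NA) until \code{\link{assignJunk}}.
#'
#' @param reducedLabels integer label per non-junk cluster.
#' @param part the \linkS4class{VertexPartition} the reduced graph came
#'   from.
#' @return integer label vector over vertices, NA for junk.
#' @export
mapBack <- function(reducedLabels, part) {
  if (length(reducedLabels) != numClusters(part))
    stop("one label per non-junk cluster required", call. = FALSE)
  labels <- rep(NA_integer_, part@n)
  for (ci in seq_along(part@clusters))
    labels[part@clusters[[ci]]] <- as.integer(reducedLabels[ci])
  labels
}

#' Distribute junk vertices to the closest labeled groups
#'
#' Each unlabeled vertex receives the label of the group to which it has
#' the highest edge density (edges into the group divided by group size);
#' ties break toward the lower label, and vertices with no edges into any
#' group are assigned to the largest group.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param labels integer label vector with NA exactly at the junk vertices.
#' @return fully labeled integer vector; non-junk labels are never changed.
#' @export
assignJunk <- function(g, labels) {
  junk <- which(is.na(labels))
  if (length(junk) == 0) return(labels)
  groups <- sort(unique(labels[!is.na(labels)]))
  if (length(groups) == 0) stop("no labeled vertices to assign junk to",
                                call. = FALSE)
  members <- lapply(groups, function(lb) which(!is.na(labels) & labels == lb))
  sizes <- lengths(members)
  largest <- groups[which.max(sizes)]  # which.max breaks ties low
  a <- g@adjacency
  out <- labels
  for (v in junk) {
    dens <- vapply(members, function(mm) sum(a[v, mm]) / length(mm),
                   numeric(1))
    out[v] <- if (all(dens == 0)) largest else groups[which.max(dens)]
  }
  out
}

# O(n^3) Hungarian algorithm (potentials formulation) for the minimum-cost
# assignment of rows to columns; requires nrow <= ncol.
.assignMin <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1)      # index j + 1; column 0 is virtual
  p <- integer(m + 1)      # p[j + 1]: row matched to column j (0 = none)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0
      for (j in seq_len(m)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

#' Hungarian-matched clustering accuracy
#'
#' Builds the truth-by-predicted confusion matrix, finds the injective
#' relabeling of predicted clusters that maximizes total agreement
#' (Hungarian assignment), and returns the matched fraction
#' Accuracy = sum_i sigma(y_i, map(c_i)) / n.
#'
#' @param truth,predicted integer label vectors of equal length, fully
#'   labeled.
#' @return accuracy in [0, 1].
#' @examples
#' clusteringAccuracy(c(1, 1, 2, 2), c(7, 7, 4, 4))  # 1: labels renamed
#' @export
clusteringAccuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length", call. = FALSE)
  if (anyNA(truth) || anyNA(predicted))
    stop("labels must be complete", call. = FALSE)
  conf <- as.matrix(table(factor(truth), factor(predicted)))
  s <- max(dim(conf))
  padded <- matrix(0, s, s)
  padded[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  assn <- .assignMin(-padded)
  sum(padded[cbind(seq_len(s), assn)]) / length(truth)
}

#' Compare reduced-graph Ncut against direct Ncut
#'
#' Runs the full reduced pipeline (regularity partitioning, reduced graph
#' in connect-all mode, Ncut on the cluster nodes, label map-back, junk
#' redistribution) and the direct pipeline (Ncut on the binary adjacency
#' taken as the affinity), and scores both against ground-truth labels with
#' Hungarian-matched accuracy.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param truth integer ground-truth label per vertex.
#' @param params \linkS4class{RegularityParams} for the partitioning stage.
#' @param nClusters number of Ncut clusters for both pipelines.
#' @param seed integer seed for the stochastic stages.
#' @return list with \code{reducedNcutAccuracy}, \code{normalNcutAccuracy},
#'   \code{history} (the \linkS4class{PartitionHistory}), and both label
#'   vectors.
#' @export
comparePipelines <- function(g, truth, params = regularityParams(),
                             nClusters, seed = 1) {
  if (length(truth) != numVertices(g))
    stop("truth labels must cover all vertices", call. = FALSE)
  hist <- regularityPartition(g, params, seed = seed)
  part <- finalPartition(hist)
  rg <- reducedGraph(g, part, finalVerdicts(hist), connectAll = TRUE)
  redLabels <- ncutCluster(rg, nClusters, seed = seed)
  vertexLabels <- assignJunk(g, mapBack(redLabels, part))
  directLabels <- ncutCluster(adjacencyMatrix(g) * 1.0, nClusters,
                              seed = seed)
  list(reducedNcutAccuracy = clusteringAccuracy(truth, vertexLabels),
       normalNcutAccuracy = clusteringAccuracy(truth, directLabels),
       history = hist, reducedLabels = vertexLabels,
       directLabels = as.integer(directLabels))
}
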