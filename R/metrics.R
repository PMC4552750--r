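#' Triangle lower-bound formula for a regular triple
#'
#' Evaluates (1 - 2 eps)(alpha - eps)(beta - eps)(gamma - eps)|X||Y||Z|,
#' the guaranteed triangle count for a triple of pairwise eps-regular
#' cluster pairs with densities alpha, beta, gamma. Negative factors are
#' clamped to 0: a lower bound below zero is vacuous.
#'
#' @param alpha,beta,gamma pairwise densities in [0, 1].
#' @param eps regularity tolerance.
#' @param sizes integer 3-vector (|X|, |Y|, |Z|).
#' @return non-negative real.
#' @examples
#' triangleBoundFormula(0.1, 0.1, 0.1, eps = 0.016, sizes = c(18, 18, 18))
#' @export
triangleBoundFormula <- function(alpha, beta, gamma, eps, sizes) {
  max(1 - 2 * eps, 0) * max(alpha - eps, 0) * max(beta - eps, 0) *
    max(gamma - eps, 0) * prod(sizes)
}

#' Triangle lower bound for a cluster triple
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param X,Y,Z pairwise disjoint non-empty vertex sets.
#' @param eps regularity tolerance.
#' @return the clamped lower bound (a real >= 0); the bound is only
#'   meaningful when all three pairs are eps-regular.
#' @export
triangleLowerBound <- function(g, X, Y, Z, eps) {
  X <- .assertVertexSet(g, X, "X")
  Y <- .assertVertexSet(g, Y, "Y")
  Z <- .assertVertexSet(g, Z, "Z")
  if (length(intersect(X, Y)) + length(intersect(Y, Z)) +
      length(intersect(X, Z)) > 0)
    stop("X, Y, Z must be pairwise disjoint", call. = FALSE)
  triangleBoundFormula(pairDensity(g, X, Y), pairDensity(g, Y, Z),
                       pairDensity(g, Z, X), eps,
                       c(length(X), length(Y), length(Z)))
}

#' Exact tripartite triangle count
#'
#' Counts triangles (x, y, z) with x in X, y in Y, z in Z and all three
#' edges present; the exact oracle the sampled lower bounds are compared
#' against.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param X,Y,Z pairwise disjoint vertex sets.
#' @return integer count.
#' @export
countTrianglesTripartite <- function(g, X, Y, Z) {
  X <- .assertVertexSet(g, X, "X")
  Y <- .assertVertexSet(g, Y, "Y")
  Z <- .assertVertexSet(g, Z, "Z")
  if (length(intersect(X, Y)) + length(intersect(Y, Z)) +
      length(intersect(X, Z)) > 0)
    stop("X, Y, Z must be pairwise disjoint", call. = FALSE)
  a <- g@adjacency
  common <- t(a[X, Y, drop = FALSE]) %*% a[X, Z, drop = FALSE]
  as.integer(sum(common * a[Y, Z, drop = FALSE]))
}

#' Sampled triangle lower bounds over random cluster triples
#'
#' Draws \code{reps} uniform random triples of distinct non-junk clusters
#' (with replacement across repetitions) and evaluates the triangle lower
#' bound on each; reports per-sample values and their min / mean / max. The
#' mean is the headline scalar; all three summaries are kept because the
#' "lowest bound out of 10 repetitions" convention is ambiguous.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param part a \linkS4class{VertexPartition} with >= 3 clusters.
#' @param eps regularity tolerance.
#' @param reps number of sampled triples (default 10).
#' @param seed integer seed.
#' @return list with \code{samples} (data.frame: cluster indices i, j, k,
#'   densities alpha, beta, gamma, bound), \code{min}, \code{mean},
#'   \code{max}, \code{reps}, \code{seed}.
#' @export
sampledTriangleBound <- function(g, part, eps, reps = 10, seed = 1) {
  k <- numClusters(part)
  if (k < 3) stop("need at least 3 non-junk clusters", call. = FALSE)
  triples <- .withSeed(seed, t(replicate(reps, sort(sample(k, 3)))))
  rows <- lapply(seq_len(reps), function(r) {
    tri <- triples[r, ]
    X <- part@clusters[[tri[1]]]
    Y <- part@clusters[[tri[2]]]
    Z <- part@clusters[[tri[3]]]
    al <- pairDensity(g, X, Y); be <- pairDensity(g, Y, Z)
    ga <- pairDensity(g, Z, X)
    data.frame(i = tri[1], j = tri[2], k = tri[3],
               alpha = al, beta = be, gamma = ga,
               bound = triangleBoundFormula(al, be, ga, eps,
                                            lengths(list(X, Y, Z))))
  })
  samples <- do.call(rbind, rows)
  list(samples = samples, min = min(samples$bound),
       mean = mean(samples$bound), max = max(samples$bound),
       reps = as.integer(reps), seed = .assertSeed(seed))
}

#' Index of a partition
#'
#' ind(P) = (1 / k^2) * sum of squared pairwise densities over ordered pairs
#' of distinct non-junk clusters -- the expected between-cluster edge mass of
#' the pseudo-random approximation. Within-cluster (i = j) terms and the
#' junk cluster are excluded. The index lies in [0, 1 - 1/k] and is
#' non-decreasing under regularity refinement (up to the practical
#' algorithm's lack of the formal guarantee).
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param part a \linkS4class{VertexPartition} with k >= 2 clusters.
#' @return real in [0, 1 - 1/k].
#' @export
partitionIndex <- function(g, part) {
  k <- numClusters(part)
  if (k < 2) stop("need at least 2 non-junk clusters", call. = FALSE)
  total <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    total <- total +
      pairDensity(g, part@clusters[[i]], part@clusters[[j]])^2
  2 * total / k^2
}

#' Newman-Girvan modularity of a partition
#'
#' MOD(P) = sum_i [ l_i / L - (d_i / 2L)^2 ] with L the total edge count,
#' l_i the number of edges inside cluster i and d_i the total degree of
#' cluster i. Junk vertices are treated as their own singleton clusters so
#' the degree mass is conserved on partial partitions.
#'
#' @param g a \linkS4class{SimpleGraph} with at least one edge.
#' @param part a \linkS4class{VertexPartition}, or an integer membership
#'   vector with one label per vertex.
#' @return modularity value (<= 1).
#' @export
partitionModularity <- function(g, part) {
  L <- numEdges(g)
  if (L == 0) stop("modularity undefined on an edgeless graph", call. = FALSE)
  if (is(part, "VertexPartition")) {
    groups <- c(part@clusters, as.list(part@junk))
  } else {
    memb <- as.integer(part)
    if (length(memb) != numVertices(g))
      stop("membership vector must cover all vertices", call. = FALSE)
    groups <- split(seq_along(memb), memb)
  }
  a <- g@adjacency
  deg <- rowSums(a)
  total <- 0
  for (grp in groups) {
    li <- sum(a[grp, grp, drop = FALSE]) / 2
    di <- sum(deg[grp])
    total <- total + li / L - (di / (2 * L))^2
  }
  total
}

#' Table-style metric summary of a partitioning run
#'
#' One row per refinement round: cluster count, cluster size, sampled
#' triangle-bound summaries, partition index and modularity -- the
#' per-partition descriptor set.
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param hist a \linkS4class{PartitionHistory}.
#' @param reps triangle-bound repetitions per round.
#' @param seed integer seed for the triple sampling.
#' @return data.frame with one row per round.
#' @export
partitionMetrics <- function(g, hist, reps = 10, seed = 1) {
  eps <- hist@params@eps
  rows <- lapply(seq_along(hist@partitions), function(r) {
    p <- hist@partitions[[r]]
    k <- numClusters(p)
    tb <- if (k >= 3)
      sampledTriangleBound(g, p, eps, reps = reps,
                           seed = (.assertSeed(seed) + r) %% 2147483647L)
    else list(min = NA_real_, mean = NA_real_, max = NA_real_)
    data.frame(round = r, n_clusters = k, cluster_size = clusterSize(p),
               junk_size = length(p@junk),
               triangle_bound_min = tb$min, triangle_bound_mean = tb$mean,
               triangle_bound_max = tb$max,
               index = if (k >= 2) partitionIndex(g, p) else NA_real_,
               modularity = partitionModularity(g, p),
               irregular_pairs = hist@irregularPairs[r])
  })
  do.call(rbind, rows)
}
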