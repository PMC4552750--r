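#' Modified co-affinity matrix over a family of partitions
#'
#' Entry (i, j) is the fraction of partitions in the family in which
#' vertices i and j share a non-junk cluster -- the same-cluster probability
#' over the low-modularity partitions the regularity refinement produces.
#' A vertex sitting in the junk cluster of a partition shares a cluster
#' with nobody in that partition (not even other junk vertices). The
#' diagonal is fixed at 1 by convention.
#'
#' @param family a \linkS4class{PartitionHistory} (all its rounds are used)
#'   or a non-empty list of \linkS4class{VertexPartition} over one vertex
#'   set.
#' @return a \linkS4class{CoAffinityMatrix}.
#' @export
coaffinityMatrix <- function(family) {
  if (is(family, "PartitionHistory")) family <- family@partitions
  if (length(family) == 0) stop("empty partition family", call. = FALSE)
  n <- family[[1]]@n
  acc <- matrix(0, n, n)
  for (p in family) {
    if (p@n != n) stop("partitions are over different vertex sets",
                       call. = FALSE)
    memb <- rep(NA_integer_, n)
    for (ci in seq_along(p@clusters)) memb[p@clusters[[ci]]] <- ci
    same <- outer(memb, memb, `==`)
    same[is.na(same)] <- FALSE
    acc <- acc + same
  }
  cmat <- acc / length(family)
  diag(cmat) <- 1
  new("CoAffinityMatrix", c = cmat, familySize = length(family))
}

#' Co-affinity values
#' @param x a \linkS4class{CoAffinityMatrix}.
#' @return symmetric numeric matrix.
#' @export
coaffinityValues <- function(x) x@c

#' Bandwidth of a symmetric sparsity pattern
#'
#' @param m square matrix; entries different from 0 off the diagonal define
#'   the pattern.
#' @return max |i - j| over off-diagonal nonzeros (0 for a diagonal
#'   pattern).
#' @export
matrixBandwidth <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  if (nrow(idx) == 0) return(0L)
  as.integer(max(abs(idx[, 1] - idx[, 2])))
}

# Reverse Cuthill-McKee on a symmetric 0/1 pattern: per connected
# component, breadth-first search from a minimum-degree vertex, visiting
# neighbours in increasing degree order; the concatenated order is reversed.
.rcm <- function(pattern) {
  n <- nrow(pattern)
  adj <- lapply(seq_len(n), function(i) {
    nb <- which(pattern[i, ] != 0)
    nb[nb != i]
  })
  deg <- lengths(adj)
  visited <- rep(FALSE, n)
  order_out <- integer(0)
  while (any(!visited)) {
    remaining <- which(!visited)
    start <- remaining[which.min(deg[remaining])]
    queue <- start
    visited[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      order_out <- c(order_out, v)
      nb <- adj[[v]][!visited[adj[[v]]]]
      nb <- nb[order(deg[nb], nb)]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  rev(order_out)
}

#' Reverse Cuthill-McKee reordering of a co-affinity matrix
#'
#' Binarizes the co-affinity values at \code{sparsifyAt} (entries >=
#' threshold form the pattern), runs reverse Cuthill-McKee on the pattern
#' to pull large values toward the diagonal, and returns the vertex
#' permutation. If the reordering does not reduce the pattern bandwidth the
#' better of the RCM order and the identity is returned, so the permuted
#' bandwidth never exceeds the original.
#'
#' @param x a \linkS4class{CoAffinityMatrix} (or a plain symmetric matrix).
#' @param sparsifyAt binarization threshold in [0, 1); default 0.5
#'   (majority vote over the partition family).
#' @return integer permutation p; apply as \code{values[p, p]}.
#' @export
rcmReorder <- function(x, sparsifyAt = 0.5) {
  if (is(x, "CoAffinityMatrix")) x <- coaffinityValues(x)
  if (sparsifyAt < 0 || sparsifyAt >= 1)
    stop("sparsifyAt must be in [0, 1)", call. = FALSE)
  pattern <- (x >= sparsifyAt) * 1L
  diag(pattern) <- 0L
  if (sum(pattern) == 0) {
    warning("sparsification produced an empty pattern; identity permutation",
            call. = FALSE)
    return(seq_len(nrow(x)))
  }
  perm <- .rcm(pattern)
  if (matrixBandwidth(pattern[perm, perm]) <= matrixBandwidth(pattern))
    perm
  else
    seq_len(nrow(x))
}
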