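#' Generate a stochastic block model graph
#'
#' Planted-partition fixture: vertices are split into \code{nBlocks}
#' contiguous blocks (the first \code{n mod k} blocks get one extra vertex);
#' each within-block pair is an edge independently with probability
#' \code{pIn}, each cross-block pair with \code{pOut}. The returned labels
#' are the ground truth used for clustering-accuracy evaluation downstream.
#'
#' @param nVertices number of vertices.
#' @param nBlocks number of planted blocks.
#' @param pIn within-block edge probability.
#' @param pOut cross-block edge probability.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return list with components \code{graph} (a \linkS4class{SimpleGraph})
#'   and \code{labels} (integer block label per vertex, 1-based).
#' @examples
#' sbm <- generateSBM(40, 4, pIn = 0.8, pOut = 0.05, seed = 1)
#' table(sbm$labels)
#' @export
generateSBM <- function(nVertices, nBlocks, pIn, pOut, seed) {
  n <- as.integer(nVertices)
  k <- as.integer(nBlocks)
  pIn <- .assertProb(pIn, "pIn")
  pOut <- .assertProb(pOut, "pOut")
  if (n < 1 || k < 1 || k > n) stop("need 1 <= nBlocks <= nVertices",
                                    call. = FALSE)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  labels <- rep(seq_len(k), times = sizes)
  pmat <- matrix(pOut, k, k)
  diag(pmat) <- pIn
  a <- .withSeed(seed, {
    u <- matrix(0, n, n)
    ut <- upper.tri(u)
    u[ut] <- stats::runif(sum(ut))
    (u < pmat[cbind(rep(labels, times = n), rep(labels, each = n))] & ut) * 1L
  })
  list(graph = simpleGraph(a + t(a)), labels = labels)
}

#' Generate a random bipartite graph
#'
#' Edges appear only between the two sides, each independently with
#' probability \code{p}; large instances behave like the pseudo-random pairs
#' the regularity machinery is built to detect.
#'
#' @param nLeft,nRight side sizes.
#' @param p edge probability.
#' @param seed integer seed.
#' @return list with \code{graph} (a \linkS4class{SimpleGraph} on
#'   \code{nLeft + nRight} vertices), \code{left} and \code{right}
#'   (the two vertex sets).
#' @export
generateRandomBipartite <- function(nLeft, nRight, p, seed) {
  nl <- as.integer(nLeft); nr <- as.integer(nRight)
  p <- .assertProb(p, "p")
  if (nl < 1 || nr < 1) stop("side sizes must be positive", call. = FALSE)
  n <- nl + nr
  left <- seq_len(nl)
  right <- nl + seq_len(nr)
  a <- matrix(0L, n, n)
  block <- .withSeed(seed, (matrix(stats::runif(nl * nr), nl, nr) < p) * 1L)
  a[left, right] <- block
  a[right, left] <- t(block)
  list(graph = simpleGraph(a), left = left, right = right)
}

#' Generate ROI-structured voxel time series
#'
#' Emulates multi-voxel BOLD recordings with block (ROI) correlation
#' structure: voxels in the same ROI share a latent signal,
#' \deqn{x_i(t) = \sqrt{\rho}\, z_{roi(i)}(t) + \sqrt{1-\rho}\, \eta_i(t)
#'   + \sigma\, m_i(t),}
#' with unit-variance Gaussian latents, so the expected within-ROI pairwise
#' correlation is \eqn{\rho / (1 + \sigma^2)} and cross-ROI correlations are
#' 0 in expectation. Voxels are assigned to ROIs contiguously (first
#' \code{nVoxels mod nRois} ROIs get one extra voxel) and given synthetic
#' grid coordinates.
#'
#' @param nVoxels number of voxels.
#' @param nRois number of ROIs (\code{<= nVoxels}).
#' @param nTimepoints number of samples per voxel (>= 3).
#' @param rhoWithin target within-ROI correlation in [0, 1).
#' @param noiseSd standard deviation \eqn{\sigma} of optional measurement
#'   noise (default 0).
#' @param seed integer seed.
#' @return an \linkS4class{ActivityMatrix} with ROI labels and coordinates.
#' @examples
#' am <- generateRoiTimeSeries(30, 3, 100, rhoWithin = 0.6, seed = 1)
#' am
#' @export
generateRoiTimeSeries <- function(nVoxels, nRois, nTimepoints, rhoWithin,
                                  noiseSd = 0, seed) {
  nv <- as.integer(nVoxels); nr <- as.integer(nRois)
  Tn <- as.integer(nTimepoints)
  if (nr > nv || nr < 1) stop("need 1 <= nRois <= nVoxels", call. = FALSE)
  if (Tn < 3) stop("nTimepoints must be >= 3 (correlation degenerate)",
                   call. = FALSE)
  if (rhoWithin < 0 || rhoWithin >= 1)
    stop("rhoWithin must be in [0, 1)", call. = FALSE)
  if (noiseSd < 0) stop("noiseSd must be non-negative", call. = FALSE)
  base <- nv %/% nr
  extra <- nv %% nr
  sizes <- rep(base, nr) + c(rep(1L, extra), rep(0L, nr - extra))
  labels <- rep(seq_len(nr), times = sizes)
  vals <- .withSeed(seed, {
    z <- matrix(stats::rnorm(nr * Tn), nr, Tn)
    eta <- matrix(stats::rnorm(nv * Tn), nv, Tn)
    m <- if (noiseSd > 0) noiseSd * matrix(stats::rnorm(nv * Tn), nv, Tn)
         else 0
    sqrt(rhoWithin) * z[labels, , drop = FALSE] +
      sqrt(1 - rhoWithin) * eta + m
  })
  # synthetic grid coordinates: one ROI per z-slab
  coords <- cbind(x = as.numeric((seq_len(nv) - 1) %% 10),
                  y = as.numeric(((seq_len(nv) - 1) %/% 10) %% 10),
                  z = as.numeric(labels))
  dimnames(coords) <- NULL
  new("ActivityMatrix", values = vals, coords = coords,
      roiLabels = as.integer(labels))
}

#' Generate repeated trials of ROI-structured time series
#'
#' Each trial draws fresh latent and noise signals under the same ROI layout,
#' mirroring the repeated-trial design of event-related recordings; trial
#' seeds are derived deterministically from \code{seed}.
#'
#' @inheritParams generateRoiTimeSeries
#' @param nTrials number of trials.
#' @return list of \linkS4class{ActivityMatrix}, one per trial (identical
#'   labels and coordinates across trials).
#' @export
generateRoiTrials <- function(nVoxels, nRois, nTimepoints, rhoWithin,
                              noiseSd = 0, seed, nTrials) {
  seed <- .assertSeed(seed)
  lapply(seq_len(as.integer(nTrials)), function(t)
    generateRoiTimeSeries(nVoxels, nRois, nTimepoints, rhoWithin, noiseSd,
                          seed = (seed + 7919L * t) %% .Machine$integer.max))
}
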