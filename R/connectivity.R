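#' Construct an activity matrix
#'
#' @param values numeric voxels-by-timepoints matrix.
#' @param coords optional n-by-3 coordinate matrix.
#' @param roiLabels optional integer label per voxel.
#' @return an \linkS4class{ActivityMatrix}.
#' @export
activityMatrix <- function(values, coords = NULL, roiLabels = NULL) {
  v <- as.matrix(values)
  if (anyNA(v)) {
    bad <- which(apply(v, 1, anyNA))
    stop(sprintf("missing values in voxel row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  new("ActivityMatrix", values = v,
      coords = if (is.null(coords)) matrix(0, 0, 3) else as.matrix(coords),
      roiLabels = if (is.null(roiLabels)) integer(0)
                  else as.integer(roiLabels))
}

#' Voxel values of an activity matrix
#' @param acts an \linkS4class{ActivityMatrix}.
#' @return numeric matrix, voxels in rows.
#' @export
activityValues <- function(acts) acts@values

#' Ground-truth ROI labels of an activity matrix
#' @param acts an \linkS4class{ActivityMatrix}.
#' @return integer vector (length 0 when absent).
#' @export
roiLabels <- function(acts) acts@roiLabels

#' Pearson correlation matrix between voxel time series
#'
#' Standard product-moment correlation
#' \deqn{r_{XY} = \frac{\sum_t (X_t - \bar X)(Y_t - \bar Y)}
#'   {\sqrt{\sum_t (X_t - \bar X)^2 \sum_t (Y_t - \bar Y)^2}}}
#' between every pair of voxel rows. Rows with zero variance cannot carry a
#' correlation; their entries are defined as 0 (off-diagonal) with a warning,
#' which preserves index alignment with coordinates and labels.
#'
#' @param acts an \linkS4class{ActivityMatrix} with at least 3 timepoints.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonCorrelationMatrix <- function(acts) {
  v <- activityValues(acts)
  if (ncol(v) < 3) stop("need at least 3 timepoints", call. = FALSE)
  sds <- apply(v, 1, stats::sd)
  flat <- which(sds == 0)
  r <- suppressWarnings(stats::cor(t(v)))
  dimnames(r) <- NULL
  if (length(flat) > 0) {
    warning(sprintf("%d zero-variance voxel(s) (e.g. row %d); correlations set to 0",
                    length(flat), flat[1]), call. = FALSE)
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Threshold a correlation matrix into a binary connectivity graph
#'
#' The adjacency rule keeps the strongest \code{keepFraction} of all voxel
#' pairs: the threshold is the (1 - keepFraction) quantile of the
#' off-diagonal correlations and an edge is placed for correlations above
#' it. Ties at the threshold are broken deterministically by lower vertex
#' index pair, so the edge count is exactly
#' \code{floor(keepFraction * n(n-1)/2)}. Only the positive tail creates
#' edges by default; set \code{absolute = TRUE} to rank by |r| instead.
#'
#' @param corr symmetric correlation matrix.
#' @param keepFraction fraction of pairs to keep, in (0, 1]; default 0.10.
#' @param absolute rank by absolute correlation instead of signed value.
#' @return a \linkS4class{SimpleGraph}; the chosen threshold is attached as
#'   attribute \code{"threshold"}.
#' @export
thresholdAdjacency <- function(corr, keepFraction = 0.10, absolute = FALSE) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (keepFraction <= 0 || keepFraction > 1)
    stop("keepFraction must be in (0, 1]", call. = FALSE)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  vals <- corr[upper.tri(corr)]
  if (absolute) vals <- abs(vals)
  if (length(vals) == 0) stop("graph too small to threshold", call. = FALSE)
  if (diff(range(vals)) == 0)
    stop("degenerate threshold: all correlations are equal", call. = FALSE)
  target <- floor(keepFraction * n * (n - 1) / 2)
  ord <- order(-vals, ut[, 1], ut[, 2])
  keep <- ord[seq_len(target)]
  g <- edgeListGraph(n, ut[keep, , drop = FALSE])
  attr(g, "threshold") <- if (target > 0) vals[ord[target]] else Inf
  g
}

#' Split an activity matrix into epochs
#'
#' Epochs are half-open column ranges \code{[start, end)} in 0-based
#' timepoint indices (e.g. three 4 s windows at 0.5 s sampling are
#' \code{(0, 8), (8, 16), (16, 24)}).
#'
#' @param acts an \linkS4class{ActivityMatrix}.
#' @param epochs list of 2-vectors \code{c(start, end)}, 0-based half-open.
#' @return list of \linkS4class{ActivityMatrix}, one per epoch.
#' @export
segmentEpochs <- function(acts, epochs) {
  Tn <- ncol(activityValues(acts))
  used <- rep(FALSE, Tn)
  out <- lapply(epochs, function(ep) {
    s <- as.integer(ep[1]); e <- as.integer(ep[2])
    if (s < 0 || e > Tn || s >= e)
      stop(sprintf("epoch [%d, %d) out of range or empty (T = %d)", s, e, Tn),
           call. = FALSE)
    cols <- (s + 1):e
    if (any(used[cols])) stop("epochs overlap", call. = FALSE)
    used[cols] <<- TRUE
    new("ActivityMatrix", values = acts@values[, cols, drop = FALSE],
        coords = acts@coords, roiLabels = acts@roiLabels)
  })
  out
}

#' Trial-averaged correlation matrix
#'
#' Computes the Pearson correlation matrix per trial and averages the
#' matrices (never the raw signals) across trials.
#'
#' @param trials list of \linkS4class{ActivityMatrix} with identical voxel
#'   counts.
#' @return symmetric matrix: the element-wise mean of per-trial correlation
#'   matrices.
#' @export
averageTrialCorrelation <- function(trials) {
  if (length(trials) == 0) stop("no trials supplied", call. = FALSE)
  nv <- nrow(activityValues(trials[[1]]))
  mats <- lapply(trials, function(tr) {
    if (nrow(activityValues(tr)) != nv)
      stop("trials have mismatched voxel counts", call. = FALSE)
    pearsonCorrelationMatrix(tr)
  })
  Reduce(`+`, mats) / length(mats)
}
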