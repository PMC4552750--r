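#' Read a graph from edge-list TSV or Matrix Market
#'
#' Edge lists are two-column, 0-based, tab-separated. Matrix Market files
#' are coordinate-format adjacency (1-based, translated at the boundary).
#' Input is symmetrized; self-loops and duplicate edges are dropped with a
#' message.
#'
#' @param path input file.
#' @param format "auto" (by extension), "edgelist", or "mtx".
#' @param n vertex count for edge lists (default: max index + 1).
#' @return a \linkS4class{SimpleGraph}.
#' @export
readGraph <- function(path, format = c("auto", "edgelist", "mtx"), n = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "edgelist"
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (nrow(m) != ncol(m)) stop("adjacency matrix must be square",
                                 call. = FALSE)
    loops <- sum(diag(m) != 0)
    if (loops > 0) message(sprintf("dropped %d self-loop(s)", loops))
    return(simpleGraph(m))
  }
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("integer", "integer"))
  if (ncol(tab) < 2) stop("edge list needs two columns", call. = FALSE)
  if (any(tab < 0)) stop("edge list indices must be non-negative",
                         call. = FALSE)
  e <- as.matrix(tab[, 1:2]) + 1L
  nv <- if (is.null(n)) max(e) else as.integer(n)
  loops <- sum(e[, 1] == e[, 2])
  if (loops > 0) message(sprintf("dropped %d self-loop(s)", loops))
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  dups <- sum(duplicated(key))
  if (dups > 0) message(sprintf("collapsed %d duplicate edge(s)", dups))
  edgeListGraph(nv, e)
}

#' Write a graph as edge-list TSV or Matrix Market
#'
#' @param g a \linkS4class{SimpleGraph}.
#' @param path output file.
#' @param format "auto" (by extension), "edgelist", or "mtx".
#' @return invisibly, the path.
#' @export
writeGraph <- function(g, path, format = c("auto", "edgelist", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "edgelist"
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(adjacencyMatrix(g),
                                               sparse = TRUE),
                                "generalMatrix"), path)
  } else {
    e <- edgeList(g) - 1L
    utils::write.table(e, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read vertex labels from two-column TSV
#' @param path file with columns: vertex (0-based), label.
#' @return integer label vector ordered by vertex.
#' @export
readLabels <- function(path) {
  tab <- utils::read.table(path, header = FALSE)
  labels <- integer(max(tab[, 1]) + 1L)
  labels[tab[, 1] + 1L] <- as.integer(tab[, 2])
  labels
}

#' Write vertex labels as two-column TSV
#' @param labels integer label per vertex.
#' @param path output file (vertex written 0-based).
#' @return invisibly, the path.
#' @export
writeLabels <- function(labels, path) {
  utils::write.table(data.frame(v = seq_along(labels) - 1L, label = labels),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read an activity matrix from delimited text
#'
#' @param path values file: voxels in rows, timepoints in columns,
#'   tab-separated, no header.
#' @param sidecar optional TSV with columns x, y, z, roi (one row per
#'   voxel, header present).
#' @return an \linkS4class{ActivityMatrix}.
#' @export
readActivityMatrix <- function(path, sidecar = NULL) {
  vals <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(vals) <- NULL
  coords <- NULL; roi <- NULL
  if (!is.null(sidecar)) {
    sc <- utils::read.table(sidecar, header = TRUE, sep = "\t")
    coords <- as.matrix(sc[, c("x", "y", "z")])
    roi <- sc$roi
  }
  activityMatrix(vals, coords = coords, roiLabels = roi)
}

#' Write an activity matrix (and optional sidecar) as delimited text
#'
#' @param acts an \linkS4class{ActivityMatrix}.
#' @param path values file.
#' @param sidecar optional path for the coordinates/ROI sidecar TSV.
#' @return invisibly, the path.
#' @export
writeActivityMatrix <- function(acts, path, sidecar = NULL) {
  utils::write.table(activityValues(acts), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(sidecar)) {
    co <- acts@coords
    if (nrow(co) == 0) co <- matrix(NA_real_, nrow(acts@values), 3)
    roi <- acts@roiLabels
    if (length(roi) == 0) roi <- rep(NA_integer_, nrow(acts@values))
    utils::write.table(
      data.frame(x = co[, 1], y = co[, 2], z = co[, 3], roi = roi),
      sidecar, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Serialize a partition history to JSON
#'
#' Vertices are written 0-based. The JSON carries the halt reason, the
#' parameters, and per round the clusters, junk set and irregular-pair
#' count.
#'
#' @param hist a \linkS4class{PartitionHistory}.
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
writePartitionHistory <- function(hist, path) {
  obj <- list(
    halt_reason = hist@haltReason,
    params = list(eps = hist@params@eps, l = hist@params@l,
                  h = hist@params@h,
                  max_iterations = hist@params@maxIterations),
    rounds = lapply(seq_along(hist@partitions), function(r) {
      p <- hist@partitions[[r]]
      list(clusters = lapply(p@clusters, function(cl) cl - 1L),
           junk = p@junk - 1L,
           irregular_pairs = hist@irregularPairs[r])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a partition history from JSON
#'
#' Restores the partitions, halt reason and parameters written by
#' \code{\link{writePartitionHistory}}. Verdicts are not serialized, so the
#' \code{verdicts} slot of the result is empty.
#'
#' @param path JSON file.
#' @param n vertex count (default: inferred from the first round).
#' @return a \linkS4class{PartitionHistory}.
#' @export
readPartitionHistory <- function(path, n = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rounds <- obj$rounds
  mkPart <- function(rd, nv) {
    junk <- as.integer(unlist(rd$junk))
    new("VertexPartition",
        junk = if (length(junk)) junk + 1L else integer(0),
        clusters = lapply(rd$clusters,
                          function(cl) as.integer(unlist(cl)) + 1L),
        n = nv)
  }
  nv <- if (!is.null(n)) as.integer(n) else {
    r1 <- rounds[[1]]
    length(unlist(r1$junk)) + length(unlist(r1$clusters))
  }
  partitions <- lapply(rounds, mkPart, nv = nv)
  new("PartitionHistory", partitions = partitions,
      verdicts = rep(list(list()), length(partitions)),
      irregularPairs = vapply(rounds, function(r)
        as.integer(r$irregular_pairs), integer(1)),
      haltReason = obj$halt_reason,
      params = regularityParams(obj$params$eps, obj$params$l, obj$params$h,
                                obj$params$max_iterations))
}

#' Write a report table as TSV
#'
#' Numeric columns are written at full double precision; for each numeric
#' column a rounded \code{<name>_display} companion (4 decimals) is
#' appended for eyeballing.
#'
#' @param rows non-empty data.frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeReport <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("report rows must be a non-empty data.frame", call. = FALSE)
  out <- rows
  for (nm in names(rows)) {
    if (is.double(rows[[nm]])) {
      out[[nm]] <- sprintf("%.17g", rows[[nm]])
      out[[paste0(nm, "_display")]] <- round(rows[[nm]], 4)
    }
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the configuration (paths, parameters, seeds), package version
#' and per-stage status of a run -- enough to re-run it bit-identically.
#'
#' @param config named list of configuration values; every stochastic stage
#'   must have a seed recorded here.
#' @param results named list of per-stage results/status.
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
runManifest <- function(config, results, path) {
  if (is.null(config$seed))
    stop("config must record a seed before execution", call. = FALSE)
  obj <- list(package = "regpart",
              version = as.character(utils::packageVersion("regpart")),
              config = config, results = results)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
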