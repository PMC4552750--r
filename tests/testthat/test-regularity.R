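test_that("sequential initial partitions are equitable with trailing junk", {
  p <- initialPartition(10, 4)
  expect_equal(clusterSize(p), 2L)
  expect_length(junkVertices(p), 2L)
  p2 <- initialPartition(8, 4)
  expect_equal(clusters(p2), list(1:2, 3:4, 5:6, 7:8))
  expect_length(junkVertices(p2), 0L)
  p3 <- initialPartition(17, 4)
  expect_equal(numClusters(p3), 4L)
  expect_equal(clusterSize(p3), 4L)
  expect_length(junkVertices(p3), 1L)
  expect_error(initialPartition(3, 4), "n >= l")
})

test_that("extreme pairs are declared regular", {
  cg <- makeCompleteGraph(16)
  v <- checkRegularity(cg, 1:8, 9:16, eps = 0.05)
  expect_true(v@regular)
  expect_equal(v@density, 1)
  ve <- checkRegularity(makeEmptyGraph(16), 1:8, 9:16, eps = 0.05)
  expect_true(ve@regular)
  expect_error(checkRegularity(cg, 1:8, 9:15, eps = 0.1), "equal size")
})

test_that("the half-complete construction yields a verified certificate", {
  hp <- makeHalfCompletePair(4)
  v <- checkRegularity(hp$g, hp$X, hp$Y, eps = 0.2)
  expect_false(v@regular)
  expect_equal(v@density, 0.25)
  expect_true(certificateIsValid(hp$g, hp$X, hp$Y, v))
  expect_gte(abs(v@density - v@certDensity), 0.2)
})

test_that("brute force enumeration decides regularity exactly", {
  expect_true(bruteForceRegularity(makeCompleteGraph(8), 1:4, 5:8,
                                   0.1)$regular)
  hp <- makeHalfCompletePair(4)
  bf <- bruteForceRegularity(hp$g, hp$X, hp$Y, eps = 0.2)
  expect_false(bf$regular)
  expect_equal(bf$worstDeviation, 0.75)
  # single edge at eps = 0.9: only near-full subsets qualify, deviation tiny
  a <- matrix(0L, 8, 8); a[1, 5] <- 1L
  g1 <- simpleGraph(a + t(a))
  expect_true(bruteForceRegularity(g1, 1:4, 5:8, eps = 0.9)$regular)
  big <- makeCompleteGraph(30)
  expect_error(bruteForceRegularity(big, 1:15, 16:30, 0.1), "too large")
})

test_that("certificates agree one-sidedly with the exhaustive oracle", {
  for (s in 1:30) {
    p <- c(0.2, 0.5, 0.8)[1 + s %% 3]
    bp <- generateRandomBipartite(10, 10, p, seed = 100 + s)
    for (eps in c(0.1, 0.2)) {
      v <- checkRegularity(bp$graph, bp$left, bp$right, eps, seed = s)
      if (!v@regular) {
        expect_true(certificateIsValid(bp$graph, bp$left, bp$right, v))
        bf <- bruteForceRegularity(bp$graph, bp$left, bp$right, eps)
        expect_false(bf$regular)
      }
    }
  }
})

test_that("refinement without certificates chops clusters into l parts", {
  part <- initialPartition(16, 2)  # two clusters of 8
  ref <- refinePartition(makeEmptyGraph(16), part, list(), l = 4)
  expect_equal(numClusters(ref), 8L)
  expect_equal(clusterSize(ref), 2L)
  expect_length(junkVertices(ref), 0L)
})

test_that("refinement splits clusters along certificate atoms", {
  part <- initialPartition(16, 2)  # clusters 1:8 and 9:16, m = 8/4 = 2
  vd <- new("RegularityVerdict", pair = c(1L, 2L), regular = FALSE,
            certA = 1:4, certB = 9:11, density = 0.5, certDensity = 0.9,
            eps = 0.2)
  ref <- refinePartition(makeEmptyGraph(16), part, list(vd), l = 4)
  expect_equal(clusterSize(ref), 2L)
  # cluster 1 atoms {1..4} and {5..8} each chop cleanly
  hasCluster <- function(part, cl)
    any(vapply(clusters(part), identical, logical(1), cl))
  for (cl in list(1:2, 3:4, 5:6, 7:8))
    expect_true(hasCluster(ref, cl))
  # cluster 2 atom {9,10,11} leaves 11 for junk; atom {12..16} leaves 16
  expect_true(all(c(11L, 16L) %in% junkVertices(ref)))
  expect_lte(numClusters(ref), 1 + 4 * 2)
  expect_error(refinePartition(makeEmptyGraph(16), ref, list(), l = 4),
               "underflow")
})

test_that("trivial graphs halt in one round as regular", {
  h <- regularityPartition(makeCompleteGraph(20),
                           regularityParams(eps = 0.1, l = 4, h = 1))
  expect_equal(h@haltReason, "regular")
  expect_length(h@partitions, 1)
  expect_equal(h@irregularPairs, 0L)
  he <- regularityPartition(makeEmptyGraph(20),
                            regularityParams(eps = 0.1, l = 4, h = 1))
  expect_equal(he@haltReason, "regular")
})

test_that("partitioning a structured graph satisfies the loop invariants", {
  # clusters deliberately straddle the planted blocks so the initial pairs
  # are genuinely irregular and refinement has to run
  sbm <- generateSBM(160, 8, 0.9, 0.02, seed = 21)
  perm <- withr::with_seed(21, sample(160))
  a <- adjacencyMatrix(sbm$graph)[perm, perm]
  g <- simpleGraph(a)
  h <- regularityPartition(g, regularityParams(eps = 0.25, l = 4, h = 2),
                           seed = 21)
  n <- 160
  prevSize <- NULL
  for (r in seq_along(h@partitions)) {
    p <- h@partitions[[r]]
    sizes <- lengths(clusters(p))
    expect_true(length(unique(sizes)) <= 1)                 # equitable
    expect_equal(length(junkVertices(p)) + sum(sizes), n)   # conservation
    if (!is.null(prevSize)) expect_equal(clusterSize(p), prevSize %/% 4)
    prevSize <- clusterSize(p)
    for (v in h@verdicts[[r]]) {
      if (!v@regular) {
        i <- v@pair[1]; j <- v@pair[2]
        expect_true(certificateIsValid(g, clusters(p)[[i]],
                                       clusters(p)[[j]], v))
      }
    }
  }
  expect_true(h@haltReason %in% c("regular", "size_limit"))
  if (h@haltReason == "regular") {
    k <- numClusters(finalPartition(h))
    expect_lte(h@irregularPairs[length(h@irregularPairs)], 0.25 * k^2)
  }
})

test_that("large random bipartite pairs read as pseudo-random", {
  reg <- vapply(1:10, function(s) {
    bp <- generateRandomBipartite(200, 200, 0.5, seed = 400 + s)
    checkRegularity(bp$graph, bp$left, bp$right, eps = 0.1,
                    seed = s)@regular
  }, logical(1))
  expect_gte(mean(reg), 0.9)
})
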