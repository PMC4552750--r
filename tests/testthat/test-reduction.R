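test_that("reduced graphs carry pairwise densities", {
  cg <- makeCompleteGraph(12)
  part <- initialPartition(12, 4)
  rg <- reducedGraph(cg, part, connectAll = TRUE)
  w <- reducedWeights(rg)
  expect_equal(w[upper.tri(w)], rep(1, 6))
  expect_equal(diag(w), rep(0, 4))
})

test_that("density-floor mode drops weak or irregular pairs", {
  sbm <- generateSBM(40, 4, 0.5, 0.05, seed = 41)
  part <- initialPartition(40, 4)
  verdicts <- list()
  k <- 4
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    verdicts[[length(verdicts) + 1]] <-
      checkRegularity(sbm$graph, clusters(part)[[i]], clusters(part)[[j]],
                      eps = 0.2, pair = c(i, j))
  rg <- reducedGraph(sbm$graph, part, verdicts, d = 0.9, connectAll = FALSE)
  expect_equal(sum(reducedWeights(rg)), 0)  # all densities ~0.05 <= 0.9
  rgAll <- reducedGraph(sbm$graph, part, verdicts, connectAll = TRUE)
  expect_true(all(reducedWeights(rgAll)[upper.tri(matrix(0, 4, 4))] > 0))
  expect_error(reducedGraph(sbm$graph, part, d = 1), "density floor")
})

test_that("aligned SBM partitions reduce to the planted connectivity", {
  sbm <- generateSBM(400, 4, 0.5, 0.05, seed = 43)
  part <- initialPartition(400, 8)  # two clusters per block
  rg <- reducedGraph(sbm$graph, part, connectAll = TRUE)
  w <- reducedWeights(rg)
  blockOf <- rep(1:4, each = 2)
  for (i in 1:7) for (j in (i + 1):8) {
    expected <- if (blockOf[i] == blockOf[j]) 0.5 else 0.05
    se <- sqrt(expected * (1 - expected) / 50^2)
    expect_lt(abs(w[i, j] - expected), 4 * se)
  }
})

test_that("ncut separates disconnected halves exactly", {
  g <- makeTwoCliques(5)
  labels <- ncutCluster(adjacencyMatrix(g) * 1.0, nClusters = 2, seed = 1)
  expect_length(unique(labels[1:5]), 1)
  expect_length(unique(labels[6:10]), 1)
  expect_false(labels[1] == labels[6])
  # determinism under the seed
  expect_identical(labels,
                   ncutCluster(adjacencyMatrix(g) * 1.0, 2, seed = 1))
  expect_error(ncutCluster(matrix(0, 4, 4), 2, seed = 1), "zero-weight")
  expect_error(ncutCluster(adjacencyMatrix(g) * 1.0, 1, seed = 1), ">= 2")
})

test_that("ncut recovers planted pairs, matching brute-force normalized cut", {
  # 8 nodes in 4 strongly tied pairs, weak ties elsewhere
  w <- matrix(0.05, 8, 8); diag(w) <- 0
  for (p in 1:4) {
    i <- 2 * p - 1
    w[i, i + 1] <- w[i + 1, i] <- 1
  }
  labels <- ncutCluster(w, nClusters = 4, seed = 3)
  for (p in 1:4) expect_equal(labels[2 * p - 1], labels[2 * p])
  expect_length(unique(labels), 4)
  # exhaustive minimization of the Ncut objective over all 4-partitions
  ncutObj <- function(assign) {
    tot <- 0
    for (lb in unique(assign)) {
      inA <- assign == lb
      cut <- sum(w[inA, !inA])
      vol <- sum(w[inA, ])
      if (vol > 0) tot <- tot + cut / vol
    }
    tot
  }
  parts <- expand.grid(rep(list(1:4), 7))
  best <- Inf; bestAssign <- NULL
  for (r in seq_len(nrow(parts))) {
    assign <- c(1L, as.integer(unlist(parts[r, ])))
    if (length(unique(assign)) != 4) next
    o <- ncutObj(assign)
    if (o < best) { best <- o; bestAssign <- assign }
  }
  for (p in 1:4) expect_equal(bestAssign[2 * p - 1], bestAssign[2 * p])
  expect_equal(ncutObj(labels), best, tolerance = 1e-9)
})

test_that("component-wise assignment handles very fragmented graphs", {
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  w[5, 6] <- w[6, 5] <- 1
  # 3 components but 2 clusters requested: grouped, all nodes labeled
  labels <- ncutCluster(w, nClusters = 2, seed = 1)
  expect_length(unique(labels), 2)
  expect_equal(labels[1], labels[2])
  expect_equal(labels[3], labels[4])
})

test_that("labels map back through the partition and junk is distributed", {
  part <- new("VertexPartition", junk = c(9L, 10L),
              clusters = list(1:4, 5:8), n = 10L)
  lv <- mapBack(c(2L, 7L), part)
  expect_equal(lv[1:4], rep(2L, 4))
  expect_equal(lv[5:8], rep(7L, 4))
  expect_true(all(is.na(lv[9:10])))
  expect_error(mapBack(c(1L), part), "per non-junk cluster")
  # vertex 9 tied only to the second group; vertex 10 isolated -> largest
  a <- matrix(0L, 10, 10)
  a[9, 5:8] <- 1L
  g <- simpleGraph(a + t(a))
  full <- assignJunk(g, lv)
  expect_equal(full[9], 7L)
  expect_equal(full[10], 2L)  # groups tie in size; lower label wins
  expect_equal(full[1:8], lv[1:8])  # non-junk labels untouched
})

test_that("junk redistribution follows the planted blocks in an SBM", {
  sbm <- generateSBM(200, 4, 0.5, 0.05, seed = 47)
  labels <- sbm$labels
  junk <- withr::with_seed(47, sample(200, 30))
  lv <- labels; lv[junk] <- NA_integer_
  full <- assignJunk(sbm$graph, lv)
  expect_gte(mean(full[junk] == labels[junk]), 0.9)
})

test_that("Hungarian-matched accuracy equals the exhaustive optimum", {
  expect_equal(clusteringAccuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(clusteringAccuracy(c(1, 1, 2, 2), c(9, 9, 4, 4)), 1)
  expect_equal(clusteringAccuracy(c(0, 0, 1, 1), c(1, 0, 0, 1)), 0.5)
  expect_error(clusteringAccuracy(1:4, 1:5), "length")
  for (s in 1:40) {
    nl <- 2 + s %% 5
    tr <- withr::with_seed(s, sample(nl, 24, replace = TRUE))
    pr <- withr::with_seed(1000 + s, sample(nl + s %% 2, 24, replace = TRUE))
    expect_equal(clusteringAccuracy(tr, pr), exhaustiveAccuracy(tr, pr))
  }
})

test_that("optimal matching dominates arbitrary fixed label mappings", {
  tr <- withr::with_seed(3, sample(4, 40, replace = TRUE))
  pr <- withr::with_seed(4, sample(4, 40, replace = TRUE))
  acc <- clusteringAccuracy(tr, pr)
  expect_gte(acc, mean(tr == pr))  # identity mapping is one candidate
})

test_that("both pipelines are perfect on disconnected cliques", {
  g <- makeTwoCliques(10)
  truth <- rep(1:2, each = 10)
  cp <- comparePipelines(g, truth,
                         regularityParams(eps = 0.1, l = 2, h = 2),
                         nClusters = 2, seed = 5)
  expect_equal(cp$reducedNcutAccuracy, 1)
  expect_equal(cp$normalNcutAccuracy, 1)
  expect_error(comparePipelines(g, truth, regularityParams(0.1, 2, 2),
                                nClusters = 1, seed = 5), ">= 2")
})
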