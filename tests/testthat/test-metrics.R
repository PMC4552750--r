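test_that("triangle bound formula evaluates and clamps", {
  expect_equal(triangleBoundFormula(1, 1, 1, eps = 0, sizes = c(7, 7, 7)),
               343)
  expect_equal(triangleBoundFormula(0.05, 0.5, 0.5, eps = 0.1,
                                    sizes = c(10, 10, 10)), 0)
  # direct arithmetic on the printed form, eps = 0.016, n = 18, d = 0.1
  expected <- (1 - 2 * 0.016) * (0.1 - 0.016)^3 * 18^3
  expect_equal(triangleBoundFormula(0.1, 0.1, 0.1, 0.016, c(18, 18, 18)),
               expected)
  expect_equal(expected, 3.346, tolerance = 1e-3)
})

test_that("triangle bound on graphs uses the pairwise densities", {
  cg <- makeCompleteGraph(9)
  expect_equal(triangleLowerBound(cg, 1:3, 4:6, 7:9, eps = 0), 27)
  expect_error(triangleLowerBound(cg, 1:3, 3:5, 7:9, eps = 0), "disjoint")
})

test_that("tripartite triangle counts match a brute-force triple loop", {
  expect_equal(countTrianglesTripartite(makeCompleteGraph(6), 1:2, 3:4, 5:6),
               8L)
  expect_equal(countTrianglesTripartite(makeEmptyGraph(6), 1:2, 3:4, 5:6),
               0L)
  sbm <- generateSBM(30, 3, 0.6, 0.3, seed = 13)
  g <- sbm$graph
  X <- 1:10; Y <- 11:20; Z <- 21:30
  a <- adjacencyMatrix(g)
  count <- 0
  for (x in X) for (y in Y) for (z in Z)
    if (a[x, y] && a[y, z] && a[x, z]) count <- count + 1
  expect_equal(countTrianglesTripartite(g, X, Y, Z), count)
})

test_that("sampled triangle bounds are deterministic and summarized", {
  cg <- makeCompleteGraph(20)
  part <- initialPartition(20, 4)
  rep1 <- sampledTriangleBound(cg, part, eps = 0.05, reps = 10, seed = 5)
  rep2 <- sampledTriangleBound(cg, part, eps = 0.05, reps = 10, seed = 5)
  expect_identical(rep1$samples, rep2$samples)
  # complete graph: every triple has all densities 1
  expect_equal(rep1$min, rep1$max)
  expect_equal(rep1$mean, 0.9 * 0.95^3 * 5^3)
  expect_equal(nrow(rep1$samples), 10L)
  eg <- makeEmptyGraph(20)
  expect_equal(sampledTriangleBound(eg, part, 0.05, seed = 1)$max, 0)
  expect_error(sampledTriangleBound(cg, initialPartition(20, 2), 0.05,
                                    seed = 1), "3 non-junk")
})

test_that("sampled bounds never exceed the exact triangle count", {
  sbm <- generateSBM(120, 4, 0.5, 0.1, seed = 17)
  part <- initialPartition(120, 6)
  rep <- sampledTriangleBound(sbm$graph, part, eps = 0.1, reps = 10,
                              seed = 17)
  for (r in seq_len(nrow(rep$samples))) {
    tri <- rep$samples[r, ]
    exact <- countTrianglesTripartite(sbm$graph,
                                      clusters(part)[[tri$i]],
                                      clusters(part)[[tri$j]],
                                      clusters(part)[[tri$k]])
    expect_lte(tri$bound, exact)
  }
})

test_that("partition index matches its closed forms", {
  expect_equal(partitionIndex(makeEmptyGraph(12), initialPartition(12, 4)), 0)
  expect_equal(partitionIndex(makeCompleteGraph(12), initialPartition(12, 2)),
               0.5)
  for (k in c(2, 4, 6)) {
    cg <- makeCompleteGraph(24)
    expect_equal(partitionIndex(cg, initialPartition(24, k)), 1 - 1 / k)
  }
  expect_error(partitionIndex(makeCompleteGraph(8), initialPartition(8, 1)),
               "at least 2")
})

test_that("modularity matches hand cases and the igraph implementation", {
  g <- makeTwoCliques(5)
  allInOne <- new("VertexPartition", junk = integer(0),
                  clusters = list(1:10), n = 10L)
  expect_equal(partitionModularity(g, allInOne), 0)
  planted <- new("VertexPartition", junk = integer(0),
                 clusters = list(1:5, 6:10), n = 10L)
  expect_equal(partitionModularity(g, planted), 0.5)
  expect_error(partitionModularity(makeEmptyGraph(4), allInOne), "edgeless")
  # independent cross-check on an arbitrary membership
  sbm <- generateSBM(60, 3, 0.6, 0.1, seed = 19)
  memb <- sbm$labels
  expect_equal(partitionModularity(sbm$graph, memb),
               igraph::modularity(asIgraph(sbm$graph), memb))
  # junk vertices enter as singletons: matches igraph with singleton labels
  pj <- new("VertexPartition", junk = 1:6,
            clusters = list(7:33, 34:60), n = 60L)
  membJ <- as.integer(factor(c(100 + 1:6, rep(1, 27), rep(2, 27))))
  expect_equal(partitionModularity(sbm$graph, pj),
               igraph::modularity(asIgraph(sbm$graph), membJ))
})

test_that("planted partitions beat random ones on modularity", {
  sbm <- generateSBM(100, 4, 0.5, 0.05, seed = 23)
  plantedPart <- new("VertexPartition", junk = integer(0),
                     clusters = split(1:100, sbm$labels), n = 100L)
  randomPart <- new("VertexPartition", junk = integer(0),
                    clusters = split(withr::with_seed(23, sample(100)),
                                     rep(1:4, each = 25)), n = 100L)
  expect_gt(partitionModularity(sbm$graph, plantedPart),
            partitionModularity(sbm$graph, randomPart))
})

test_that("per-round metric tables cover every refinement round", {
  sbm <- generateSBM(64, 4, 0.9, 0.02, seed = 29)
  perm <- withr::with_seed(29, sample(64))
  g <- simpleGraph(adjacencyMatrix(sbm$graph)[perm, perm])
  h <- regularityPartition(g, regularityParams(eps = 0.3, l = 4, h = 2),
                           seed = 29)
  tab <- partitionMetrics(g, h, reps = 5, seed = 29)
  expect_equal(nrow(tab), length(h@partitions))
  expect_true(all(tab$modularity <= 1))
  expect_true(all(tab$n_clusters * tab$cluster_size + tab$junk_size == 64))
})
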