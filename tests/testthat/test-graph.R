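test_that("proportionalThreshold retains exactly the top-k edges", {
  # weights 1..10 on the 10 edges of K5, enumeration order
  fc <- edgeMatrix(1:10, 5)
  A <- proportionalThreshold(fc, 0.3) # k = 3: weights 10, 9, 8
  expect_equal(sum(A) / 2, 3)
  expect_equal(A[4, 5], 1L) # weight 10
  expect_equal(A[3, 5], 1L) # weight 9
  expect_equal(A[3, 4], 1L) # weight 8
  expect_equal(A[1, 2], 0L)

  expect_equal(sum(proportionalThreshold(fc, 1)) / 2, 10) # complete graph
  expect_error(proportionalThreshold(fc, 0), "density")
  expect_error(proportionalThreshold(fc, 1.5), "density")

  # R = 116 at density 0.1 -> exactly round(0.1 * 6670) = 667 edges
  set.seed(51)
  big <- edgeMatrix(stats::rnorm(6670), 116)
  expect_equal(sum(proportionalThreshold(big, 0.1)) / 2, 667)

  # deterministic lexicographic tie-break on equal weights
  tied <- edgeMatrix(rep(1, 6), 4)
  At <- proportionalThreshold(tied, 0.5) # k = 3
  expect_equal(which(At[upper.tri(At)] == 1),
               which(edgeMatrix(c(1, 1, 1, 0, 0, 0), 4)[upper.tri(At)] == 1))

  # absolute ranking picks large negative weights too
  fcNeg <- edgeMatrix(c(-5, 4, 0, 0, 0, 0), 4)
  expect_equal(proportionalThreshold(fcNeg, 1 / 6, absolute = TRUE)[1, 2], 1L)
  expect_equal(proportionalThreshold(fcNeg, 1 / 6, absolute = FALSE)[1, 2], 0L)
})

test_that("nodal clustering matches hand cases and the triple-enumeration oracle", {
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(nodalClustering(K3), rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(nodalClustering(star), rep(0, 5))
  A <- randomAdjacency(12, 0.4, seed = 52)
  expect_equal(nodalClustering(A), oracleClustering(A), tolerance = 1e-12)
})

test_that("local efficiency matches hand cases and the induced-subgraph oracle", {
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(nodalLocalEfficiency(K5), rep(1, 5))
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(nodalLocalEfficiency(path3), c(0, 0, 0)) # a,c not linked
  A <- randomAdjacency(10, 0.5, seed = 53)
  expect_equal(nodalLocalEfficiency(A), oracleLocalEfficiency(A),
               tolerance = 1e-12)
})

test_that("characteristic path length is the harmonic mean of geodesics", {
  K6 <- matrix(1, 6, 6) - diag(6)
  expect_equal(characteristicPathLength(K6), 1)
  # two disjoint dyads on 4 nodes: sum(1/d) = 4 over P = 12 ordered pairs
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  expect_equal(characteristicPathLength(dyads), 3)
  # path a-b-c: L = 6 / (1 + 1 + 0.5 + 1 + 1 + 0.5) = 1.2
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(characteristicPathLength(path3), 1.2)
  expect_error(characteristicPathLength(matrix(0, 4, 4)), "edgeless")
})

test_that("largest component size matches the label-propagation oracle", {
  pathN <- matrix(0, 7, 7)
  for (i in 1:6) pathN[i, i + 1] <- pathN[i + 1, i] <- 1
  expect_equal(largestComponentSize(pathN), 7)
  expect_equal(largestComponentSize(matrix(0, 5, 5)), 1)
  for (s in 1:5) {
    A <- randomAdjacency(11, 0.15, seed = 60 + s)
    expect_equal(largestComponentSize(A), oracleLargestComponent(A))
  }
})

test_that("graph metrics agree with igraph on random graphs", {
  for (s in 1:20) {
    A <- randomAdjacency(12, stats::runif(1, 0.2, 0.6), seed = 70 + s)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(nodalClustering(A), cc, tolerance = 1e-12)
    expect_equal(largestComponentSize(A),
                 max(igraph::components(g)$csize))
    if (sum(A) > 0) {
      expect_equal(characteristicPathLength(A),
                   1 / igraph::global_efficiency(g), tolerance = 1e-12)
    }
  }
})

test_that("rewiring nulls preserve the degree multiset and simplicity", {
  A <- randomAdjacency(20, 0.3, seed = 80)
  nulls <- rewireDegreePreserving(A, nNulls = 5, swapsPerEdge = 10, seed = 80)
  for (nl in nulls) {
    expect_true(isSimpleBinary(nl))
    expect_equal(degreeMultiset(nl), degreeMultiset(A))
    expect_equal(sum(nl), sum(A))
    expect_false(identical(nl, A)) # thoroughly randomized graph moved
  }
  expect_identical(nulls,
                   rewireDegreePreserving(A, 5, 10, seed = 80))
  # 4-cycle: the only simple graphs on degree sequence (2,2,2,2) are 4-cycles
  C4 <- matrix(0, 4, 4)
  C4[1, 2] <- C4[2, 3] <- C4[3, 4] <- C4[1, 4] <- 1
  C4 <- C4 + t(C4)
  for (nl in rewireDegreePreserving(C4, nNulls = 20, swapsPerEdge = 10,
                                    seed = 81)) {
    expect_equal(degreeMultiset(nl), c(2, 2, 2, 2))
    expect_equal(sum(nl) / 2, 4)
    expect_equal(largestComponentSize(nl), 4) # connected -> a 4-cycle
  }
})

test_that("small-worldness is 1 on the complete graph and > 1 on a lattice-like graph", {
  K8 <- matrix(1, 8, 8) - diag(8)
  sw <- suppressWarnings(smallWorldness(K8, nNulls = 5, seed = 90))
  expect_equal(sw$sigma, 1)
  expect_equal(sw$C, 1)
  expect_equal(sw$L, 1)

  # ring lattice with k = 4 neighbours: high C, long paths; nulls break both
  n <- 24
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (d in 1:2) {
      j <- ((i - 1 + d) %% n) + 1
      ring[i, j] <- ring[j, i] <- 1
    }
  }
  swr <- smallWorldness(ring, nNulls = 10, seed = 91)
  expect_gt(swr$sigma, 1)
})

test_that("runDensityGrid yields nested edge counts and unit-normalized endpoint", {
  co <- makeCohort(2, 2, covariates = FALSE, seed = 92)
  ef <- makeEffectMap(45, 0, 0, 0, noiseSd = 1, seed = 92)
  fce <- simulateDirectZ(co, ef, seed = 92)
  grid <- suppressWarnings(
    runDensityGrid(fce, grid = c(0.2, 0.5, 1), nNulls = 3, seed = 92))
  for (sid in unique(grid$global$subject_id)) {
    ne <- grid$global$n_edges[grid$global$subject_id == sid]
    expect_true(all(diff(ne) > 0)) # strictly increasing along the grid
  }
  dense <- grid$global[grid$global$density == 1, ]
  expect_equal(dense$C_norm, rep(1, 4), tolerance = 1e-12)
  expect_equal(dense$L_norm, rep(1, 4), tolerance = 1e-12)
  expect_equal(dense$sigma, rep(1, 4), tolerance = 1e-12)
  expect_equal(dense$largest_component, rep(10, 4))
  # deterministic given the seed
  grid2 <- suppressWarnings(
    runDensityGrid(fce, grid = c(0.2, 0.5, 1), nNulls = 3, seed = 92))
  expect_identical(grid$global, grid2$global)
  expect_identical(grid$nodal, grid2$nodal)
  # default grid
  expect_length(parseDensityGrid("0.05:0.95:0.05"), 19)
})
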