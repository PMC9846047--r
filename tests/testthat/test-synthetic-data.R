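test_that("generated heads are exact ellipsoids with analytic landmarks", {
  h <- sphereHead(3)
  expect_lt(max(abs(sqrt(rowSums(h@vertices^2)) - 1)), 1e-9)
  # landmarks are geodesically equidistant from the apex on a sphere
  apex <- c(0, 0, 1)
  angles <- apply(h@landmarks, 1, function(l)
    acos(sum(l * apex) / sqrt(sum(l^2))))
  expect_lt(max(abs(angles - pi / 2)), 1e-12)
  expect_error(makeHead(axes = c(1, -1, 1)), "invalid axis")
})

test_that("each subdivision level quadruples the face count", {
  f1 <- nrow(makeHead(subdiv = 1L)@faces)
  f2 <- nrow(makeHead(subdiv = 2L)@faces)
  f3 <- nrow(sphereHead(3)@faces)
  expect_equal(f1, 80L)    # 20 * 4
  expect_equal(f2, 4L * f1)
  expect_equal(f3, 4L * f2)
})

test_that("the shell mask matches brute-force enumeration", {
  h <- sphereHead(3, radius = 60)
  g <- makeShellGrid(h, voxelSize = 10, thickness = 30, gap = 12)
  xyz <- voxelCoordinates(g)
  r <- sqrt(rowSums(xyz^2))
  expect_true(all(r >= 60 - 30 - 1e-9 & r <= 60 - 12 + 1e-9))
  # full-array enumeration oracle for the mask count
  dims <- g@dims
  all_idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
  world <- cbind(all_idx, 1) %*% t(gridAffine(g))
  rAll <- sqrt(rowSums(world[, 1:3]^2))
  expect_equal(nVoxels(g), sum(rAll >= 30 & rAll <= 48))
  # every shell voxel is strictly inside the scalp
  expect_lt(max(r), 60)
  expect_error(makeShellGrid(h, thickness = 0), "thickness")
  expect_error(makeShellGrid(h, thickness = 10, gap = 12), "thickness")
})

test_that("connectome blocks converge to their specified correlations", {
  h <- sphereHead(2, radius = 60)
  g <- makeShellGrid(h, voxelSize = 12, thickness = 30, gap = 10)
  mc <- makeConnectome(g, k = 2L, rhoWithin = 0.8, between = -0.4,
                       timepoints = 2000L, seed = 12L)
  x <- mc$connectome@data
  cc <- crossprod(x) / (nrow(x) - 1)
  w1 <- mc$labels == 1L
  off1 <- cc[w1, w1][upper.tri(cc[w1, w1])]
  off2 <- cc[!w1, !w1][upper.tri(cc[!w1, !w1])]
  betw <- cc[w1, !w1]
  expect_lt(abs(mean(off1) - 0.8), 0.05)
  expect_lt(abs(mean(off2) - 0.8), 0.05)
  expect_lt(abs(mean(betw) + 0.4), 0.05)
  # labels split the shell into contiguous angular sectors
  expect_equal(sort(unique(mc$labels)), c(1L, 2L))
  xyz <- voxelCoordinates(g)
  expect_true(all(mc$labels[xyz[, 2] > abs(xyz[, 1])] == 1L))
})

test_that("heavy measurement noise washes out the correlations", {
  h <- sphereHead(2, radius = 60)
  g <- makeShellGrid(h, voxelSize = 14, thickness = 30, gap = 10)
  mc <- makeConnectome(g, k = 2L, rhoWithin = 0.8, between = -0.4,
                       timepoints = 500L, noiseSd = 30, seed = 13L)
  x <- mc$connectome@data
  cc <- crossprod(x) / (nrow(x) - 1)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.1)
})

test_that("an infeasible block structure is rejected", {
  h <- sphereHead(2, radius = 60)
  g <- makeShellGrid(h, voxelSize = 14, thickness = 30, gap = 10)
  # K = 3 with all pairwise factor correlations -0.9 is not PSD
  expect_error(makeConnectome(g, k = 3L, rhoWithin = 0.5, between = -0.45,
                              timepoints = 10L, seed = 1L),
               "positive definite")
})

test_that("generation is bitwise deterministic under a fixed seed", {
  h <- sphereHead(2, radius = 60)
  g <- makeShellGrid(h, voxelSize = 12, thickness = 30, gap = 10)
  a <- makeConnectome(g, timepoints = 50L, seed = 99L)
  b <- makeConnectome(g, timepoints = 50L, seed = 99L)
  expect_identical(a$connectome@data, b$connectome@data)
  expect_identical(a$labels, b$labels)
  # the caller's RNG stream is untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(makeConnectome(g, timepoints = 10L, seed = 7L))
  expect_identical(rnorm(1), before)
})

test_that("noiseless planted cohorts have a perfect NTA-outcome coupling", {
  st <- testStudy()
  h <- testHead(); g <- testGrid()
  labels <- makeConnectome(g, timepoints = 3L, seed = 1L)$labels
  noiseless <- makePlantedCohort(h, g, labels, nSubjects = 4L,
                                 timepoints = 80L, beta = 2, sigmaE = 0,
                                 seed = 3L)
  expect_equal(cor(noiseless$cohort$nta, noiseless$cohort$outcome), 1.0,
               tolerance = 1e-12)
  expect_equal(noiseless$cohort$outcome, 2 * noiseless$cohort$nta)
  # cohort regenerated from the same seed is identical
  again <- makePlantedCohort(h, g, labels, nSubjects = 4L,
                             timepoints = 80L, beta = 2, sigmaE = 0,
                             seed = 3L)
  expect_identical(noiseless$cohort, again$cohort)
  # planted foci: hypoactive cluster on the target network
  expect_true(all(st$foci$direction %in% c(-1, 1)))
  expect_true(any(st$foci$direction == -1))
  # the bundle passes every upstream validity check by construction
  for (s in st$subjects) expect_true(validObject(s))
})

test_that("the planted scalp projection sits inside the CPC domain", {
  st <- testStudy()
  pc <- st$truth$projectionCpc
  expect_true(all(pc > 0.05 & pc < 0.95))
  # placements are jittered around it within the stated window
  expect_true(all(abs(st$cohort$p_nz - pc[1]) <= 0.18 + 1e-9 |
                  st$cohort$p_nz %in% c(0.05, 0.95)))
})
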