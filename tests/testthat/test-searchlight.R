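test_that("enumerateSearchlights clips cubes at borders and masks", {
  mask <- array(TRUE, dim = c(9, 9, 9))
  sls <- enumerateSearchlights(mask, 3)
  byCenter <- vapply(sls, function(s) length(s$voxelIds), integer(1))
  centerIdx <- which(vapply(sls, function(s) all(s$center == c(5, 5, 5)),
                            logical(1)))
  expect_equal(byCenter[centerIdx], 343L)        # interior: 7^3
  cornerIdx <- which(vapply(sls, function(s) all(s$center == c(1, 1, 1)),
                            logical(1)))
  expect_equal(byCenter[cornerIdx], 64L)         # corner: 4^3
  # random mask: counts match a brute-force triple loop
  set.seed(1)
  rmask <- array(runif(6 * 6 * 6) < 0.5, dim = c(6, 6, 6))
  rmask[1, 1, 1] <- TRUE
  sls2 <- enumerateSearchlights(rmask, 2)
  for (k in sample(length(sls2), 5)) {
    s <- sls2[[k]]
    count <- 0
    for (x in 1:6) for (y in 1:6) for (z in 1:6) {
      if (abs(x - s$center[1]) <= 2 && abs(y - s$center[2]) <= 2 &&
          abs(z - s$center[3]) <= 2 && rmask[x, y, z]) count <- count + 1
    }
    expect_equal(length(s$voxelIds), count)
  }
  expect_error(enumerateSearchlights(array(FALSE, c(2, 2, 2))), "empty mask")
})

test_that("countPairings matches printed values and brute-force enumeration", {
  expect_equal(unname(countPairings(16, 8)), c(448, 6720))
  expect_equal(unname(countPairings(2, 2)), c(2, 2))
  bruteCount <- function(nImages, nRuns) {
    w <- 0; b <- 0
    for (r in 1:(nRuns - 1)) for (s in (r + 1):nRuns) {
      for (i in 1:nImages) for (j in 1:nImages) {
        if (i == j) w <- w + 1 else b <- b + 1
      }
    }
    c(w, b)
  }
  expect_equal(unname(countPairings(16, 6)), bruteCount(16, 6))
  for (ni in c(2, 5, 20)) for (nr in c(2, 4, 10)) {
    expect_equal(unname(countPairings(ni, nr)), bruteCount(ni, nr))
  }
})

test_that("stabilityZ separates stable patterns from noise and is invariant to labels", {
  nImg <- 8; nVox <- 60; nRuns <- 4
  set.seed(2)
  base <- matrix(rnorm(nImg * nVox), nImg, nVox)
  stable <- lapply(1:nRuns, function(r) betaMaps(base + 0 * r))
  zHigh <- stabilityZ(stable, nResamples = 500, seed = 1)
  expect_gt(zHigh, 3)
  noise <- noiseRunBetas(nImg, nVox, nRuns, seed = 3)
  zLow <- stabilityZ(noise, nResamples = 500, seed = 1)
  expect_lt(abs(zLow), 4)
  # seeded repetition is exact
  expect_identical(stabilityZ(noise, nResamples = 500, seed = 1), zLow)
  # relabeling images consistently across runs leaves z unchanged
  perm <- sample(nImg)
  relabeled <- lapply(noise, function(b) betaMaps(betaValues(b)[perm, ]))
  expect_equal(stabilityZ(relabeled, nResamples = 500, seed = 1), zLow,
               tolerance = 1e-12)
  # run order is irrelevant
  expect_equal(stabilityZ(noise[c(3, 1, 4, 2)], nResamples = 500, seed = 1),
               zLow, tolerance = 1e-12)
})

test_that("similarity pools have the combinatorially correct sizes", {
  for (nRuns in c(2, 4)) {
    runs <- noiseRunBetas(5, 20, nRuns, seed = 4)
    pools <- layerprint:::.similarityPools(runs, 1:20)
    expect_length(pools$within, unname(countPairings(5, nRuns)["within"]))
    expect_length(pools$between, unname(countPairings(5, nRuns)["between"]))
  }
  degenerate <- lapply(1:2, function(r)
    betaMaps(rbind(rep(1, 5), rnorm(5), rnorm(5))))
  expect_error(layerprint:::.similarityPools(degenerate, 1:5), "degenerate")
})

test_that("stabilityMap localizes a stable region and stays calibrated on noise", {
  rsms <- orthogonalLayerRSMs(2, nImages = 8, seed = 5)
  grid <- c(12L, 12L, 6L)
  regionVox <- gridCube(c(3, 3, 1), 5, grid)
  spec <- groundTruthSpec(grid, list(list(voxels = regionVox,
                                          layerId = "layer01",
                                          signalScale = 2)),
                          noiseSd = 0.5, nParticipants = 1, nRuns = 4,
                          participantSd = 0, seed = 6)
  runs <- simulateBetaMaps(spec, rsms)$betamaps[[1]]
  mask <- array(TRUE, dim = grid)
  zmap <- stabilityMap(runs, mask = mask, halfWidth = 2, nResamples = 300,
                       seed = 7)
  z <- statValues(zmap)
  hot <- which(z > 5)
  # suprathreshold centers confined to the region plus a 3-voxel dilation
  regCoord <- arrayInd(regionVox, grid)
  hotCoord <- arrayInd(which(mask)[hot], grid)
  for (k in seq_len(nrow(hotCoord))) {
    dist <- min(apply(abs(sweep(regCoord, 2, hotCoord[k, ])), 1, max))
    expect_lte(dist, 3)
  }
  expect_gt(length(hot), 0)
  # all-noise grid: z approximately calibrated (the subsampled null runs
  # slightly narrow because within-pool correlations share runs and images,
  # so a mildly heavy tail is expected)
  noiseRuns <- noiseRunBetas(8, prod(grid), 8, seed = 8)
  noiseRuns <- lapply(noiseRuns, function(b)
    betaMaps(betaValues(b), mask = mask))
  zn <- statValues(stabilityMap(noiseRuns, mask = mask, halfWidth = 1,
                                nResamples = 300, seed = 9))
  expect_lt(abs(mean(zn)), 0.5)
  expect_gt(sd(zn), 0.8)
  expect_lt(sd(zn), 1.3)
  expect_lt(mean(abs(zn) > 1.96), 0.15)
  # single-voxel mask: single-entry map (undefined: searchlight too small)
  m1 <- array(FALSE, dim = grid); m1[6, 6, 3] <- TRUE
  z1 <- stabilityMap(runs, mask = m1, halfWidth = 2, nResamples = 50,
                     seed = 10)
  expect_length(statValues(z1), 1)
})
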