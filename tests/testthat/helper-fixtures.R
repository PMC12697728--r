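# Shared fixtures built in code: tiny adapters, pattern matrices and
# synthetic-brain helpers used across the test files.

# independent Pearson oracle: textbook formula, double loop
bruteForcePearsonRSM <- function(patterns) {
  n <- nrow(patterns)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    x <- patterns[i, ]; y <- patterns[j, ]
    xc <- x - mean(x); yc <- y - mean(y)
    out[i, j] <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  out
}

# a cube of linear indices inside a grid
gridCube <- function(orig, size, grid) {
  g <- expand.grid(x = orig[1]:(orig[1] + size - 1),
                   y = orig[2]:(orig[2] + size - 1),
                   z = orig[3]:(orig[3] + size - 1))
  g$x + (g$y - 1) * grid[1] + (g$z - 1) * grid[1] * grid[2]
}

# a small two-region synthetic brain carrying two orthogonalized layer RSMs
makeTwoRegionSim <- function(seed, nLayers = 4, nImages = 16, nParticipants = 6,
                             nRuns = 4, noiseSd = 0.5, signalScale = 1,
                             participantSd = 0.2) {
  rsms <- orthogonalLayerRSMs(nLayers, nImages = nImages, seed = seed)
  grid <- c(16L, 16L, 8L)
  regions <- list(
    list(voxels = gridCube(c(1, 1, 1), 7, grid), layerId = names(rsms)[1],
         signalScale = signalScale),
    list(voxels = gridCube(c(10, 10, 2), 7, grid), layerId = names(rsms)[2],
         signalScale = signalScale))
  spec <- groundTruthSpec(grid, regions, noiseSd = noiseSd,
                          nParticipants = nParticipants, nRuns = nRuns,
                          participantSd = participantSd, seed = seed)
  sim <- simulateBetaMaps(spec, rsms)
  centerOf <- function(orig) (orig[1] + 3) + (orig[2] + 2) * grid[1] +
    (orig[3] + 2) * grid[1] * grid[2]
  list(rsms = rsms, grid = grid, regions = regions, sim = sim,
       centers = c(centerOf(c(1, 1, 1)), centerOf(c(10, 10, 2))))
}

# noise-only run-level beta maps (flat grid)
noiseRunBetas <- function(nImages, nVoxels, nRuns, seed) {
  lapply(seq_len(nRuns), function(r) {
    set.seed(seed * 1000 + r)
    betaMaps(matrix(rnorm(nImages * nVoxels), nImages, nVoxels))
  })
}
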