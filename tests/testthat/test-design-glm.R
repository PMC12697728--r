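test_that("generateSequence satisfies the full trial contract", {
  sq <- generateSequence(seed = 1)
  tr <- trials(sq)
  expect_equal(nrow(tr), 80)
  expect_equal(sum(tr$is_target), 8)          # ceiling(0.1 * 80)
  counts <- table(tr$image_id)
  expect_true(all(counts == 5))
  expect_false(any(tr$image_id[-1] == tr$image_id[-80]))
  expect_true(all(diff(tr$onset_s) > 0))
  isis <- diff(tr$onset_s) - tr$duration_s[-80]
  expect_true(all(isis %in% c(1.5, 3, 4.5)))
  # seeded bit-reproducibility
  expect_identical(trials(generateSequence(seed = 1)), tr)
  # contract holds across many seeds
  for (s in 2:50) {
    t2 <- trials(generateSequence(seed = s))
    expect_false(any(t2$image_id[-1] == t2$image_id[-80]))
    expect_true(all(table(t2$image_id) == 5))
  }
  expect_error(generateSequence(nImages = 1, nReps = 2, maxRetries = 50),
               "no-back-to-back")
})

test_that("ISI frequencies are uniform over the jitter set across seeds", {
  isis <- unlist(lapply(1:150, function(s) {
    tr <- trials(generateSequence(seed = s))
    diff(tr$onset_s) - tr$duration_s[-nrow(tr)]
  }))
  n <- length(isis)     # 150 sequences x 79 ISIs
  counts <- table(factor(isis, levels = c(1.5, 3, 4.5)))
  # 4-sigma binomial band around 1/3
  band <- 4 * sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(counts / n - 1 / 3) < band))
})

test_that("doubleGammaHRF has the canonical two-gamma shape", {
  expect_equal(doubleGammaHRF(0), 0)
  grid <- seq(0, 32, by = 0.001)
  h <- doubleGammaHRF(grid)
  expect_equal(max(h), 1, tolerance = 1e-4)   # peak-normalized
  # argmax matches an independent fine-grid evaluation of the formula
  raw <- dgamma(grid, shape = 6, scale = 1) -
    dgamma(grid, shape = 16, scale = 1) / 6
  expect_equal(grid[which.max(h)], grid[which.max(raw)], tolerance = 1e-3)
  expect_error(doubleGammaHRF(-1), "nonnegative")
})

test_that("buildDesign places HRF responses only where events occur", {
  tr0 <- data.frame(image_id = character(0), onset_s = numeric(0),
                    duration_s = numeric(0), is_target = logical(0))
  empty <- new("TrialSequence", trials = tr0, runLength = 30)
  X0 <- buildDesign(empty, nVolumes = 20, imageIds = c("a", "b"))
  expect_true(all(as.matrix(X0) == 0))
  one <- new("TrialSequence",
             trials = data.frame(image_id = "a", onset_s = 3, duration_s = 1.5,
                                 is_target = FALSE),
             runLength = 30)
  X1 <- buildDesign(one, nVolumes = 30, imageIds = c("a", "b"))
  m <- as.matrix(X1)
  expect_gt(max(abs(m[, "a"])), 0.5)
  expect_true(all(m[, "b"] == 0))
  # determinism
  expect_identical(as.matrix(buildDesign(one, nVolumes = 30,
                                         imageIds = c("a", "b"))), m)
  expect_error(buildDesign(one, nVolumes = 2), "past the run end")
})

test_that("fitGLM is exact on noiseless data and matches normal equations", {
  sq <- generateSequence(nImages = 6, nReps = 3, seed = 4)
  B <- matrix(rnorm(6 * 20), 6, 20)
  sim <- simulateBOLD(B, sq, noiseSd = 0)
  fit <- fitGLM(sim$bold, sim$design)
  expect_lt(max(abs(betaValues(fit) - B)), 1e-8)
  # brute-force normal-equations oracle on noisy data
  sim2 <- simulateBOLD(B, sq, noiseSd = 1, seed = 9)
  fit2 <- fitGLM(sim2$bold, sim2$design)
  X <- cbind(as.matrix(sim2$design), 1)
  oracle <- solve(t(X) %*% X, t(X) %*% sim2$bold)
  expect_lt(max(abs(betaValues(fit2) - oracle[1:6, ])), 1e-8)
  # constant offset lands in the intercept, not the image betas
  fit3 <- fitGLM(sim2$bold + 5, sim2$design)
  expect_lt(max(abs(betaValues(fit3) - betaValues(fit2))), 1e-8)
  # rank deficiency names the collinear regressor
  Xbad <- as.matrix(sim2$design)
  Xbad[, 2] <- Xbad[, 1]
  dbad <- new("DesignMatrix", values = Xbad, trS = 1.5,
              regressorIds = sim2$design@regressorIds)
  expect_error(fitGLM(sim2$bold, dbad), "collinear")
})

test_that("pure-noise GLM betas are centered on zero", {
  sq <- generateSequence(nImages = 4, nReps = 4, seed = 6)
  X <- buildDesign(sq)
  set.seed(7)
  bold <- matrix(rnorm(nrow(as.matrix(X)) * 400), nrow(as.matrix(X)), 400)
  fit <- fitGLM(bold, X)
  b <- betaValues(fit)
  se <- sd(b) / sqrt(length(b))
  expect_lt(abs(mean(b)), 3 * se + 1e-12)
})
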