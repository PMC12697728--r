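test_that("lopoFit is exact for perfect fits and matches an lm oracle", {
  set.seed(1)
  lv <- rnorm(10)
  # every participant equals the layer vector: perfect out-of-sample fit
  perfect <- matrix(rep(lv, 4), 4, byrow = TRUE)
  expect_equal(lopoFit(perfect, lv), rep(1, 4), tolerance = 1e-12)
  # small instance against an independent lm-based oracle
  sl <- matrix(rnorm(3 * 6), 3, 6)
  got <- lopoFit(sl, lv[1:6])
  for (p in 1:3) {
    avg <- colMeans(sl[-p, , drop = FALSE])
    fit <- lm(avg ~ x, data = data.frame(avg = avg, x = lv[1:6]))
    pred <- predict(fit, newdata = data.frame(x = lv[1:6]))
    h <- sl[p, ]
    oracle <- 1 - sum((h - pred)^2) / sum((h - mean(h))^2)
    expect_equal(got[p], unname(oracle), tolerance = 1e-10)
  }
  expect_error(lopoFit(sl[1:2, ], lv[1:6]), "at least 3")
})

test_that("out-of-sample R2 of an unrelated predictor is nonpositive on average", {
  set.seed(2)
  meanR2 <- replicate(500, {
    sl <- matrix(rnorm(5 * 120), 5, 120)
    mean(lopoFit(sl, rnorm(120)))
  })
  expect_lte(mean(meanR2), 0)
})

test_that("permutationNull is seeded and powers a large z on matched data", {
  set.seed(3)
  lv <- upperTriangle(orthogonalLayerRSMs(2, nImages = 16, seed = 3)[[1]])
  sl <- t(sapply(1:6, function(p) lv + rnorm(120, sd = 0.2)))
  n1 <- permutationNull(sl, lv, nPerm = 100, seed = 5)
  n2 <- permutationNull(sl, lv, nPerm = 100, seed = 5)
  expect_identical(n1, n2)
  lf <- layerFit(sl, lv, nPerm = 300, seed = 5)
  expect_gt(lf$mean_z, 3)
  expect_true(all(lf$z > 3))
  # null mean R2 nonpositive for unrelated data
  slNoise <- matrix(rnorm(5 * 120), 5, 120)
  expect_lte(mean(permutationNull(slNoise, lv, nPerm = 200, seed = 6)), 0.02)
})

test_that("permutation-null z is approximately standard normal under a true null", {
  zs <- vapply(1:200, function(s) {
    set.seed(s)
    sl <- matrix(rnorm(5 * 60), 5, 60)
    layerFit(sl, rnorm(60), nPerm = 500, seed = s)$mean_z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(sd(zs), 0.8)
  expect_lt(sd(zs), 1.2)
})

test_that("residualize residuals satisfy the normal-equation identity", {
  rsms <- orthogonalLayerRSMs(12, nImages = 16, seed = 7)
  tris <- sapply(rsms, upperTriangle)
  others <- scale(tris[, 1:11])
  set.seed(8)
  y <- rnorm(120)
  rz <- residualize(y, others)
  expect_lt(max(abs(crossprod(rz$X, rz$residuals))), 1e-8)
})

test_that("residualFit isolates unique variance and reduces to lopoFit without others", {
  rsms <- orthogonalLayerRSMs(12, nImages = 16, seed = 9)
  tris <- sapply(rsms, upperTriangle)
  target <- tris[, 12]; others <- tris[, 1:11]
  # searchlight fully explained by the other layers: residual fit ~ 0
  set.seed(10)
  sl <- t(sapply(1:6, function(p) others %*% rnorm(11, mean = 1, sd = 0.2)))
  expect_lt(max(abs(residualFit(sl, target, others))), 0.05)
  # searchlight carrying the target layer: residual fit is positive and
  # comparable to the plain LOPO fit (others orthogonal by construction)
  sl2 <- t(sapply(1:6, function(p) target + rnorm(120, sd = 0.15)))
  rf <- mean(residualFit(sl2, target, others))
  lp <- mean(lopoFit(sl2, target))
  expect_gt(rf, 0.2)
  expect_lt(abs(rf - lp), 0.2)
  # no other layers: identical to lopoFit on z-scored rows
  slZ <- t(apply(sl2, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(residualFit(sl2, target, NULL), lopoFit(slZ, target),
               tolerance = 1e-10)
  # collinear predictors are named
  bad <- cbind(others, dup = others[, 1])
  colnames(bad) <- c(colnames(others), "layer01_dup")
  expect_error(residualFit(sl2, target, bad), "layer01_dup")
})

test_that("zmapForLayer recovers a ground-truth region and handles empty masks", {
  fx <- makeTwoRegionSim(seed = 11)
  mask <- array(TRUE, dim = fx$grid)
  maps <- zmapForLayer(fx$sim$betamaps, fx$rsms[[1]], mask, halfWidth = 3,
                       nPerm = 150, seed = 11, centers = fx$centers)
  zmat <- do.call(rbind, lapply(maps, statValues))
  pos <- match(fx$centers, which(mask))
  gz <- colMeans(zmat[, pos])
  expect_gt(gz[1], gz[2])     # layer 1 lives in region 1
  expect_gt(gz[1], 3)
  # everything outside the evaluated centers stays undefined
  expect_true(all(is.na(zmat[, -pos])))
  # empty mask: empty maps with a warning
  expect_warning(
    empty <- zmapForLayer(fx$sim$betamaps, fx$rsms[[1]],
                          array(FALSE, dim = fx$grid)),
    "empty")
  expect_length(statValues(empty[[1]]), 0)
})

test_that("groupInference controls the degenerate cases and localizes signal", {
  zeros <- matrix(0, 6, 10)
  g0 <- groupInference(zeros, nSignFlips = 200, seed = 1)
  expect_false(any(g0$significant))
  fives <- matrix(5, 10, 4)
  g5 <- groupInference(fives, nSignFlips = 200, seed = 2)
  expect_true(all(g5$significant))
  expect_error(groupInference(matrix(0, 3, 4)), "at least 5")
  # signal in some centers only: significant set confined to them
  set.seed(3)
  correct <- replicate(5, {
    z <- matrix(rnorm(8 * 30), 8, 30)
    z[, 1:5] <- z[, 1:5] + 3
    g <- groupInference(z, nSignFlips = 300, seed = sample(1e6, 1))
    all(which(g$significant) %in% 1:5) && any(g$significant[1:5])
  })
  expect_gte(mean(correct), 0.8)
})

test_that("maxLayerMap labels by largest t with lowest-index ties", {
  gr <- list(
    layerA = list(t = c(2, 5, 1), significant = c(TRUE, TRUE, FALSE)),
    layerB = list(t = c(3, 5, 2), significant = c(TRUE, TRUE, FALSE)))
  lab <- maxLayerMap(gr)
  expect_equal(lab, c("layerB", "layerA", NA))   # tie at center 2 -> lowest index
})
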