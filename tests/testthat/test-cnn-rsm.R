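test_that("extractActivations honors the adapter contract on toy layers", {
  ad <- toyAdapter(c(4, 4, 3))
  set.seed(1)
  px <- array(runif(2 * 4 * 4 * 3), dim = c(2, 4, 4, 3))
  px[2, , , ] <- px[1, , , ]           # two identical images
  st <- stimulusSet(px)
  acts <- extractActivations(ad, st)
  expect_named(acts, c("identity", "negation"))
  expect_equal(acts$identity[1, ], acts$identity[2, ])   # determinism
  expect_equal(acts$identity[1, ], as.vector(px[1, , , ]))
  expect_equal(acts$negation[1, ], -as.vector(px[1, , , ]))
  expect_error(extractActivations(ad, st, layers = "nope"), "unknown layer")
  bad <- stimulusSet(array(runif(2 * 3 * 3 * 3), dim = c(2, 3, 3, 3)))
  expect_error(extractActivations(ad, bad), "shape mismatch")
})

test_that("computeRSM matches hand values and the brute-force Pearson oracle", {
  expect_equal(computeRSM(rbind(c(1, 2, 3), c(1, 2, 3)))@values[1, 2], 1)
  expect_equal(computeRSM(rbind(c(1, 2, 3), c(3, 2, 1)))@values[1, 2], -1)
  expect_equal(computeRSM(rbind(c(1, 0, 0), c(0, 1, 0)))@values[1, 2], -0.5)
  expect_error(computeRSM(rbind(c(1, 1, 1), c(0, 1, 0))), "degenerate")
  expect_error(computeRSM(matrix(1:4, 4, 1)), "at least 2 units")
  set.seed(7)
  for (rep in 1:5) {
    pat <- matrix(rnorm(6 * 11), 6, 11)
    expect_lt(max(abs(computeRSM(pat)@values - bruteForcePearsonRSM(pat))),
              1e-10)
  }
})

test_that("upperTriangle is row-major, sized n(n-1)/2, and invertible", {
  set.seed(2)
  r16 <- computeRSM(matrix(rnorm(16 * 40), 16, 40))
  expect_length(upperTriangle(r16), 120)
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  expect_equal(upperTriangle(m), c(0.1, 0.2, 0.3))
  # round-trip bijection
  v <- upperTriangle(r16)
  expect_equal(fromUpperTriangle(v, 16), r16@values, tolerance = 1e-12)
  expect_error(upperTriangle(diag(2)), "too small")
})

test_that("secondOrderMatrix correlates triangles and flags degeneracy", {
  set.seed(3)
  base <- computeRSM(matrix(rnorm(5 * 30), 5, 30), "a")
  same <- list(base, layerRSM(base@values, "b"), layerRSM(base@values, "c"))
  expect_true(all(abs(secondOrderMatrix(same)@values - 1) < 1e-12))
  # triangles that are exact negatives about their means
  t1 <- seq(0.05, 0.45, length.out = 10)
  a1 <- layerRSM(fromUpperTriangle(t1, 5), "p")
  a2 <- layerRSM(fromUpperTriangle(0.5 - t1, 5), "q")
  som2 <- secondOrderMatrix(list(a1, a2))
  expect_equal(som2@values[1, 2], -1, tolerance = 1e-10)
  # independent Pearson oracle on three random RSMs
  rsms <- lapply(1:3, function(i)
    computeRSM(matrix(rnorm(6 * 25), 6, 25), paste0("l", i)))
  S <- secondOrderMatrix(rsms)@values
  tri <- vapply(rsms, upperTriangle, numeric(15))
  oracle <- bruteForcePearsonRSM(t(tri))
  expect_lt(max(abs(S - oracle)), 1e-10)
  # constant triangle -> degenerate error
  flat <- layerRSM(matrix(0.5, 4, 4) + diag(0.5, 4), "flat")
  expect_error(secondOrderMatrix(list(base4 <- computeRSM(matrix(rnorm(16), 4, 4)), flat)),
               "degenerate")
})

test_that("orthogonalityCost sums squared off-diagonals and is permutation-invariant", {
  expect_equal(orthogonalityCost(diag(12)), 0)
  expect_equal(orthogonalityCost(matrix(1, 12, 12)), 132)
  r <- 0.37
  m2 <- matrix(c(1, r, r, 1), 2, 2)
  expect_equal(orthogonalityCost(m2), 2 * r^2)
  set.seed(4)
  rsms <- lapply(1:4, function(i)
    computeRSM(matrix(rnorm(5 * 20), 5, 20), paste0("l", i)))
  c1 <- orthogonalityCost(secondOrderMatrix(rsms))
  c2 <- orthogonalityCost(secondOrderMatrix(rsms[c(3, 1, 4, 2)]))
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("independent-pattern RSMs decorrelate as the image set grows", {
  # the second-order correlation of independent geometries concentrates
  # near zero at a rate set by the triangle length n(n-1)/2
  set.seed(5)
  meanAbs <- vapply(c(6, 12, 24), function(ni) {
    vals <- replicate(10, {
      rsms <- lapply(1:4, function(i)
        computeRSM(matrix(rnorm(ni * 100), ni, 100), paste0("l", i)))
      s <- secondOrderMatrix(rsms)@values
      mean(abs(s[row(s) != col(s)]))
    })
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(meanAbs) < 0))
  expect_lt(meanAbs[3], 0.1)
})

test_that("matrix CSV serialization round-trips to 15 significant digits", {
  set.seed(6)
  rsm <- computeRSM(matrix(rnorm(5 * 30), 5, 30))
  p <- file.path(tempdir(), "rsm.csv")
  writeMatrixCSV(rsm, p)
  back <- readMatrixCSV(p)
  expect_equal(signif(unname(back), 15), signif(rsm@values, 15))
  som <- secondOrderMatrix(lapply(1:3, function(i)
    computeRSM(matrix(rnorm(5 * 30), 5, 30), paste0("l", i))))
  p2 <- file.path(tempdir(), "som.csv")
  writeMatrixCSV(som, p2, ids = layerIds(som))
  expect_equal(rownames(readMatrixCSV(p2)), layerIds(som))
})
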