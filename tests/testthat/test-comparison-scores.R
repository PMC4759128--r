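# straight-line re-implementations used as oracles
bruteNumExcess <- function(mat) {
  r <- responseMatrix(mat); n <- 0L
  for (i in 2:nrow(r)) for (j in 2:ncol(r))
    if (r[i, j] > r[i, 1] && r[i, j] > r[1, j]) n <- n + 1L
  n
}
bruteExcessHSA <- function(mat) {
  r <- responseMatrix(mat); s <- 0
  for (i in 2:nrow(r)) for (j in 2:ncol(r))
    s <- s + (100 * (1 - r[i, j])) - (100 * (1 - max(r[i, 1], r[1, j])))
  s
}
bruteLs3x3 <- function(mat) {
  r <- responseMatrix(mat)
  ex <- matrix(NA_real_, nrow(r) - 1, ncol(r) - 1)
  for (i in 2:nrow(r)) for (j in 2:ncol(r))
    ex[i - 1, j - 1] <- 100 * (max(r[i, 1], r[1, j]) - r[i, j])
  best <- Inf
  for (i in 1:(nrow(ex) - 2)) for (j in 1:(ncol(ex) - 2))
    best <- min(best, sum(ex[i:(i + 2), j:(j + 2)]))
  best
}

test_that("excess counts and sums match exhaustive enumeration", {
  set.seed(31)
  for (k in 1:25) {
    mat <- randomResponseMatrix()
    expect_identical(numExcess(mat), bruteNumExcess(mat))
    expect_equal(excessHSA(mat), bruteExcessHSA(mat), tolerance = 1e-10)
    expect_equal(ls3x3(mat), bruteLs3x3(mat), tolerance = 1e-10)
  }
})

test_that("HSA-excess scores behave on constructed cases", {
  # combination wells exactly at the HSA expectation
  conc <- c(0, 1, 2, 4, 8, 16)
  y1 <- seq(0, 0.5, length.out = 6); y2 <- seq(0, 0.4, length.out = 6)
  resp <- outer(y1, y2, pmax)
  mat <- doseResponseMatrix(resp, conc, conc)
  expect_identical(numExcess(mat), 0L)
  expect_equal(excessHSA(mat), 0)
  expect_equal(medianExcess(mat), 0)
  expect_equal(ls3x3(mat), 0)
  # a single well 10 viability points below the HSA expectation
  resp2 <- resp; resp2[4, 4] <- resp2[4, 4] + 0.10
  mat2 <- doseResponseMatrix(resp2, conc, conc)
  expect_equal(excessHSA(mat2), -10)
  expect_identical(numExcess(mat2), 1L)
  # uniform per-well excess e sums to 9e in every 3x3 block
  resp3 <- resp + 0.02; resp3[, 1] <- resp[, 1]; resp3[1, ] <- resp[1, ]
  resp3[1, 1] <- 0
  mat3 <- doseResponseMatrix(resp3, conc, conc)
  expect_equal(ls3x3(mat3), 9 * (-2))
  # combination region smaller than 3x3
  small <- doseResponseMatrix(matrix(runif(9), 3, 3), c(0, 1, 2), c(0, 1, 2))
  expect_error(ls3x3(small), "3 x 3")
})

test_that("median excess uses the inhibition scale with synergy positive", {
  set.seed(32)
  mat <- randomResponseMatrix()
  r <- responseMatrix(mat)
  ex <- c()
  for (i in 2:nrow(r)) for (j in 2:ncol(r))
    ex <- c(ex, 100 * (r[i, j] - max(r[i, 1], r[1, j])))
  expect_equal(medianExcess(mat), median(ex))
})

test_that("beta and gamma match 1-D numeric least squares", {
  set.seed(33)
  for (k in 1:25) {
    mat <- randomResponseMatrix()
    r <- responseMatrix(mat)
    vc <- vb <- vh <- c()
    for (i in 2:nrow(r)) for (j in 2:ncol(r)) {
      vc <- c(vc, 1 - r[i, j])
      vb <- c(vb, (1 - r[i, 1]) * (1 - r[1, j]))
      vh <- c(vh, max(1 - r[i, 1], 1 - r[1, j]))
    }
    bOpt <- uniroot(function(b) -2 * sum((vc - b * vb) * vb),
                    c(-1e6, 1e6), tol = 1e-14)$root
    gOpt <- uniroot(function(g) -2 * sum((vc - g * vh) * vh),
                    c(-1e6, 1e6), tol = 1e-14)$root
    expect_equal(betaScore(mat), max(bOpt, 0), tolerance = 1e-10)
    expect_equal(gammaScore(mat), max(gOpt, 0), tolerance = 1e-10)
  }
})

test_that("beta and gamma hit their anchor values on constructed data", {
  # combination viability exactly Bliss-expected -> beta 1
  mat <- blissNullMatrix()
  expect_equal(betaScore(mat), 1, tolerance = 1e-12)
  # complete kill -> both 0
  conc <- c(0, 1, 2, 4)
  resp <- matrix(1, 4, 4)
  resp[, 1] <- c(0, 0.2, 0.3, 0.4); resp[1, ] <- c(0, 0.1, 0.2, 0.3)
  killed <- doseResponseMatrix(resp, conc, conc)
  expect_equal(betaScore(killed), 0)
  expect_equal(gammaScore(killed), 0)
  # combination viability exactly the hybrid expectation -> gamma 1
  r2 <- resp
  for (i in 2:4) for (j in 2:4)
    r2[i, j] <- 1 - max(1 - r2[i, 1], 1 - r2[1, j])
  expect_equal(gammaScore(doseResponseMatrix(r2, conc, conc)), 1,
               tolerance = 1e-12)
})

test_that("scores are invariant under drug relabeling", {
  set.seed(34)
  mat <- randomResponseMatrix()
  tmat <- transposeBlock(mat)
  expect_identical(numExcess(mat), numExcess(tmat))
  expect_equal(excessHSA(mat), excessHSA(tmat))
  expect_equal(medianExcess(mat), medianExcess(tmat))
  expect_equal(ls3x3(mat), ls3x3(tmat))
  expect_equal(betaScore(mat), betaScore(tmat))
  expect_equal(gammaScore(mat), gammaScore(tmat))
})

test_that("injecting extra inhibition moves every score toward synergy", {
  tr <- syntheticTruth("bliss-null", noiseSd = 0.02, seed = 8)
  mat <- generateSyntheticMatrix(tr)
  boosted <- responseMatrix(mat)
  boosted[-1, -1] <- boosted[-1, -1] + 0.15
  bmat <- doseResponseMatrix(boosted, concRow(mat), concCol(mat))
  expect_lt(excessHSA(bmat), excessHSA(mat))
  expect_lt(betaScore(bmat), betaScore(mat))
  expect_lt(gammaScore(bmat), gammaScore(mat))
  expect_gt(summaryDelta(deltaScore(bmat)), summaryDelta(deltaScore(mat)))
})

test_that("the score panel collects everything with status flags", {
  tr <- syntheticTruth("potency-shift", noiseSd = 0.02, seed = 3)
  mat <- generateSyntheticMatrix(tr)
  sp <- scorePanel(mat)
  df <- as.data.frame(sp)
  expect_identical(nrow(df), 1L)
  expect_true(is.na(df$excess_crx))
  expect_identical(unname(sp@status["excessCRX"]), "not-implemented")
  expect_equal(df$summary_delta, summaryDelta(deltaScore(mat)))
  expect_equal(df$beta, betaScore(mat))
  expect_identical(unname(sp@status["beta"]), "ok")
})
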