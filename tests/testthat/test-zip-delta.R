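test_that("the three zero-interaction formulations coincide", {
  # drug-1-centric baseline shift, drug-2-centric baseline shift, and the
  # multiplicative-survival factorization, written out independently
  set.seed(1)
  n <- 2000
  m1 <- 10^runif(n, -1, 1); lam1 <- runif(n, 0.3, 4)
  m2 <- 10^runif(n, -1, 1); lam2 <- runif(n, 0.3, 4)
  x1 <- 10^runif(n, -2, 2); x2 <- 10^runif(n, -2, 2)
  t1 <- (x1 / m1)^lam1; t2 <- (x2 / m2)^lam2
  y1 <- t1 / (1 + t1); y2 <- t2 / (1 + t2)
  via12 <- (y2 + t1) / (1 + t1)
  via21 <- (y1 + t2) / (1 + t2)
  factored <- y1 + y2 - y1 * y2
  expect_equal(via12, via21, tolerance = 1e-12)
  expect_equal(via12, factored, tolerance = 1e-12)
})

test_that("zipExpected is symmetric and inert at dose zero", {
  set.seed(2)
  for (k in 1:20) {
    f1 <- randomFit(); f2 <- randomFit()
    x1 <- 10^runif(1, -1, 1); x2 <- 10^runif(1, -1, 1)
    expect_equal(zipExpected(f1, f2, x1, x2), zipExpected(f2, f1, x2, x1))
    expect_equal(zipExpected(f1, f2, 0, x2), evaluateLogistic(f2, x2))
    expect_equal(zipExpected(f1, f2, x1, 0), evaluateLogistic(f1, x1))
  }
})

test_that("conditional fits recover the generating curves on null data", {
  mat <- blissNullMatrix(m1 = 1, lam1 = 1.5, m2 = 2, lam2 = 1)
  fits <- fitConditionalCurves(mat)
  for (cf in fits$condRow) {  # row drug's curve at each partner dose
    expect_true(isConverged(cf))
    expect_equal(potency(cf), 1, tolerance = 1e-3)
    expect_equal(shape(cf), 1.5, tolerance = 1e-3)
  }
  for (cf in fits$condCol) {
    expect_equal(potency(cf), 2, tolerance = 1e-3)
    expect_equal(shape(cf), 1, tolerance = 1e-3)
  }
})

test_that("a sham combination shifts the conditional potency by the partner dose", {
  # for unit slope, f(x1 + x2) rewritten as a curve in x1 has midpoint m + x2
  m <- 1
  conc <- halfLogDoses(1)
  f <- logisticFit(m = m, lambda = 1)
  for (x2 in c(0.25, 0.5, 2)) {
    y <- evaluateLogistic(f, conc + x2)
    cf <- fitLogistic(conc, y, eMinFixed = evaluateLogistic(f, x2),
                      eMaxFixed = 1)
    expect_equal(potency(cf), m + x2, tolerance = 1e-3)
    expect_equal(shape(cf), 1, tolerance = 1e-3)
  }
})

test_that("a flat combination series stays at its baseline", {
  conc <- halfLogDoses(1)
  b <- 0.4
  cf <- fitLogistic(conc, rep(b, length(conc)), eMinFixed = b, eMaxFixed = 1)
  expect_lt(max(abs(evaluateLogistic(cf, conc) - b)), 0.005)
})

test_that("delta vanishes on the zero-interaction surface", {
  mat <- blissNullMatrix()
  land <- deltaScore(mat)
  expect_identical(land@nWells, 25L)
  expect_identical(dim(deltaGrid(land)), c(5L, 5L))
  expect_lt(max(abs(deltaGrid(land))), 1e-4)
  expect_lt(abs(summaryDelta(land)), 1e-4)
})

test_that("delta landscapes are invariant under drug relabeling", {
  tr <- syntheticTruth("potency-shift", noiseSd = 0.03, seed = 5)
  mat <- generateSyntheticMatrix(tr)
  a <- deltaScore(mat)
  b <- deltaScore(transposeBlock(mat))
  expect_equal(summaryDelta(a), summaryDelta(b), tolerance = 1e-6)
  expect_equal(unname(deltaGrid(b)), unname(t(deltaGrid(a))), tolerance = 1e-6)
})

test_that("injected potency shifts move delta monotonically", {
  baseFit <- baseTrue <- NULL
  for (shift in c(1, 0.8, 0.6, 0.4)) {
    tr <- syntheticTruth("potency-shift", potencyShift = shift, noiseSd = 0)
    land <- deltaScore(generateSyntheticMatrix(tr))
    dTrue <- trueDeltaSurface(tr)
    if (!is.null(baseFit)) {
      # the generating surface is strictly monotone in the shift; the
      # fitted pipeline tracks it within its projection tolerance
      expect_true(all(dTrue > baseTrue))
      expect_true(all(deltaGrid(land) > baseFit - 1e-3))
    }
    baseFit <- deltaGrid(land); baseTrue <- dTrue
  }
})

test_that("summaryDelta averages the grid and reports percent", {
  tr <- syntheticTruth("potency-shift", noiseSd = 0)
  land <- deltaScore(generateSyntheticMatrix(tr))
  expect_equal(summaryDelta(land), mean(deltaGrid(land)))
  expect_equal(summaryDelta(land, percent = TRUE), 100 * summaryDelta(land))
})

test_that("matrices without enough doses are rejected", {
  m <- doseResponseMatrix(matrix(c(0, 0.2, 0.3, 0.6), 2, 2),
                          c(0, 1), c(0, 1))
  expect_error(deltaScore(m), "nonzero doses")
  expect_error(doseResponseMatrix(matrix(0, 2, 2), c(1, 2), c(0, 1)),
               "zero dose")
})
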