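test_that("HSA and Bliss expectations follow their defining formulas", {
  expect_equal(hsaExpected(0.3, 0.4), 0.4)
  expect_equal(hsaExpected(0.5, 0.5), 0.5)
  expect_equal(hsaExpected(0, 0), 0)
  expect_equal(blissExpected(0.3, 0.4), 0.58)
  expect_equal(blissExpected(0, 0.7), 0.7)
  expect_equal(blissExpected(1, 0.4), 1)
  expect_error(blissExpected(1.2, 0.4, strict = TRUE), "\\[0, 1\\]")
  # Bliss dominates HSA on the unit square (up to fp rounding)
  g <- seq(0, 1, by = 0.05)
  for (a in g)
    expect_true(all(blissExpected(a, g) >= hsaExpected(a, g) - 1e-12))
})

test_that("Loewe solver matches the sham closed form and the single-drug limit", {
  f <- logisticFit(m = 1.5, lambda = 2)
  for (x1 in c(0.2, 0.7, 1.5, 4)) {
    for (x2 in c(0.1, 1, 3)) {
      r <- loeweExpected(f, f, x1, x2)
      expect_identical(r$status, "ok")
      expect_equal(r$yLoewe, evaluateLogistic(f, x1 + x2), tolerance = 1e-6)
    }
  }
  g <- logisticFit(m = 3, lambda = 1)
  expect_equal(loeweExpected(f, g, 2, 0)$yLoewe, evaluateLogistic(f, 2))
  expect_equal(loeweExpected(f, g, 0, 2)$yLoewe, evaluateLogistic(g, 2))
})

test_that("Loewe solver agrees with a dense grid search", {
  set.seed(5)
  for (k in 1:10) {
    f1 <- randomFit(); f2 <- randomFit()
    x1 <- 10^runif(1, -1, 1); x2 <- 10^runif(1, -1, 1)
    r <- loeweExpected(f1, f2, x1, x2)
    lo <- max(eMin(f1), eMin(f2)); hi <- min(eMax(f1), eMax(f2))
    ys <- seq(lo + 1e-9, hi - 1e-9, length.out = 1e5)
    g <- x1 / inverseLogistic(f1, ys, strict = FALSE) +
      x2 / inverseLogistic(f2, ys, strict = FALSE) - 1
    if (r$status == "ok") {
      yGrid <- ys[which.min(abs(g))]
      expect_lt(abs(r$yLoewe - yGrid), (hi - lo) * 1e-4)
    } else {
      expect_true(all(g > 0))  # no root anywhere in the band
    }
  }
})

test_that("weak single agents make the Loewe expectation unreachable", {
  f1 <- logisticFit(eMax = 0.4, m = 1, lambda = 1)
  f2 <- logisticFit(eMax = 0.5, m = 1, lambda = 1)
  r <- loeweExpected(f1, f2, 100, 100)  # combination demands > 0.4
  expect_identical(r$status, "unreachable")
  expect_true(is.na(r$yLoewe))
  expect_true(is.na(combinationIndex(f1, f2, 1, 1, yc = 0.6)))
  expect_true(is.na(interactionAlpha(f1, f2, 1, 1, yc = 0.6)))
})

test_that("CI is 1 and alpha 0 at the additive point", {
  set.seed(9)
  for (k in 1:10) {
    f1 <- randomFit(); f2 <- randomFit()
    x1 <- 10^runif(1, -0.5, 0.5); x2 <- 10^runif(1, -0.5, 0.5)
    r <- loeweExpected(f1, f2, x1, x2)
    if (r$status != "ok") next
    expect_equal(combinationIndex(f1, f2, x1, x2, r$yLoewe), 1,
                 tolerance = 1e-6)
    expect_equal(interactionAlpha(f1, f2, x1, x2, r$yLoewe), 0,
                 tolerance = 1e-5)
  }
  sham <- logisticFit(m = 1, lambda = 1)
  expect_equal(combinationIndex(sham, sham, 0.5, 0.5, yc = 0.5), 1)
  expect_equal(interactionAlpha(sham, sham, 1, 1, yc = 0.75), 1)
})

test_that("CI and alpha agree in sign whenever both are defined", {
  set.seed(13)
  sgn <- 0L
  for (k in 1:40) {
    f1 <- randomFit(); f2 <- randomFit()
    x1 <- 10^runif(1, -1, 1); x2 <- 10^runif(1, -1, 1)
    yc <- runif(1, 0.05, 0.95)
    ci <- combinationIndex(f1, f2, x1, x2, yc)
    al <- interactionAlpha(f1, f2, x1, x2, yc)
    if (is.na(ci) || is.na(al)) next
    expect_equal(sign(1 - ci), sign(al))
    sgn <- sgn + 1L
  }
  expect_gt(sgn, 10)  # the loop exercised real cases
})

test_that("expected effects are symmetric under drug swap", {
  set.seed(17)
  for (k in 1:20) {
    f1 <- randomFit(); f2 <- randomFit()
    x1 <- 10^runif(1, -1, 1); x2 <- 10^runif(1, -1, 1)
    y1 <- evaluateLogistic(f1, x1); y2 <- evaluateLogistic(f2, x2)
    expect_identical(hsaExpected(y1, y2), hsaExpected(y2, y1))
    expect_equal(blissExpected(y1, y2), blissExpected(y2, y1))
    a <- loeweExpected(f1, f2, x1, x2); b <- loeweExpected(f2, f1, x2, x1)
    expect_identical(a$status, b$status)
    if (a$status == "ok") expect_equal(a$yLoewe, b$yLoewe, tolerance = 1e-8)
  }
})
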