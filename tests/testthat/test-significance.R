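test_that("the normal-approximation interval follows its formula", {
  expect_equal(deltaConfidenceInterval(rep(0.3, 50)), c(0.3, 0.3))
  # symmetric two-point sample: centered at 0, half-width z * sd / sqrt(2)
  ci <- deltaConfidenceInterval(c(-1, 1))
  expect_equal(mean(ci), 0)
  expect_equal(ci[2], 1.959964 * sqrt(2 / 2), tolerance = 1e-4)
  # n = 1 treats the spread as the standard error itself
  set.seed(40)
  s <- rnorm(500, 0, 0.1)
  ci1 <- deltaConfidenceInterval(s, n = 1)
  expect_equal(ci1[2] - ci1[1], 2 * 1.959964 * sd(s), tolerance = 1e-4)
  expect_error(deltaConfidenceInterval(0.5), "2 samples")
})

test_that("bootstrap draws are deterministic and degenerate without noise", {
  tr <- syntheticTruth("potency-shift", noiseSd = 0)
  mat <- generateSyntheticMatrix(tr)
  b1 <- bootstrapDelta(mat, well = c(3, 3), nBoot = 150, seed = 11)
  b2 <- bootstrapDelta(mat, well = c(3, 3), nBoot = 150, seed = 11)
  expect_identical(b1@samples, b2@samples)
  # noiseless fits have zero residual variance: all draws collapse to the
  # point estimate and the interval has zero width (up to fp jitter)
  expect_lt(diff(range(b1@samples)), 1e-6)
  expect_lt(b1@ciHigh - b1@ciLow, 1e-5)
  # strong noiseless synergy: every draw is positive
  expect_gt(b1@deltaHat, 0.05)
  expect_equal(b1@pSynergy, 1.0)
})

test_that("bootstrap proportions partition exactly", {
  tr <- syntheticTruth("bliss-null", noiseSd = 0.05, seed = 14)
  mat <- generateSyntheticMatrix(tr)
  b <- bootstrapDelta(mat, well = c(2, 4), nBoot = 300, seed = 2)
  expect_identical(b@pSynergy + b@pAntagonism + b@pTies, 1)
  expect_equal(b@pSynergy, sum(b@samples > 0) / 300)
  expect_identical(length(b@samples), 300L)
})

test_that("p(synergy) is monotone in the injected synergy on matched seeds", {
  ps <- sapply(c(1, 0.7, 0.45, 0.25), function(shift) {
    tr <- syntheticTruth("potency-shift", potencyShift = shift,
                         noiseSd = 0.05, seed = 77)
    mat <- generateSyntheticMatrix(tr)
    bootstrapDelta(mat, well = c(3, 3), nBoot = 300, seed = 42)@pSynergy
  })
  expect_true(all(diff(ps) >= 0))
})

test_that("bootstrapping refuses matrices whose fits fell back", {
  conc <- c(0, 1, 2, 4, 8, 16)
  resp <- matrix(runif(36, 0, 0.05), 6, 6)
  resp[, 1] <- c(0.9, 0.75, 0.6, 0.45, 0.3, 0.15)  # inverted monotherapy
  resp[1, 1] <- 0.9
  mat <- doseResponseMatrix(resp, conc, conc)
  expect_error(bootstrapDelta(mat, well = c(2, 2), nBoot = 100, seed = 1),
               class = "zipscore_fit_failure")
})

test_that("monotherapy variance pools the anchor drug across blocks", {
  conc <- c(0, 1, 2, 4, 8, 16)
  mk <- function(monoRow, id) {
    resp <- matrix(0.5, 6, 6)
    resp[, 1] <- monoRow; resp[1, ] <- seq(0, 0.5, length.out = 6)
    resp[1, 1] <- monoRow[1]
    doseResponseMatrix(resp, conc, conc, drugRow = "anchor",
                       drugCol = paste0("partner", id), blockId = id)
  }
  y <- seq(0, 0.5, length.out = 6)
  # identical monotherapy rows -> zero variance everywhere
  v0 <- monotherapyVariance(list(mk(y, "a"), mk(y, "b")), "anchor")
  expect_equal(v0$variance, rep(0, 6))
  # a 0.2 offset -> sample variance 0.02 at every concentration
  v1 <- monotherapyVariance(list(mk(y, "a"), mk(y + 0.2, "b")), "anchor")
  expect_equal(v1$variance, rep(0.02, 6))
  expect_false(any(v1$flagged))
  # a concentration present in a single block is flagged with NA variance
  short <- mk(y, "c")
  long <- doseResponseMatrix(rbind(short@response, 0.6),
                             c(conc, 32), conc, drugRow = "anchor",
                             drugCol = "partnerd", blockId = "d")
  v2 <- monotherapyVariance(list(short, long), "anchor")
  expect_true(v2$flagged[v2$conc == 32])
  expect_true(is.na(v2$variance[v2$conc == 32]))
  expect_error(monotherapyVariance(list(short), "anchor"), "fewer than 2")
})

test_that("matrix resampling is consistent and degenerates at zero variance", {
  tr <- syntheticTruth("bliss-null", noiseSd = 0.03, seed = 6)
  mat <- generateSyntheticMatrix(tr)
  sig0 <- data.frame(conc = concRow(mat), variance = 0)
  r0 <- resampleMatrixDelta(mat, sig0, nSim = 50, seed = 9)
  expect_true(all(r0$samples == r0$pointDelta))
  sig <- data.frame(conc = concRow(mat), variance = 1e-4)
  r1 <- resampleMatrixDelta(mat, sig, nSim = 60, seed = 9)
  r2 <- resampleMatrixDelta(mat, sig, nSim = 60, seed = 9)
  expect_identical(r1$samples, r2$samples)
  # small-noise Monte-Carlo mean stays within 2 standard errors of the point
  se <- sd(r1$samples) / sqrt(length(r1$samples))
  expect_lt(abs(mean(r1$samples) - r1$pointDelta), max(2 * se, 5e-3))
  expect_error(resampleMatrixDelta(mat, data.frame(conc = 1, variance = 0),
                                   nSim = 5, seed = 1), "missing")
})
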