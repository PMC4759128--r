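# shared fixture builders; everything is generated in code at test time

halfLogDoses <- function(center = 1) c(0, center * 10^seq(-1, 1, by = 0.5))

# random valid logistic fit (for property loops); rng state comes from the
# caller's set.seed
randomFit <- function() {
  logisticFit(eMin = 0, eMax = runif(1, 0.3, 1),
              m = 10^runif(1, -1, 1), lambda = runif(1, 0.3, 4))
}

# a noiseless matrix whose combination wells sit exactly on the
# zero-interaction (Bliss) surface of its own monotherapy curves
blissNullMatrix <- function(m1 = 1, lam1 = 1.5, m2 = 2, lam2 = 1,
                            concRow = halfLogDoses(m1),
                            concCol = halfLogDoses(m2)) {
  f1 <- logisticFit(m = m1, lambda = lam1)
  f2 <- logisticFit(m = m2, lambda = lam2)
  y1 <- evaluateLogistic(f1, concRow)
  y2 <- evaluateLogistic(f2, concCol)
  resp <- outer(y1, y2, function(a, b) a + b - a * b)
  doseResponseMatrix(resp, concRow, concCol, blockId = "bliss-null")
}

# arbitrary random response matrix (not from any model) for brute-force
# score oracles
randomResponseMatrix <- function(nr = 6, nc = 6) {
  cr <- c(0, sort(10^runif(nr - 1, -1, 1)))
  cc <- c(0, sort(10^runif(nc - 1, -1, 1)))
  resp <- matrix(runif(nr * nc, -0.05, 1.05), nr, nc)
  resp[1, 1] <- 0
  doseResponseMatrix(resp, cr, cc, blockId = "random")
}
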