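#' @include comparison-scores.R
NULL

#' Normal-approximation confidence interval for delta
#'
#' The interval `mean(samples) +/- z[1 - alpha/2] * sqrt(var(samples)/n)`.
#' Following the printed bootstrap recipe, `n` defaults to the number of
#' samples; pass `n = 1` to treat the sample spread itself as the standard
#' error of the estimate (the convention [bootstrapDelta()] uses for its
#' reported interval, since the bootstrap spread already estimates the
#' sampling variability of the point estimate).
#'
#' @param samples numeric vector of (bootstrap) delta values, length >= 2.
#' @param alphaLevel type-I error level; 0.05 gives a 95\% interval.
#' @param n divisor of the variance in the standard-error term.
#' @return numeric vector `c(low, high)`.
#' @examples
#' deltaConfidenceInterval(rnorm(1000, 0.1, 0.02), n = 1)
#' @export
deltaConfidenceInterval <- function(samples, alphaLevel = 0.05,
                                    n = length(samples)) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop("need at least 2 samples")
  stopifnot(alphaLevel > 0, alphaLevel < 1, n >= 1)
  z <- stats::qnorm(1 - alphaLevel / 2)
  mu <- mean(samples)
  hw <- z * sqrt(stats::var(samples) / n)
  c(mu - hw, mu + hw)
}

# Draw nBoot parameter vectors for one fit from independent normals at the
# estimated values/standard errors; fixed parameters stay put. Positive
# parameters are floored just above 0, eMax capped at 1.
.drawFitParams <- function(fit, nBoot) {
  se <- fit@se
  draw <- function(nm, est, lo = NULL, hi = NULL) {
    s <- if (nm %in% names(se) && is.finite(se[[nm]])) se[[nm]] else 0
    v <- stats::rnorm(nBoot, est, s)
    if (!is.null(lo)) v <- pmax(v, lo)
    if (!is.null(hi)) v <- pmin(v, hi)
    v
  }
  list(eMax = draw("eMax", fit@eMax, lo = 1e-6, hi = 1),
       m = draw("m", fit@m, lo = 1e-8),
       lambda = draw("lambda", fit@lambda, lo = 1e-3))
}

#' Parametric bootstrap for the delta score at one combination well
#'
#' Estimates the statistical uncertainty of the delta score by resampling
#' the fitted curve parameters: the monotherapy and conditional fits
#' touching the well are estimated from the matrix together with their
#' standard errors, `nBoot` parameter sets are drawn from independent
#' normal distributions at those means and standard deviations, and the
#' closed-form delta is re-evaluated per draw. The reported `pSynergy` is
#' the proportion of draws with delta > 0; a conventional two-sided
#' p-value `2*min(pSynergy, pAntagonism)` is also carried because the
#' support proportion is not a classical p-value.
#'
#' The confidence bounds are `deltaHat +/- z * sqrt(var(samples) /
#' ciDenominator)`; see [deltaConfidenceInterval()] for the choice of
#' denominator.
#'
#' @param mat a [DoseResponseMatrix-class].
#' @param well integer pair `(i, j)`: indices of the well within the
#'   combination region (1 = first nonzero dose of each drug).
#' @param nBoot number of bootstrap draws (>= 100).
#' @param seed integer RNG seed; the same seed reproduces the draws
#'   bit-identically.
#' @param alphaLevel type-I error level of the interval.
#' @param ciDenominator the `n` of the interval formula (default 1).
#' @param landscape optional precomputed [deltaScore()] result.
#' @return a [BootstrapResult-class].
#' @examples
#' tr <- syntheticTruth("potency-shift", noiseSd = 0.03)
#' mat <- generateSyntheticMatrix(tr)
#' bootstrapDelta(mat, well = c(3, 3), nBoot = 200, seed = 7)
#' @export
bootstrapDelta <- function(mat, well = c(1L, 1L), nBoot = 1000L, seed = 1L,
                           alphaLevel = 0.05, ciDenominator = 1,
                           landscape = NULL) {
  stopifnot(is(mat, "DoseResponseMatrix"), length(well) == 2L, nBoot >= 100)
  if (is.null(landscape)) landscape <- deltaScore(mat)
  i <- as.integer(well[1]); j <- as.integer(well[2])
  cr <- landscape@concRow; cc <- landscape@concCol
  if (i < 1L || i > length(cr) || j < 1L || j > length(cc))
    stop("well indices outside the combination region")
  x1 <- cr[i]; x2 <- cc[j]
  fitR <- landscape@fitRow; fitC <- landscape@fitCol
  condR <- landscape@condRow[[j]]  # row drug at this column dose
  condC <- landscape@condCol[[i]]
  fits <- list(fitR, fitC, condR, condC)
  if (any(!vapply(fits, function(f) f@converged, logical(1))))
    stop(structure(
      class = c("zipscore_fit_failure", "error", "condition"),
      list(message = "cannot bootstrap: a contributing curve fit did not converge",
           call = sys.call(-1))))

  deltaHat <- landscape@delta[i, j]
  set.seed(seed)
  dR <- .drawFitParams(fitR, nBoot)
  dC <- .drawFitParams(fitC, nBoot)
  dcR <- .drawFitParams(condR, nBoot)
  dcC <- .drawFitParams(condC, nBoot)
  samples <- .deltaTheta(x1, x2,
                         mR = dR$m, lamR = dR$lambda,
                         mC = dC$m, lamC = dC$lambda,
                         mCondR = dcR$m, lamCondR = dcR$lambda,
                         mCondC = dcC$m, lamCondC = dcC$lambda,
                         eMaxR = dR$eMax, eMaxC = dC$eMax)
  pS <- sum(samples > 0) / nBoot
  pA <- sum(samples < 0) / nBoot
  pT <- sum(samples == 0) / nBoot
  z <- stats::qnorm(1 - alphaLevel / 2)
  hw <- z * sqrt(stats::var(samples) / ciDenominator)
  if (!is.finite(hw)) hw <- 0
  new("BootstrapResult",
      deltaHat = deltaHat, samples = as.numeric(samples),
      pSynergy = pS, pAntagonism = pA, pTies = pT,
      pTwoSided = min(1, 2 * min(pS, pA)),
      ciLow = deltaHat - hw, ciHigh = deltaHat + hw,
      alphaLevel = alphaLevel, nBoot = as.integer(nBoot),
      seed = as.integer(seed), well = c(i, j))
}

#' Per-concentration variance of an anchor drug's monotherapy response
#'
#' Collects the monotherapy responses of a drug shared across several
#' combination blocks (e.g. the anchor compound of a one-vs-many screen)
#' and returns the sample variance at each of its concentrations. This is
#' the noise model used by [resampleMatrixDelta()] when true replicates
#' are unavailable. Concentrations observed in fewer than two blocks are
#' flagged and carry `NA` variance.
#'
#' @param mats list of [DoseResponseMatrix-class] objects.
#' @param anchor drug name to collect (matched against `drugRow` and
#'   `drugCol` of each block).
#' @return data frame with columns `conc`, `variance`, `n`, `flagged`.
#' @export
monotherapyVariance <- function(mats, anchor) {
  stopifnot(is.list(mats), length(mats) >= 1L, is.character(anchor))
  vals <- list()
  found <- 0L
  for (m in mats) {
    stopifnot(is(m, "DoseResponseMatrix"))
    if (m@drugRow == anchor) {
      conc <- m@concRow; y <- m@response[, 1]
    } else if (m@drugCol == anchor) {
      conc <- m@concCol; y <- m@response[1, ]
    } else next
    found <- found + 1L
    key <- format(conc, digits = 12, trim = TRUE)
    for (k in seq_along(conc)) vals[[key[k]]] <- c(vals[[key[k]]], y[k])
  }
  if (found < 2L)
    stop(sprintf("anchor drug '%s' present in fewer than 2 blocks", anchor))
  conc <- as.numeric(names(vals))
  n <- vapply(vals, length, integer(1))
  variance <- vapply(vals, function(v)
    if (length(v) >= 2L) stats::var(v) else NA_real_, numeric(1))
  out <- data.frame(conc = conc, variance = variance, n = n,
                    flagged = n < 2L, row.names = NULL)
  out[order(out$conc), , drop = FALSE]
}

#' Matrix resampling distribution of the summary delta
#'
#' Propagates measurement noise into the summary delta score when no
#' replicates exist: every well is redrawn from a normal distribution
#' centered at its observed response with the variance estimated for the
#' anchor drug at that well's anchor concentration (see
#' [monotherapyVariance()]), and the full delta pipeline is recomputed per
#' draw. With all variances zero every draw reproduces the point estimate.
#'
#' @param mat a [DoseResponseMatrix-class].
#' @param sigmaByConc data frame as returned by [monotherapyVariance()]
#'   (columns `conc`, `variance`), covering every anchor concentration of
#'   `mat`.
#' @param nSim number of simulated matrices.
#' @param seed integer RNG seed.
#' @param anchor `"row"` or `"col"`: which axis of `mat` carries the
#'   anchor drug.
#' @return list with elements `pointDelta`, `samples` (numeric of length
#'   `nSim`), `nFlagged` (draws containing any fit fallback), `seed`.
#' @export
resampleMatrixDelta <- function(mat, sigmaByConc, nSim = 1000L, seed = 1L,
                                anchor = c("row", "col")) {
  stopifnot(is(mat, "DoseResponseMatrix"), is.data.frame(sigmaByConc),
            all(c("conc", "variance") %in% names(sigmaByConc)), nSim >= 1)
  anchor <- match.arg(anchor)
  conc <- if (anchor == "row") mat@concRow else mat@concCol
  idx <- match(format(conc, digits = 12, trim = TRUE),
               format(sigmaByConc$conc, digits = 12, trim = TRUE))
  if (any(is.na(idx)) || any(is.na(sigmaByConc$variance[idx])))
    stop("variance missing for at least one anchor concentration")
  sd_i <- sqrt(sigmaByConc$variance[idx])
  sdMat <- if (anchor == "row")
    matrix(sd_i, nrow(mat@response), ncol(mat@response))
  else
    matrix(sd_i, nrow(mat@response), ncol(mat@response), byrow = TRUE)

  point <- summaryDelta(deltaScore(mat))
  if (all(sd_i == 0))  # degenerate: every draw is the observed matrix
    return(list(pointDelta = point, samples = rep(point, nSim),
                nFlagged = 0L, seed = as.integer(seed)))

  set.seed(seed)
  samples <- numeric(nSim)
  nFlagged <- 0L
  for (s in seq_len(nSim)) {
    pert <- mat@response + matrix(stats::rnorm(length(sdMat), 0, sdMat),
                                  nrow(sdMat), ncol(sdMat))
    pmat <- doseResponseMatrix(pert, mat@concRow, mat@concCol,
                               mat@drugRow, mat@drugCol,
                               mat@unitRow, mat@unitCol, mat@blockId)
    land <- deltaScore(pmat)
    samples[s] <- summaryDelta(land)
    if (any(land@flags)) nFlagged <- nFlagged + 1L
  }
  list(pointDelta = point, samples = samples, nFlagged = nFlagged,
       seed = as.integer(seed))
}
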