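#' @include reference-models.R
NULL

#' Zero-interaction-potency expected effect
#'
#' The expected combination effect when neither drug shifts the potency of
#' the other's dose-response curve: adding a non-interacting partner only
#' lifts the baseline. For curves with baseline 0 and maximum 1 this
#' baseline-shift construction factorizes exactly into the multiplicative
#' survival form `y1 + y2 - y1*y2`, i.e. probabilistic independence, and is
#' invariant under the order in which the drugs are added.
#'
#' @param fit1,fit2 monotherapy [LogisticFit-class] objects.
#' @param x1,x2 combination doses (>= 0), vectorized.
#' @return expected fractional inhibition.
#' @examples
#' f1 <- logisticFit(m = 1, lambda = 1.5); f2 <- logisticFit(m = 2, lambda = 1)
#' zipExpected(f1, f2, 1, 2)
#' @export
zipExpected <- function(fit1, fit2, x1, x2) {
  stopifnot(is(fit1, "LogisticFit"), is(fit2, "LogisticFit"),
            is.numeric(x1), is.numeric(x2), all(x1 >= 0), all(x2 >= 0))
  y1 <- evaluateLogistic(fit1, x1)
  y2 <- evaluateLogistic(fit2, x2)
  y1 + y2 - y1 * y2
}

#' Fit conditional combination curves along both axes of a matrix
#'
#' For every nonzero dose of the partner drug, fits the other drug's
#' combination responses along that row or column with the baseline pinned
#' to the fitted partner monotherapy effect and the maximum at 1 (see
#' [ConditionalFit-class]); only the conditional potency and slope are
#' estimated. The zero-dose well of each series participates in the fit.
#' A series that cannot be fitted yields a fallback-flagged fit; the matrix
#' is never aborted.
#'
#' @param mat a [DoseResponseMatrix-class].
#' @param fitRow,fitCol monotherapy fits for the row and column drug; when
#'   omitted they are fitted from the matrix margins with [fitLogistic()]
#'   defaults.
#' @return list with elements `condRow` (row-drug curves, one
#'   [ConditionalFit-class] per nonzero column dose) and `condCol`
#'   (column-drug curves, one per nonzero row dose).
#' @export
fitConditionalCurves <- function(mat, fitRow = NULL, fitCol = NULL) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  cr <- mat@concRow; cc <- mat@concCol
  resp <- mat@response
  if (is.null(fitRow)) fitRow <- fitLogistic(cr, resp[, 1])
  if (is.null(fitCol)) fitCol <- fitLogistic(cc, resp[1, ])

  fitOne <- function(doses, responses, bl, partnerDose) {
    bl <- min(max(bl, 0), 1 - 1e-6)
    f <- fitLogistic(doses, responses, eMinFixed = bl, eMaxFixed = 1)
    new("ConditionalFit", f, fixedPartnerDose = as.numeric(partnerDose))
  }
  condRow <- lapply(seq_along(cc)[-1], function(j) {
    fitOne(cr, resp[, j], evaluateLogistic(fitCol, cc[j]), cc[j])
  })
  condCol <- lapply(seq_along(cr)[-1], function(i) {
    fitOne(cc, resp[i, ], evaluateLogistic(fitRow, cr[i]), cr[i])
  })
  names(condRow) <- format(cc[-1], trim = TRUE)
  names(condCol) <- format(cr[-1], trim = TRUE)
  list(condRow = condRow, condCol = condCol, fitRow = fitRow, fitCol = fitCol)
}

#' Delta interaction landscape of a dose-response matrix
#'
#' Runs the full potency-shift scoring pipeline on one combination block:
#' fits both monotherapy curves, fits the conditional combination curves
#' along both axes, and for every combination well evaluates the delta
#' score — the average deviation of the two fitted conditional responses
#' from the zero-interaction expectation,
#' \deqn{\delta = \tfrac12\left[(\hat y_c^{r} - y_{ZIP}) +
#'       (\hat y_c^{c} - y_{ZIP})\right].}
#' `delta > 0` marks synergy, `delta < 0` antagonism, and 0 zero
#' interaction, in units of fractional inhibition. Wells whose contributing
#' fits fell back to interpolation are flagged, never dropped.
#'
#' @param mat a [DoseResponseMatrix-class] with at least two nonzero doses
#'   per drug (three points per conditional fit, counting the pinned
#'   baseline).
#' @return an [InteractionLandscape-class].
#' @examples
#' tr <- syntheticTruth("bliss-null", noiseSd = 0)
#' land <- deltaScore(generateSyntheticMatrix(tr))
#' summaryDelta(land)
#' @export
deltaScore <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  cr <- mat@concRow; cc <- mat@concCol
  if (length(cr) < 3L || length(cc) < 3L)
    stop("delta scoring needs at least 2 nonzero doses per drug")
  fits <- fitConditionalCurves(mat)
  fitRow <- fits$fitRow; fitCol <- fits$fitCol
  nR <- length(cr) - 1L; nC <- length(cc) - 1L
  delta <- matrix(NA_real_, nR, nC)
  flags <- matrix(FALSE, nR, nC)
  for (i in seq_len(nR)) {
    for (j in seq_len(nC)) {
      x1 <- cr[i + 1L]; x2 <- cc[j + 1L]
      ycR <- evaluateLogistic(fits$condRow[[j]], x1)
      ycC <- evaluateLogistic(fits$condCol[[i]], x2)
      delta[i, j] <- 0.5 * (ycR + ycC) - zipExpected(fitRow, fitCol, x1, x2)
      flags[i, j] <- !fits$condRow[[j]]@converged || !fits$condCol[[i]]@converged ||
        !fitRow@converged || !fitCol@converged
    }
  }
  new("InteractionLandscape",
      delta = delta, flags = flags,
      concRow = cr[-1], concCol = cc[-1],
      summaryDelta = mean(delta), nWells = length(delta),
      blockId = mat@blockId, drugRow = mat@drugRow, drugCol = mat@drugCol,
      fitRow = fitRow, fitCol = fitCol,
      condRow = fits$condRow, condCol = fits$condCol)
}

# Closed-form delta at (x1, x2) from a full parameter set: monotherapy
# curves (eMax, m, lambda per drug; baseline 0) plus the two conditional
# potency/slope pairs. Vectorized over any argument; the workhorse behind
# the synthetic truth surface and the parametric bootstrap.
.deltaTheta <- function(x1, x2, mR, lamR, mC, lamC,
                        mCondR, lamCondR, mCondC, lamCondC,
                        eMaxR = 1, eMaxC = 1) {
  t <- function(x, m, lam) ifelse(x <= 0, 0, exp(lam * (log(x) - log(m))))
  y1 <- eMaxR * stats::plogis(log(t(x1, mR, lamR)))
  y2 <- eMaxC * stats::plogis(log(t(x2, mC, lamC)))
  tR <- t(x1, mCondR, lamCondR)
  tC <- t(x2, mCondC, lamCondC)
  ycR <- (y2 + tR) / (1 + tR)  # row drug varying, baseline = partner effect
  ycC <- (y1 + tC) / (1 + tC)
  0.5 * (ycR + ycC) - (y1 + y2 - y1 * y2)
}
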