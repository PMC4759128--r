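#' @include io.R
NULL

#' Describe the ground truth of a synthetic combination matrix
#'
#' Builds a [SyntheticTruth-class] for [generateSyntheticMatrix()]. The
#' two monotherapy curves have baseline 0 and maximum 1 (equally effective
#' drugs) with potency `m1`/`m2` and slope `lambda1`/`lambda2`. Under the
#' `potency-shift` mode the conditional potency of each drug in the
#' presence of the partner is `potencyShift * m`; a shift below 1 makes
#' the partner sensitize the drug (synergy), above 1 desensitize it
#' (antagonism). Conditional slopes stay at the monotherapy values unless
#' overridden.
#'
#' @param mode `"bliss-null"`, `"loewe-sham"` or `"potency-shift"`.
#' @param m1,lambda1,m2,lambda2 monotherapy curve parameters.
#' @param potencyShift multiplicative conditional potency shift (used by
#'   `potency-shift`; default 0.5, a two-fold sensitization).
#' @param mCondRow,lambdaCondRow,mCondCol,lambdaCondCol explicit
#'   conditional parameters, overriding `potencyShift`.
#' @param noiseSd additive Gaussian noise sd on the inhibition-fraction
#'   scale (default 0.05, a typical large-screen noise level).
#' @param seed integer RNG seed.
#' @return a [SyntheticTruth-class].
#' @examples
#' syntheticTruth("potency-shift", potencyShift = 0.5, noiseSd = 0.05)
#' @export
syntheticTruth <- function(mode = c("bliss-null", "loewe-sham", "potency-shift"),
                           m1 = 1, lambda1 = 1.5, m2 = 2, lambda2 = 1,
                           potencyShift = 0.5,
                           mCondRow = potencyShift * m1,
                           lambdaCondRow = lambda1,
                           mCondCol = potencyShift * m2,
                           lambdaCondCol = lambda2,
                           noiseSd = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "loewe-sham" && (m1 != m2 || lambda1 != lambda2)) {
    warning("loewe-sham emulates a drug combined with itself; forcing drug 2 parameters to drug 1's")
    m2 <- m1; lambda2 <- lambda1
  }
  new("SyntheticTruth", mode = mode,
      m1 = m1, lambda1 = lambda1, m2 = m2, lambda2 = lambda2,
      mCondRow = mCondRow, lambdaCondRow = lambdaCondRow,
      mCondCol = mCondCol, lambdaCondCol = lambdaCondCol,
      noiseSd = noiseSd, seed = as.integer(seed))
}

.defaultConc <- function(m) c(0, m * 10^seq(-1, 1, by = 0.5))

.truthSurface <- function(truth, concRow, concCol) {
  f1 <- logisticFit(0, 1, truth@m1, truth@lambda1)
  f2 <- logisticFit(0, 1, truth@m2, truth@lambda2)
  y1 <- evaluateLogistic(f1, concRow)
  y2 <- evaluateLogistic(f2, concCol)
  resp <- matrix(0, length(concRow), length(concCol))
  resp[, 1] <- y1
  resp[1, ] <- y2
  for (i in seq_along(concRow)[-1]) {
    for (j in seq_along(concCol)[-1]) {
      x1 <- concRow[i]; x2 <- concCol[j]
      resp[i, j] <- switch(truth@mode,
        "bliss-null" = y1[i] + y2[j] - y1[i] * y2[j],
        "loewe-sham" = evaluateLogistic(f1, x1 + x2),
        "potency-shift" = {
          tR <- (x1 / truth@mCondRow)^truth@lambdaCondRow
          tC <- (x2 / truth@mCondCol)^truth@lambdaCondCol
          0.5 * ((y2[j] + tR) / (1 + tR) + (y1[i] + tC) / (1 + tC))
        })
    }
  }
  resp
}

#' Generate a synthetic dose-response combination matrix
#'
#' Emulates a serially diluted full-matrix combination screen: monotherapy
#' wells come from the generating log-logistic curves, combination wells
#' from the surface of the selected interaction mode (see
#' [SyntheticTruth-class]), and i.i.d. Gaussian noise with sd
#' `truth@noiseSd` is added to every well. Generation is deterministic
#' under the truth's seed. Default concentrations are five half-log
#' dilutions centered on each drug's own midpoint dose, plus the zero
#' dose — the standard 6x6 design.
#'
#' @param truth a [SyntheticTruth-class].
#' @param concRow,concCol concentration vectors (first element 0); default
#'   `c(0, m * 10^seq(-1, 1, 0.5))` per drug.
#' @return a [DoseResponseMatrix-class].
#' @examples
#' mat <- generateSyntheticMatrix(syntheticTruth("bliss-null", noiseSd = 0))
#' max(abs(deltaGrid(deltaScore(mat))))  # ~0
#' @export
generateSyntheticMatrix <- function(truth,
                                    concRow = .defaultConc(truth@m1),
                                    concCol = .defaultConc(truth@m2)) {
  stopifnot(is(truth, "SyntheticTruth"))
  resp <- .truthSurface(truth, concRow, concCol)
  if (truth@noiseSd > 0) {
    set.seed(truth@seed)
    resp <- resp + matrix(stats::rnorm(length(resp), 0, truth@noiseSd),
                          nrow(resp), ncol(resp))
  }
  doseResponseMatrix(resp, concRow, concCol,
                     drugRow = "synthRow", drugCol = "synthCol",
                     blockId = sprintf("synthetic-%s-seed%d", truth@mode,
                                       truth@seed))
}

#' Analytic delta surface of a synthetic truth
#'
#' The delta values implied directly by the generating parameters, without
#' any curve fitting: zero everywhere for `bliss-null`, and the closed-form
#' potency-shift deviation for `potency-shift`. For `loewe-sham` no
#' analytic delta surface is defined under this construction and `NA`s are
#' returned.
#'
#' @inheritParams generateSyntheticMatrix
#' @return numeric matrix over the combination region (nonzero doses).
#' @export
trueDeltaSurface <- function(truth,
                             concRow = .defaultConc(truth@m1),
                             concCol = .defaultConc(truth@m2)) {
  stopifnot(is(truth, "SyntheticTruth"))
  cr <- concRow[-1]; cc <- concCol[-1]
  if (truth@mode == "bliss-null")
    return(matrix(0, length(cr), length(cc)))
  if (truth@mode == "loewe-sham")
    return(matrix(NA_real_, length(cr), length(cc)))
  outer(cr, cc, function(x1, x2)
    .deltaTheta(x1, x2,
                mR = truth@m1, lamR = truth@lambda1,
                mC = truth@m2, lamC = truth@lambda2,
                mCondR = truth@mCondRow, lamCondR = truth@lambdaCondRow,
                mCondC = truth@mCondCol, lamCondC = truth@lambdaCondCol))
}
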