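#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# LogisticFit
# ---------------------------------------------------------------------------

#' Fitted log-logistic (4PL) dose-response curve
#'
#' Container for the four parameters of a log-logistic dose-response curve
#' \deqn{y(x) = \frac{E_{min} + E_{max}\,(x/m)^\lambda}{1 + (x/m)^\lambda},}
#' i.e. a sigmoid rising from the baseline effect `eMin` at dose 0 to the
#' maximal effect `eMax` as the dose grows, with midpoint dose `m` (the
#' relative IC50/EC50) and slope `lambda`. Effects are fractions of
#' inhibition, so `0 <= eMin < eMax <= 1`.
#'
#' When the nonlinear fit of noisy plate data does not converge (for
#' example on inverted or erratic response rows), the object instead
#' carries the observed points and every curve evaluation falls back to
#' piecewise-linear interpolation clamped to \[0, 1\]; such objects have
#' `converged = FALSE`.
#'
#' @slot eMin,eMax baseline and maximal fractional inhibition.
#' @slot m midpoint dose, in the concentration unit of the input doses.
#' @slot lambda dimensionless slope (> 0).
#' @slot rss residual sum of squares of the fit.
#' @slot nPoints number of wells used.
#' @slot converged logical; `FALSE` marks the interpolation fallback.
#' @slot se named numeric vector of standard errors for the freely fitted
#'   parameters (empty when unavailable).
#' @slot fallbackDoses,fallbackResponses observed points backing the
#'   fallback curve (length 0 for converged fits).
#' @seealso [fitLogistic()], [evaluateLogistic()]
#' @export
setClass("LogisticFit",
  representation(
    eMin = "numeric", eMax = "numeric", m = "numeric", lambda = "numeric",
    rss = "numeric", nPoints = "integer", converged = "logical",
    se = "numeric", fallbackDoses = "numeric", fallbackResponses = "numeric"
  ),
  prototype(
    eMin = 0, eMax = 1, m = 1, lambda = 1, rss = 0, nPoints = 0L,
    converged = TRUE, se = numeric(0),
    fallbackDoses = numeric(0), fallbackResponses = numeric(0)
  )
)

setValidity("LogisticFit", function(object) {
  msg <- character(0)
  p <- c(object@eMin, object@eMax, object@m, object@lambda)
  if (length(object@eMin) != 1L || length(object@eMax) != 1L ||
      length(object@m) != 1L || length(object@lambda) != 1L) {
    msg <- c(msg, "eMin, eMax, m and lambda must be scalars")
  } else if (any(!is.finite(p))) {
    msg <- c(msg, "curve parameters must be finite")
  } else {
    if (object@eMin < 0 || object@eMax > 1 || object@eMin >= object@eMax)
      msg <- c(msg, "need 0 <= eMin < eMax <= 1")
    if (object@m <= 0) msg <- c(msg, "m must be > 0")
    if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  }
  if (length(object@fallbackDoses) != length(object@fallbackResponses))
    msg <- c(msg, "fallback doses/responses length mismatch")
  if (length(msg)) msg else TRUE
})

#' Construct a LogisticFit from known parameters
#'
#' Mostly useful for tests, simulations and for evaluating theoretical
#' curves; data-driven fits come from [fitLogistic()].
#'
#' @param eMin,eMax,m,lambda curve parameters (see [LogisticFit-class]).
#' @return a [LogisticFit-class] object flagged as converged.
#' @examples
#' fit <- logisticFit(eMax = 1, m = 2, lambda = 1.5)
#' evaluateLogistic(fit, 2)  # midpoint effect 0.5
#' @export
logisticFit <- function(eMin = 0, eMax = 1, m = 1, lambda = 1) {
  new("LogisticFit", eMin = as.numeric(eMin), eMax = as.numeric(eMax),
      m = as.numeric(m), lambda = as.numeric(lambda),
      rss = 0, nPoints = 0L, converged = TRUE)
}

#' @rdname accessors
setMethod("eMin", "LogisticFit", function(object) object@eMin)
#' @rdname accessors
setMethod("eMax", "LogisticFit", function(object) object@eMax)
#' @rdname accessors
setMethod("potency", "LogisticFit", function(object) object@m)
#' @rdname accessors
setMethod("shape", "LogisticFit", function(object) object@lambda)
#' @rdname accessors
setMethod("isConverged", "LogisticFit", function(object) object@converged)

setMethod("show", "LogisticFit", function(object) {
  cat("LogisticFit:",
      if (object@converged) "converged" else "FALLBACK (interpolation)", "\n")
  cat(sprintf("  eMin = %.4g, eMax = %.4g, m = %.4g, lambda = %.4g\n",
              object@eMin, object@eMax, object@m, object@lambda))
  cat(sprintf("  rss = %.4g over %d points\n", object@rss, object@nPoints))
  invisible(object)
})

# ---------------------------------------------------------------------------
# ConditionalFit
# ---------------------------------------------------------------------------

#' Combination-axis dose-response fit conditional on a partner dose
#'
#' A log-logistic curve describing one drug's dose-response in the presence
#' of a fixed dose of the partner drug. Under the zero-interaction-potency
#' construction the partner only lifts the baseline: the curve runs from
#' `baseline` (the fitted partner monotherapy effect, held fixed) up to 1,
#' \deqn{y(x) = \frac{b + (x/m)^\lambda}{1 + (x/m)^\lambda},}
#' and only the conditional potency `m` and slope `lambda` are estimated.
#' The class extends [LogisticFit-class] with `eMin = baseline` and
#' `eMax = 1`, so all curve operations apply unchanged.
#'
#' @slot fixedPartnerDose the partner-drug concentration this curve is
#'   conditioned on (> 0).
#' @seealso [fitConditionalCurves()]
#' @export
setClass("ConditionalFit",
  contains = "LogisticFit",
  representation(fixedPartnerDose = "numeric"),
  prototype(fixedPartnerDose = 1)
)

setValidity("ConditionalFit", function(object) {
  if (length(object@fixedPartnerDose) != 1L || !is.finite(object@fixedPartnerDose) ||
      object@fixedPartnerDose <= 0)
    return("fixedPartnerDose must be a single positive number")
  TRUE
})

#' Baseline (partner effect) of a conditional fit
#' @param object a `ConditionalFit`.
#' @return the fixed baseline effect, identical to `eMin(object)`.
#' @export
baseline <- function(object) {
  stopifnot(is(object, "ConditionalFit"))
  object@eMin
}

setMethod("show", "ConditionalFit", function(object) {
  cat(sprintf("ConditionalFit (partner dose %.4g): baseline = %.4g, m = %.4g, lambda = %.4g%s\n",
              object@fixedPartnerDose, object@eMin, object@m, object@lambda,
              if (object@converged) "" else "  [FALLBACK]"))
  invisible(object)
})

# ---------------------------------------------------------------------------
# DoseResponseMatrix
# ---------------------------------------------------------------------------

#' Two-drug dose-response combination matrix
#'
#' One combination block of a matrix screen: the full factorial grid of two
#' drugs' concentration series, each series starting at dose 0, with one
#' measured response per well on the inhibition-fraction scale. Row 1
#' (row-drug dose 0) carries the column drug's monotherapy series, column 1
#' carries the row drug's, and cell (1, 1) is the untreated well.
#'
#' @slot drugRow,drugCol drug identifiers.
#' @slot concRow,concCol concentration vectors; first element 0, then
#'   strictly increasing positive doses.
#' @slot response numeric matrix of fractional inhibition, rows indexed by
#'   `concRow` and columns by `concCol`. Values may fall outside \[0, 1\]
#'   because of measurement noise and are retained as observed.
#' @slot unitRow,unitCol concentration unit labels.
#' @slot blockId block identifier.
#' @seealso [doseResponseMatrix()], [deltaScore()], [readCombinationTable()]
#' @export
setClass("DoseResponseMatrix",
  representation(
    drugRow = "character", drugCol = "character",
    concRow = "numeric", concCol = "numeric",
    response = "matrix", unitRow = "character", unitCol = "character",
    blockId = "character"
  )
)

setValidity("DoseResponseMatrix", function(object) {
  msg <- character(0)
  chkConc <- function(x, lab) {
    if (length(x) < 2L) return(sprintf("%s needs at least 2 doses", lab))
    if (x[1] != 0) return(sprintf("%s must start with the zero dose", lab))
    if (any(diff(x) <= 0) || any(x[-1] <= 0))
      return(sprintf("%s must be strictly increasing and positive after 0", lab))
    NULL
  }
  msg <- c(msg, chkConc(object@concRow, "concRow"), chkConc(object@concCol, "concCol"))
  if (!identical(dim(object@response),
                 c(length(object@concRow), length(object@concCol))))
    msg <- c(msg, "response dimensions must match the concentration vectors")
  if (any(!is.finite(object@response)))
    msg <- c(msg, "all responses must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseResponseMatrix
#'
#' @param response numeric matrix of fractional inhibition (rows = row-drug
#'   doses, columns = column-drug doses).
#' @param concRow,concCol concentration vectors starting at 0.
#' @param drugRow,drugCol drug names.
#' @param unitRow,unitCol concentration unit labels.
#' @param blockId block identifier.
#' @return a [DoseResponseMatrix-class].
#' @examples
#' conc <- c(0, 0.1, 1, 10)
#' f <- logisticFit(m = 1, lambda = 1)
#' y1 <- evaluateLogistic(f, conc); y2 <- evaluateLogistic(f, conc)
#' resp <- outer(y1, y2, function(a, b) a + b - a * b)
#' doseResponseMatrix(resp, conc, conc)
#' @export
doseResponseMatrix <- function(response, concRow, concCol,
                               drugRow = "drugRow", drugCol = "drugCol",
                               unitRow = "uM", unitCol = "uM",
                               blockId = "block1") {
  new("DoseResponseMatrix",
      drugRow = as.character(drugRow), drugCol = as.character(drugCol),
      concRow = as.numeric(concRow), concCol = as.numeric(concCol),
      response = as.matrix(response),
      unitRow = as.character(unitRow), unitCol = as.character(unitCol),
      blockId = as.character(blockId))
}

#' @rdname accessors
setMethod("concRow", "DoseResponseMatrix", function(object) object@concRow)
#' @rdname accessors
setMethod("concCol", "DoseResponseMatrix", function(object) object@concCol)
#' @rdname accessors
setMethod("drugRow", "DoseResponseMatrix", function(object) object@drugRow)
#' @rdname accessors
setMethod("drugCol", "DoseResponseMatrix", function(object) object@drugCol)
#' @rdname accessors
setMethod("blockId", "DoseResponseMatrix", function(object) object@blockId)
#' @rdname accessors
setMethod("responseMatrix", "DoseResponseMatrix", function(object) {
  m <- object@response
  dimnames(m) <- list(format(object@concRow, trim = TRUE),
                      format(object@concCol, trim = TRUE))
  m
})

setMethod("show", "DoseResponseMatrix", function(object) {
  cat(sprintf("DoseResponseMatrix '%s': %s (rows, %s) x %s (cols, %s)\n",
              object@blockId, object@drugRow, object@unitRow,
              object@drugCol, object@unitCol))
  cat(sprintf("  %d x %d wells; inhibition range [%.3f, %.3f]\n",
              nrow(object@response), ncol(object@response),
              min(object@response), max(object@response)))
  invisible(object)
})

#' Transpose a combination block (swap the two drugs)
#'
#' Swaps the roles of the row and column drugs. All interaction scores in
#' the package are invariant under this relabeling (up to curve-fitting
#' tolerance for the delta score).
#'
#' @param object a [DoseResponseMatrix-class].
#' @return the transposed [DoseResponseMatrix-class].
#' @export
transposeBlock <- function(object) {
  stopifnot(is(object, "DoseResponseMatrix"))
  new("DoseResponseMatrix",
      drugRow = object@drugCol, drugCol = object@drugRow,
      concRow = object@concCol, concCol = object@concRow,
      response = t(object@response),
      unitRow = object@unitCol, unitCol = object@unitRow,
      blockId = object@blockId)
}

# ---------------------------------------------------------------------------
# InteractionLandscape
# ---------------------------------------------------------------------------

#' Per-dose-pair delta landscape of a combination block
#'
#' The delta score surface over the combination region of a dose-response
#' matrix (all wells with both doses > 0), together with the summary score
#' (the mean delta), per-well fallback flags, and the fitted monotherapy
#' and conditional curves the scores were derived from. Delta has units of
#' fractional inhibition: `delta = 0.2` means 20 percentage points of
#' inhibition beyond the zero-interaction expectation.
#'
#' @slot delta numeric matrix of delta values, `(nrow-1) x (ncol-1)` of the
#'   parent matrix, indexed by the nonzero doses.
#' @slot flags logical matrix, `TRUE` where any contributing curve fit fell
#'   back to interpolation.
#' @slot concRow,concCol the nonzero concentration vectors.
#' @slot summaryDelta mean of `delta`.
#' @slot nWells number of combination wells.
#' @slot blockId,drugRow,drugCol identifiers carried over from the input.
#' @slot fitRow,fitCol monotherapy [LogisticFit-class] objects.
#' @slot condRow list of [ConditionalFit-class] for the row drug, one per
#'   nonzero column dose; `condCol` likewise for the column drug.
#' @seealso [deltaScore()], [summaryDelta()], [exportLandscape()]
#' @export
setClass("InteractionLandscape",
  representation(
    delta = "matrix", flags = "matrix",
    concRow = "numeric", concCol = "numeric",
    summaryDelta = "numeric", nWells = "integer",
    blockId = "character", drugRow = "character", drugCol = "character",
    fitRow = "LogisticFit", fitCol = "LogisticFit",
    condRow = "list", condCol = "list"
  )
)

setValidity("InteractionLandscape", function(object) {
  msg <- character(0)
  if (!identical(dim(object@delta), dim(object@flags)))
    msg <- c(msg, "delta and flags dimensions differ")
  if (object@nWells != length(object@delta))
    msg <- c(msg, "nWells must equal the number of delta entries")
  if (length(object@summaryDelta) == 1L && object@nWells > 0L &&
      abs(object@summaryDelta - mean(object@delta)) > 1e-12)
    msg <- c(msg, "summaryDelta must be the mean of the delta grid")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
setMethod("deltaGrid", "InteractionLandscape", function(object) {
  d <- object@delta
  dimnames(d) <- list(format(object@concRow, trim = TRUE),
                      format(object@concCol, trim = TRUE))
  d
})
#' @rdname accessors
setMethod("concRow", "InteractionLandscape", function(object) object@concRow)
#' @rdname accessors
setMethod("concCol", "InteractionLandscape", function(object) object@concCol)
#' @rdname accessors
setMethod("blockId", "InteractionLandscape", function(object) object@blockId)

#' @rdname summaryDelta
setMethod("summaryDelta", "InteractionLandscape", function(object, percent = FALSE) {
  if (percent) 100 * object@summaryDelta else object@summaryDelta
})

setMethod("show", "InteractionLandscape", function(object) {
  cat(sprintf("InteractionLandscape '%s' (%s x %s): %d combination wells\n",
              object@blockId, object@drugRow, object@drugCol, object@nWells))
  cat(sprintf("  summary delta = %.4f (%.1f%% inhibition beyond expectation)\n",
              object@summaryDelta, 100 * object@summaryDelta))
  cat(sprintf("  delta range [%.4f, %.4f]; %d flagged wells\n",
              min(object@delta), max(object@delta), sum(object@flags)))
  invisible(object)
})

# ---------------------------------------------------------------------------
# ScorePanel
# ---------------------------------------------------------------------------

#' Panel of per-combination interaction scores
#'
#' All summary interaction scores of one combination block. Scores that
#' cannot be computed carry an explicit status instead of a silent default.
#' `excessCRX` is reserved but never computed (status `"not-implemented"`).
#'
#' Scale conventions: `excessHSA` and `ls3x3` are sums of per-well excess
#' over the HSA expectation on the percent-viability scale (synergy
#' negative); `medianExcess` is the median per-well HSA excess on the
#' percent-inhibition scale (synergy positive); `beta` and `gamma` are
#' dimensionless with non-interaction at 1 and synergy below 1, left-bounded
#' at 0; `summaryDelta` is on the inhibition-fraction scale with synergy
#' positive.
#'
#' @slot blockId,drugRow,drugCol identifiers.
#' @slot summaryDelta,numExcess,excessHSA,medianExcess,ls3x3,beta,gamma
#'   numeric scores (`NA` when undefined; see `status`).
#' @slot ciMedian,alphaMedian median Combination Index and interaction-index
#'   alpha over the combination wells where they are defined.
#' @slot excessCRX always `NA`.
#' @slot status named character vector of per-score status flags
#'   (`"ok"`, `"undefined"`, `"clamped"`, `"not-implemented"`, ...).
#' @seealso [scorePanel()]
#' @export
setClass("ScorePanel",
  representation(
    blockId = "character", drugRow = "character", drugCol = "character",
    summaryDelta = "numeric", numExcess = "numeric", excessHSA = "numeric",
    medianExcess = "numeric", ls3x3 = "numeric", beta = "numeric",
    gamma = "numeric", ciMedian = "numeric", alphaMedian = "numeric",
    excessCRX = "numeric", status = "character"
  )
)

setMethod("show", "ScorePanel", function(object) {
  cat(sprintf("ScorePanel '%s' (%s x %s)\n", object@blockId,
              object@drugRow, object@drugCol))
  df <- as.data.frame(object)
  print(df[, setdiff(names(df), c("block_id", "drug_row", "drug_col"))],
        row.names = FALSE)
  bad <- object@status[object@status != "ok"]
  if (length(bad))
    cat("  status:", paste(sprintf("%s=%s", names(bad), bad), collapse = ", "), "\n")
  invisible(object)
})

#' @describeIn ScorePanel-class flatten to a one-row data frame (the CSV
#'   row format used by the command-line interface).
#' @param x a `ScorePanel`.
#' @param row.names,optional,... ignored; present for the generic.
#' @export
as.data.frame.ScorePanel <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    block_id = x@blockId, drug_row = x@drugRow, drug_col = x@drugCol,
    summary_delta = x@summaryDelta, num_excess = x@numExcess,
    excess_hsa = x@excessHSA, median_excess = x@medianExcess,
    ls3x3 = x@ls3x3, beta = x@beta, gamma = x@gamma,
    ci_median = x@ciMedian, alpha_median = x@alphaMedian,
    excess_crx = x@excessCRX,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# BootstrapResult
# ---------------------------------------------------------------------------

#' Parametric-bootstrap significance estimate for a delta score
#'
#' Result of resampling the fitted curve parameters from independent normal
#' distributions and re-evaluating the delta score of one combination well.
#' `pSynergy` is the proportion of bootstrap draws with delta > 0 (the
#' support-proportion "p-value"); `pTwoSided` is the conventional two-sided
#' version `2 * min(pSynergy, pAntagonism)`. The identity
#' `pSynergy + pAntagonism + pTies = 1` holds exactly.
#'
#' @slot deltaHat point estimate of delta at the well.
#' @slot samples bootstrap delta draws.
#' @slot pSynergy,pAntagonism,pTies,pTwoSided bootstrap proportions.
#' @slot ciLow,ciHigh normal-approximation confidence bounds.
#' @slot alphaLevel type-I error level of the interval.
#' @slot nBoot number of draws; `seed` the RNG seed used.
#' @slot well row/column indices of the well within the combination region.
#' @seealso [bootstrapDelta()]
#' @export
setClass("BootstrapResult",
  representation(
    deltaHat = "numeric", samples = "numeric",
    pSynergy = "numeric", pAntagonism = "numeric", pTies = "numeric",
    pTwoSided = "numeric", ciLow = "numeric", ciHigh = "numeric",
    alphaLevel = "numeric", nBoot = "integer", seed = "integer",
    well = "integer"
  )
)

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: delta = %.4f at well (%d, %d)\n",
              object@deltaHat, object@well[1], object@well[2]))
  cat(sprintf("  p(synergy) = %.3f, p(two-sided) = %.3f  [%d draws, seed %d]\n",
              object@pSynergy, object@pTwoSided, object@nBoot, object@seed))
  cat(sprintf("  %.0f%% CI [%.4f, %.4f]\n",
              100 * (1 - object@alphaLevel), object@ciLow, object@ciHigh))
  invisible(object)
})

# ---------------------------------------------------------------------------
# SyntheticTruth
# ---------------------------------------------------------------------------

#' Generating parameters for a synthetic combination matrix
#'
#' Describes the ground truth behind a simulated dose-response matrix:
#' the two monotherapy log-logistic curves (with baseline 0 and maximum 1),
#' the interaction mode of the combination surface, the conditional
#' potency/slope parameters used by the `potency-shift` mode, the Gaussian
#' noise level and the RNG seed.
#'
#' Modes: `bliss-null` builds combination wells from the multiplicative
#' survival of the two curves (the zero-interaction surface, true delta 0);
#' `loewe-sham` emulates a drug combined with itself, responding as the
#' single drug at dose `x1 + x2` (requires identical curve parameters);
#' `potency-shift` injects interaction by shifting the conditional potency
#' of each drug in the presence of the partner, and the true delta surface
#' follows in closed form from the generating parameters.
#'
#' @slot mode one of `"bliss-null"`, `"loewe-sham"`, `"potency-shift"`.
#' @slot m1,lambda1 row-drug potency and slope; `m2,lambda2` column drug.
#' @slot mCondRow,lambdaCondRow conditional parameters of the row drug when
#'   the partner is present; `mCondCol,lambdaCondCol` likewise.
#' @slot noiseSd standard deviation of additive Gaussian noise, on the
#'   inhibition-fraction scale.
#' @slot seed integer RNG seed.
#' @seealso [syntheticTruth()], [generateSyntheticMatrix()],
#'   [trueDeltaSurface()]
#' @export
setClass("SyntheticTruth",
  representation(
    mode = "character",
    m1 = "numeric", lambda1 = "numeric", m2 = "numeric", lambda2 = "numeric",
    mCondRow = "numeric", lambdaCondRow = "numeric",
    mCondCol = "numeric", lambdaCondCol = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("bliss-null", "loewe-sham", "potency-shift"))
    msg <- c(msg, "mode must be bliss-null, loewe-sham or potency-shift")
  par <- c(object@m1, object@lambda1, object@m2, object@lambda2,
           object@mCondRow, object@lambdaCondRow,
           object@mCondCol, object@lambdaCondCol)
  if (any(!is.finite(par)) || any(par <= 0))
    msg <- c(msg, "all curve parameters must be finite and positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: mode '%s', noise sd %.3g, seed %d\n",
              object@mode, object@noiseSd, object@seed))
  cat(sprintf("  row drug: m = %.3g, lambda = %.3g; col drug: m = %.3g, lambda = %.3g\n",
              object@m1, object@lambda1, object@m2, object@lambda2))
  if (object@mode == "potency-shift")
    cat(sprintf("  conditional: row m = %.3g (lambda %.3g), col m = %.3g (lambda %.3g)\n",
                object@mCondRow, object@lambdaCondRow,
                object@mCondCol, object@lambdaCondCol))
  invisible(object)
})
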