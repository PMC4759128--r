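#' @include zip-delta.R
NULL

# Split a block into the pieces the matrix-level scores operate on:
# observed monotherapy effects expanded over the combination region, plus
# the combination responses themselves.
.comboPieces <- function(mat) {
  resp <- mat@response
  nR <- nrow(resp); nC <- ncol(resp)
  yc <- resp[-1, -1, drop = FALSE]
  y1 <- matrix(resp[-1, 1], nR - 1L, nC - 1L)          # row drug alone
  y2 <- matrix(resp[1, -1], nR - 1L, nC - 1L, byrow = TRUE)  # col drug alone
  list(yc = yc, y1 = y1, y2 = y2)
}

#' Number of wells exceeding both monotherapies
#'
#' Counts the combination wells whose inhibition is strictly greater than
#' both the same-row and the same-column monotherapy inhibition.
#'
#' @param mat a [DoseResponseMatrix-class].
#' @return integer count.
#' @export
numExcess <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  sum(p$yc > p$y1 & p$yc > p$y2)
}

#' Total excess over the HSA expectation (viability scale)
#'
#' Sum over the combination wells of the difference between the observed
#' combination viability and the HSA-expected viability (the lower of the
#' two monotherapy viabilities), in percent-viability points. Synergy
#' drives the total negative.
#'
#' @inheritParams numExcess
#' @return percentage-point sum (negative = synergy).
#' @export
excessHSA <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  sum(100 * (hsaExpected(p$y1, p$y2) - p$yc))
}

#' Median excess over the HSA expectation (inhibition scale)
#'
#' Median over the combination wells of the per-well excess inhibition
#' beyond the HSA expectation, in percent-inhibition points. Synergy is
#' positive on this scale (the complement of the [excessHSA()] viability
#' convention).
#'
#' @inheritParams numExcess
#' @return percentage points (positive = synergy).
#' @export
medianExcess <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  stats::median(100 * (p$yc - hsaExpected(p$y1, p$y2)))
}

#' Best 3x3 block of HSA excess
#'
#' The minimum (most synergistic, i.e. most negative on the viability
#' scale) total HSA excess over all contiguous 3x3 blocks of the
#' combination region.
#'
#' @inheritParams numExcess
#' @return percentage-point sum of the best block.
#' @export
ls3x3 <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  ex <- 100 * (hsaExpected(p$y1, p$y2) - p$yc)  # per-well viability excess
  nR <- nrow(ex); nC <- ncol(ex)
  if (nR < 3L || nC < 3L)
    stop("ls3x3 needs a combination region of at least 3 x 3 wells")
  best <- Inf
  for (i in seq_len(nR - 2L)) {
    for (j in seq_len(nC - 2L)) {
      s <- sum(ex[i:(i + 2L), j:(j + 2L)])
      if (s < best) best <- s
    }
  }
  best
}

# Closed-form 1-D least squares argmin_b sum((vc - b*vb)^2) = sum(vc*vb)/sum(vb^2),
# clamped at the left bound 0; returns value + status.
.lsRatio <- function(vc, vb) {
  den <- sum(vb^2)
  if (den <= 0)
    return(list(value = NA_real_, status = "degenerate-denominator"))
  b <- sum(vc * vb) / den
  if (b < 0) list(value = 0, status = "clamped") else list(value = b, status = "ok")
}

#' Bliss interaction parameter beta
#'
#' The multiplier minimizing the squared deviance of the observed
#' combination viabilities `1 - yc` from the Bliss-expected viabilities
#' `(1 - y1)(1 - y2)` over the combination wells, in closed form
#' `beta = sum(vc*vb) / sum(vb^2)`. `beta = 1` means perfect Bliss
#' independence and `beta < 1` synergy; the score is left-bounded at 0.
#' Observed (not fitted) monotherapy responses are used.
#'
#' @inheritParams numExcess
#' @return dimensionless beta (>= 0), `NA` with an error if all
#'   Bliss-expected viabilities are zero.
#' @export
betaScore <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  r <- .lsRatio(1 - p$yc, (1 - p$y1) * (1 - p$y2))
  if (r$status == "degenerate-denominator")
    stop("beta undefined: all Bliss-expected viabilities are zero")
  r$value
}

#' HSA/Bliss hybrid interaction parameter gamma
#'
#' Like [betaScore()] but against the hybrid expectation
#' `max(1 - y1, 1 - y2)`: `gamma = sum(vc*vh) / sum(vh^2)` with
#' `vh = max(1 - y1, 1 - y2)` per well. `gamma < 1` indicates synergy;
#' left-bounded at 0.
#'
#' @inheritParams numExcess
#' @return dimensionless gamma (>= 0).
#' @export
gammaScore <- function(mat) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  p <- .comboPieces(mat)
  r <- .lsRatio(1 - p$yc, pmax(1 - p$y1, 1 - p$y2))
  if (r$status == "degenerate-denominator")
    stop("gamma undefined: all hybrid-expected viabilities are zero")
  r$value
}

#' Compute the full score panel of a combination block
#'
#' Runs the delta pipeline plus all matrix-level comparison scores on one
#' block and collects them with per-score status flags. The Loewe-derived
#' entries (`ciMedian`, `alphaMedian`) are the medians of the per-well
#' Combination Index and interaction-index alpha over the wells where they
#' are defined; when the observed effect is unreachable for a single-agent
#' curve in every well they are `NA` with status `"undefined"`.
#'
#' @inheritParams numExcess
#' @param landscape optionally, a precomputed [InteractionLandscape-class]
#'   for this block (avoids refitting).
#' @return a [ScorePanel-class].
#' @examples
#' tr <- syntheticTruth("potency-shift", noiseSd = 0.02)
#' sp <- scorePanel(generateSyntheticMatrix(tr))
#' as.data.frame(sp)
#' @export
scorePanel <- function(mat, landscape = NULL) {
  stopifnot(is(mat, "DoseResponseMatrix"))
  if (is.null(landscape)) landscape <- deltaScore(mat)
  status <- c(summaryDelta = "ok", numExcess = "ok", excessHSA = "ok",
              medianExcess = "ok", ls3x3 = "ok", beta = "ok", gamma = "ok",
              ciMedian = "ok", alphaMedian = "ok",
              excessCRX = "not-implemented")
  if (any(landscape@flags)) status["summaryDelta"] <- "fit-fallback"

  ls3 <- tryCatch(ls3x3(mat), error = function(e) NA_real_)
  if (is.na(ls3)) status["ls3x3"] <- "too-small-matrix"
  p <- .comboPieces(mat)
  bt <- .lsRatio(1 - p$yc, (1 - p$y1) * (1 - p$y2))
  gm <- .lsRatio(1 - p$yc, pmax(1 - p$y1, 1 - p$y2))
  status["beta"] <- if (bt$status == "degenerate-denominator") "undefined" else bt$status
  status["gamma"] <- if (gm$status == "degenerate-denominator") "undefined" else gm$status

  # per-well Loewe-derived indices from the fitted monotherapy curves
  fitR <- landscape@fitRow; fitC <- landscape@fitCol
  cr <- landscape@concRow; cc <- landscape@concCol
  ci <- al <- rep(NA_real_, length(cr) * length(cc))
  k <- 0L
  for (i in seq_along(cr)) for (j in seq_along(cc)) {
    k <- k + 1L
    yc <- mat@response[i + 1L, j + 1L]
    ci[k] <- combinationIndex(fitR, fitC, cr[i], cc[j], yc)
    al[k] <- interactionAlpha(fitR, fitC, cr[i], cc[j], yc)
  }
  ciMed <- if (all(is.na(ci))) NA_real_ else stats::median(ci, na.rm = TRUE)
  alMed <- if (all(is.na(al))) NA_real_ else stats::median(al, na.rm = TRUE)
  if (is.na(ciMed)) status["ciMedian"] <- "undefined"
  if (is.na(alMed)) status["alphaMedian"] <- "undefined"

  new("ScorePanel",
      blockId = mat@blockId, drugRow = mat@drugRow, drugCol = mat@drugCol,
      summaryDelta = landscape@summaryDelta,
      numExcess = as.numeric(numExcess(mat)),
      excessHSA = excessHSA(mat), medianExcess = medianExcess(mat),
      ls3x3 = ls3, beta = bt$value, gamma = gm$value,
      ciMedian = ciMed, alphaMedian = alMed,
      excessCRX = NA_real_, status = status)
}
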