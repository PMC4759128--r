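#' @include logistic-fit.R
NULL

#' Highest-single-agent (HSA) expected effect
#'
#' The non-interaction expectation under the HSA model: the stronger of
#' the two monotherapy effects, `max(y1, y2)`.
#'
#' @param y1,y2 monotherapy fractional inhibition values.
#' @return numeric vector of expected effects.
#' @examples hsaExpected(0.3, 0.4)
#' @export
hsaExpected <- function(y1, y2) {
  stopifnot(is.numeric(y1), is.numeric(y2), all(is.finite(y1)), all(is.finite(y2)))
  pmax(y1, y2)
}

#' Bliss-independence expected effect
#'
#' The non-interaction expectation when the two drugs act as independent
#' probabilistic events: `y1 + y2 - y1*y2`.
#'
#' @param y1,y2 monotherapy fractional inhibition values, in \[0, 1\].
#' @param strict if `TRUE`, out-of-range inputs raise an error; otherwise
#'   (default) they are clamped to \[0, 1\] before combining.
#' @return numeric vector of expected effects.
#' @examples blissExpected(0.3, 0.4)  # 0.58
#' @export
blissExpected <- function(y1, y2, strict = FALSE) {
  stopifnot(is.numeric(y1), is.numeric(y2), all(is.finite(y1)), all(is.finite(y2)))
  out <- y1 < 0 | y1 > 1 | y2 < 0 | y2 > 1
  if (any(out)) {
    if (strict) stop("Bliss expectation needs effects in [0, 1]")
    y1 <- pmin(pmax(y1, 0), 1)
    y2 <- pmin(pmax(y2, 0), 1)
  }
  y1 + y2 - y1 * y2
}

#' Loewe-additivity expected effect
#'
#' Solves the dose-additivity equation
#' \deqn{x_1 / D_1(y) + x_2 / D_2(y) = 1}
#' for the expected effect `y`, where `D_i(y)` is the dose of drug `i`
#' alone producing `y` (the inverse of its fitted curve). The root is
#' bracketed on the open effect band `(max(eMin1, eMin2), min(eMax1,
#' eMax2))` and found by bisection. When no root exists in the band — a
#' combination whose required effect exceeds what one of the single agents
#' can reach — the result carries `status = "unreachable"` rather than a
#' number: the classical blind spot of Loewe-based scoring.
#'
#' A zero dose short-circuits to the other drug's monotherapy effect. For
#' identical drugs (a sham combination) the solution equals the single-drug
#' response at dose `x1 + x2`.
#'
#' @param fit1,fit2 monotherapy [LogisticFit-class] objects.
#' @param x1,x2 the combination doses (>= 0).
#' @param tol bisection tolerance on the effect scale.
#' @param maxIter maximum bisection iterations.
#' @return a list with elements `yLoewe` (numeric or `NA`) and `status`
#'   (one of `"ok"`, `"unreachable"`, `"no-convergence"`).
#' @examples
#' f <- logisticFit(m = 1, lambda = 1)
#' loeweExpected(f, f, 0.5, 0.5)$yLoewe  # sham: f(1) = 0.5
#' @export
loeweExpected <- function(fit1, fit2, x1, x2, tol = 1e-10, maxIter = 200L) {
  stopifnot(is(fit1, "LogisticFit"), is(fit2, "LogisticFit"),
            is.numeric(x1), is.numeric(x2), x1 >= 0, x2 >= 0)
  if (x1 == 0 && x2 == 0)
    return(list(yLoewe = max(fit1@eMin, fit2@eMin), status = "ok"))
  if (x2 == 0)
    return(list(yLoewe = evaluateLogistic(fit1, x1), status = "ok"))
  if (x1 == 0)
    return(list(yLoewe = evaluateLogistic(fit2, x2), status = "ok"))

  lo <- max(fit1@eMin, fit2@eMin)
  hi <- min(fit1@eMax, fit2@eMax)
  if (hi <= lo) return(list(yLoewe = NA_real_, status = "unreachable"))
  eps <- (hi - lo) * 1e-12
  g <- function(y) {
    x1 / inverseLogistic(fit1, y, strict = FALSE) +
      x2 / inverseLogistic(fit2, y, strict = FALSE) - 1
  }
  yHi <- hi - eps
  if (g(yHi) > 0)  # even the strongest reachable effect needs too much dose
    return(list(yLoewe = NA_real_, status = "unreachable"))
  a <- lo + eps; b <- yHi
  for (i in seq_len(maxIter)) {
    mid <- (a + b) / 2
    if (g(mid) > 0) a <- mid else b <- mid
    if ((b - a) < tol)
      return(list(yLoewe = (a + b) / 2, status = "ok"))
  }
  list(yLoewe = (a + b) / 2, status = "no-convergence")
}

#' Combination Index (CI)
#'
#' The sum of observed-dose to equipotent-dose ratios,
#' `CI = x1 / D1(yc) + x2 / D2(yc)`, where `D_i(yc)` is the dose of drug
#' `i` alone producing the observed combination effect `yc`. `CI < 1`
#' indicates Loewe synergy, `CI = 1` additivity, `CI > 1` antagonism.
#' `NA` is returned when `yc` is unreachable for either single-agent curve.
#'
#' @inheritParams loeweExpected
#' @param x1,x2 combination doses (> 0).
#' @param yc observed combination effect (fractional inhibition).
#' @return the CI, or `NA_real_` when undefined.
#' @examples
#' f <- logisticFit(m = 1, lambda = 1)
#' combinationIndex(f, f, 0.5, 0.5, yc = 0.5)  # additive: 1
#' @export
combinationIndex <- function(fit1, fit2, x1, x2, yc) {
  stopifnot(is(fit1, "LogisticFit"), is(fit2, "LogisticFit"),
            is.numeric(x1), is.numeric(x2), x1 > 0, x2 > 0, is.numeric(yc))
  d1 <- inverseLogistic(fit1, yc, strict = FALSE)
  d2 <- inverseLogistic(fit2, yc, strict = FALSE)
  ifelse(is.na(d1) | is.na(d2), NA_real_, x1 / d1 + x2 / d2)
}

#' Interaction index alpha
#'
#' The interaction parameter of the extended isobole equation
#' \deqn{1 = x_1/D_1(y_c) + x_2/D_2(y_c) +
#'       \alpha\, x_1 x_2 / (G_1(y_c)\, G_2(y_c)),}
#' where `D_i` is the single-agent dose producing `yc` and
#' `G_i(yc) = m_i ((yc - eMin_i)/(eMax_i - yc))^(1/(2 lambda_i))` are the
#' half-exponent dose terms. Solved in closed form for `alpha`.
#' `alpha = 0` is equivalent to `CI = 1` (additivity); `alpha > 0`
#' indicates synergy (`CI < 1`) and `alpha < 0` antagonism.
#'
#' @inheritParams combinationIndex
#' @return alpha, or `NA_real_` when `yc` is unreachable for either curve.
#' @examples
#' f <- logisticFit(m = 1, lambda = 1)
#' interactionAlpha(f, f, 1, 1, yc = 0.75)  # 1
#' @export
interactionAlpha <- function(fit1, fit2, x1, x2, yc) {
  stopifnot(is(fit1, "LogisticFit"), is(fit2, "LogisticFit"),
            is.numeric(x1), is.numeric(x2), x1 > 0, x2 > 0, is.numeric(yc))
  d1 <- inverseLogistic(fit1, yc, strict = FALSE)
  d2 <- inverseLogistic(fit2, yc, strict = FALSE)
  if (any(is.na(d1) | is.na(d2))) return(rep(NA_real_, length(yc))[seq_along(yc)])
  g1 <- fit1@m * ((yc - fit1@eMin) / (fit1@eMax - yc))^(1 / (2 * fit1@lambda))
  g2 <- fit2@m * ((yc - fit2@eMin) / (fit2@eMax - yc))^(1 / (2 * fit2@lambda))
  (1 - x1 / d1 - x2 / d2) / (x1 * x2 / (g1 * g2))
}
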