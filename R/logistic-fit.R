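#' @include AllClasses.R
NULL

# Stable 4PL evaluation: t/(1+t) with t = (x/m)^lambda is plogis(lambda *
# (log x - log m)), which never overflows and is exactly 0 at dose 0.
.logistic4 <- function(dose, eMin, eMax, m, lambda) {
  y <- rep(eMin, length(dose))
  pos <- dose > 0
  y[pos] <- eMin + (eMax - eMin) * stats::plogis(lambda * (log(dose[pos]) - log(m)))
  y
}

.evalFallback <- function(fit, dose) {
  y <- stats::approx(fit@fallbackDoses, fit@fallbackResponses, xout = dose,
                     rule = 2, ties = mean)$y
  pmin(pmax(y, 0), 1)
}

#' Evaluate a fitted dose-response curve
#'
#' Returns the fractional inhibition predicted at the given dose(s). For a
#' converged fit this is the log-logistic curve
#' \eqn{(E_{min} + E_{max} (x/m)^\lambda) / (1 + (x/m)^\lambda)}; at dose 0
#' the `(x/m)^\lambda` term vanishes and the value is exactly `eMin`. For a
#' fallback fit the observed responses are interpolated piecewise-linearly
#' and clamped to \[0, 1\].
#'
#' @param fit a [LogisticFit-class] (or [ConditionalFit-class]).
#' @param dose numeric vector of concentrations (>= 0).
#' @return numeric vector of fractional inhibition values.
#' @examples
#' fit <- logisticFit(eMax = 1, m = 2, lambda = 1)
#' evaluateLogistic(fit, c(0, 2, 1e6))
#' @export
evaluateLogistic <- function(fit, dose) {
  stopifnot(is(fit, "LogisticFit"), is.numeric(dose), all(dose >= 0))
  if (!fit@converged && length(fit@fallbackDoses) >= 2L)
    return(.evalFallback(fit, dose))
  .logistic4(dose, fit@eMin, fit@eMax, fit@m, fit@lambda)
}

#' Median-effect odds of a fitted curve
#'
#' The odds of the affected fraction, `(y - eMin) / (eMax - y)`, which for
#' a log-logistic curve equals `(x/m)^lambda` (the median-effect form of
#' the mass-action law).
#'
#' @inheritParams evaluateLogistic
#' @param dose a positive concentration.
#' @return dimensionless odds.
#' @examples
#' medianEffectOdds(logisticFit(m = 1, lambda = 2), 3)  # 9
#' @export
medianEffectOdds <- function(fit, dose) {
  stopifnot(is(fit, "LogisticFit"), is.numeric(dose), all(dose > 0))
  y <- evaluateLogistic(fit, dose)
  if (any(y >= fit@eMax))
    stop("median-effect odds undefined: effect at or above eMax")
  if (!fit@converged && length(fit@fallbackDoses) >= 2L)
    return((y - fit@eMin) / (fit@eMax - y))
  # analytically (y - eMin)/(eMax - y) = (x/m)^lambda; the power form stays
  # exact where the ratio would lose precision near saturation
  exp(fit@lambda * (log(dose) - log(fit@m)))
}

#' Invert a fitted dose-response curve
#'
#' Returns the dose producing a given effect,
#' `m * ((y - eMin) / (eMax - y))^(1/lambda)`. Effects at or outside the
#' open band `(eMin, eMax)` are unreachable by the curve; by default this
#' raises a classed error (`zipscore_unreachable_effect`), or returns `NA`
#' when `strict = FALSE`. This unreachability is exactly what limits
#' Loewe-based scores when a combination outperforms a weakly effective
#' single drug.
#'
#' @inheritParams evaluateLogistic
#' @param effect fractional inhibition, strictly inside `(eMin, eMax)`.
#' @param strict raise on unreachable effects (default) or return `NA`.
#' @return concentration(s) on the scale of the input doses.
#' @examples
#' inverseLogistic(logisticFit(m = 5, lambda = 2), 0.5)  # 5
#' @export
inverseLogistic <- function(fit, effect, strict = TRUE) {
  stopifnot(is(fit, "LogisticFit"), is.numeric(effect))
  bad <- effect <= fit@eMin | effect >= fit@eMax
  if (any(bad) && strict) {
    stop(structure(
      class = c("zipscore_unreachable_effect", "error", "condition"),
      list(message = sprintf(
        "effect %s unreachable: curve band is (%.4g, %.4g)",
        paste(format(effect[bad]), collapse = ", "), fit@eMin, fit@eMax),
        call = sys.call(-1))))
  }
  x <- rep(NA_real_, length(effect))
  ok <- !bad
  x[ok] <- fit@m * ((effect[ok] - fit@eMin) / (fit@eMax - effect[ok]))^(1 / fit@lambda)
  x
}

# Standard errors of the freely fitted parameters from the Jacobian of the
# model at the solution: cov = sigma^2 (J'J)^-1 with sigma^2 = rss/(n - p).
.fitSe <- function(doses, responses, eMin, eMax, m, lambda, free, rss) {
  n <- length(doses); p <- length(free)
  if (n <= p) return(setNames(rep(0, p), free))
  pars <- c(eMin = eMin, eMax = eMax, m = m, lambda = lambda)
  J <- sapply(free, function(nm) {
    h <- max(abs(pars[nm]) * 1e-5, 1e-8)
    up <- pars; up[nm] <- up[nm] + h
    dn <- pars; dn[nm] <- dn[nm] - h
    (.logistic4(doses, up["eMin"], up["eMax"], up["m"], up["lambda"]) -
     .logistic4(doses, dn["eMin"], dn["eMax"], dn["m"], dn["lambda"])) / (2 * h)
  })
  J <- matrix(J, nrow = n)
  sigma2 <- rss / (n - p)
  JtJ <- crossprod(J)
  s <- svd(JtJ)
  pos <- s$d > max(s$d) * 1e-12
  inv <- s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  v <- diag(inv) * sigma2
  setNames(sqrt(pmax(v, 0)), free)
}

# Core bounded least-squares fit of the 4PL curve. Optimization runs on
# log10(m) and log10(lambda); dose 0 enters the objective through the
# analytic baseline value, never through a log transform.
.fitLogisticCore <- function(doses, responses, eMinFixed = 0, eMaxFixed = NULL) {
  n <- length(doses)
  pos <- doses > 0
  loM <- log10(min(doses[pos]) / 100)
  hiM <- log10(max(doses) * 100)
  loL <- log10(0.05); hiL <- 1  # lambda in [0.05, 10]
  freeEMin <- is.null(eMinFixed)
  freeEMax <- is.null(eMaxFixed)
  rng <- range(responses)

  # deterministic initialization: m from linear interpolation of the dose
  # reaching half the observed response range; lambda = 1
  m0 <- {
    yhalf <- mean(rng)
    idx <- which(responses >= yhalf & seq_len(n) > 1L)
    if (diff(rng) < 1e-8 || length(idx) == 0L) {
      max(doses) * 10
    } else {
      i <- min(idx)
      x0 <- doses[i - 1L]; x1 <- doses[i]
      y0 <- responses[i - 1L]; y1 <- responses[i]
      if (abs(y1 - y0) < 1e-12) x1 else x0 + (yhalf - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  m0 <- min(max(m0, 10^loM * 1.001, 1e-300), 10^hiM * 0.999)

  unpack <- function(p) {
    i <- 1L
    eMn <- if (freeEMin) { v <- p[i]; i <- i + 1L; v } else eMinFixed
    eMx <- if (freeEMax) { v <- p[i]; i <- i + 1L; v } else eMaxFixed
    c(eMn, eMx, 10^p[i], 10^p[i + 1L])
  }
  obj <- function(p) {
    q <- unpack(p)
    if (q[1] >= q[2]) return(1e10)
    sum((responses - .logistic4(doses, q[1], q[2], q[3], q[4]))^2)
  }
  p0 <- c(if (freeEMin) max(min(rng), 0),
          if (freeEMax) min(max(max(responses), 0.05), 1),
          log10(m0), 0)
  lower <- c(if (freeEMin) 0, if (freeEMax) 1e-6, loM, loL)
  upper <- c(if (freeEMin) 1 - 1e-6, if (freeEMax) 1, hiM, hiL)

  # one polish restart; a restart at an already-converged minimum may abort
  # the line search, so convergence is granted if either pass succeeded and
  # the better parameter vector is kept
  o <- tryCatch({
    o1 <- stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                       upper = upper, control = list(maxit = 500, factr = 1e2))
    o2 <- tryCatch(
      stats::optim(o1$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500, factr = 1e2)),
      error = function(e) NULL)
    best <- if (!is.null(o2) && o2$value <= o1$value) o2 else o1
    best$convergence <- if (o1$convergence == 0 ||
                            (!is.null(o2) && o2$convergence == 0)) 0L else 1L
    best
  }, error = function(e) NULL)

  # convergence is judged by fit adequacy, not by the solver's exit code
  # (L-BFGS-B reports a failed line search on objectives that are flat at
  # the minimum): accept when the curve explains the data at least as well
  # as a constant, or leaves residuals within typical assay noise
  # (rms <= 0.1 inhibition). A pinned baseline can make the flat benchmark
  # unbeatable on nearly flat series, hence the second clause; genuinely
  # inverted or erratic rows fail both and get the interpolation fallback.
  tss <- sum((responses - mean(responses))^2)
  ok <- !is.null(o) &&
    (o$value <= tss * (1 + 1e-8) + 1e-9 || sqrt(o$value / n) <= 0.1)
  q <- if (!is.null(o)) unpack(o$par) else c(eMinFixed %||% 0, eMaxFixed %||% 1, m0, 1)
  if (q[1] >= q[2]) q[2] <- min(q[1] + 1e-6, 1)
  free <- c(if (freeEMin) "eMin", if (freeEMax) "eMax", "m", "lambda")
  rss <- if (!is.null(o)) o$value else sum((responses - mean(responses))^2)
  se <- if (ok) .fitSe(doses, responses, q[1], q[2], q[3], q[4], free, rss)
        else setNames(rep(NA_real_, length(free)), free)
  list(eMin = q[1], eMax = q[2], m = q[3], lambda = q[4],
       rss = rss, converged = ok, se = se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a log-logistic dose-response curve
#'
#' Bounded least-squares fit of the 4PL curve to dose-response points. The
#' default monotherapy configuration fixes the baseline at `eMinFixed = 0`
#' and fits the maximal effect freely in (0, 1\], so weakly effective drugs
#' remain representable; pass `eMinFixed = NULL` for a full four-parameter
#' fit. Bounds keep the solver on realistic curves: `m` within
#' \[min positive dose / 100, max dose x 100\] and `lambda` within
#' \[0.05, 10\]. Initialization is deterministic (midpoint-dose
#' interpolation, `lambda = 1`); there are no random restarts.
#'
#' Responses outside \[0, 1\] are used as observed (never clamped); only
#' fitted curves are bounded. The fit never errors on irregular data:
#' when the optimizer fails, or the best curve both explains the data
#' worse than a constant and leaves residuals beyond typical assay noise
#' (as on an inverted, decreasing response row), the returned object is
#' flagged `converged = FALSE` and evaluates by piecewise-linear
#' interpolation of the observations clamped to \[0, 1\].
#'
#' @param doses concentrations (>= 0, distinct, at most one zero which must
#'   come first once sorted).
#' @param responses fractional inhibition values, same length as `doses`.
#' @param eMinFixed fixed baseline effect, or `NULL` to fit it.
#' @param eMaxFixed fixed maximal effect, or `NULL` (default) to fit it.
#' @return a [LogisticFit-class].
#' @examples
#' d <- c(0, 10^seq(-1, 1, 0.5))
#' y <- evaluateLogistic(logisticFit(m = 1, lambda = 2), d)
#' fitLogistic(d, y)
#' @export
fitLogistic <- function(doses, responses, eMinFixed = 0, eMaxFixed = NULL) {
  if (!is.numeric(doses) || !is.numeric(responses) ||
      length(doses) != length(responses) || length(doses) < 2L ||
      any(!is.finite(doses)) || any(!is.finite(responses)))
    stop("need >= 2 finite dose-response points of equal length")
  if (any(doses < 0)) stop("doses must be >= 0")
  if (sum(doses == 0) > 1L) stop("at most one zero dose is allowed")
  if (anyDuplicated(doses)) stop("doses must be distinct")
  ord <- order(doses)
  doses <- doses[ord]; responses <- responses[ord]
  if (all(doses == 0)) stop("at least one positive dose is required")

  f <- .fitLogisticCore(doses, responses, eMinFixed, eMaxFixed)
  new("LogisticFit",
      eMin = f$eMin, eMax = f$eMax, m = f$m, lambda = f$lambda,
      rss = f$rss, nPoints = length(doses), converged = f$converged,
      se = if (f$converged) f$se else numeric(0),
      fallbackDoses = if (f$converged) numeric(0) else doses,
      fallbackResponses = if (f$converged) numeric(0) else responses)
}
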