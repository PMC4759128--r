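#' @include AllGenerics.R
NULL

#' Accessors for fitted log-logistic curves and dose-response objects
#'
#' `eMin()`, `eMax()`, `potency()` and `shape()` return the four parameters
#' of a fitted log-logistic curve (baseline effect, maximal effect, midpoint
#' dose and slope). `isConverged()` reports whether the nonlinear fit
#' converged or the object carries the piecewise-linear fallback curve.
#'
#' @param object a `LogisticFit`, `ConditionalFit`, `DoseResponseMatrix`
#'   or `InteractionLandscape` object, as applicable.
#' @return a numeric scalar (parameter accessors), logical scalar
#'   (`isConverged`), numeric vector (`concRow`, `concCol`), character
#'   scalar (`drugRow`, `drugCol`, `blockId`) or matrix (`responseMatrix`,
#'   `deltaGrid`).
#' @name accessors
#' @aliases eMin eMax potency shape isConverged concRow concCol drugRow
#'   drugCol blockId responseMatrix deltaGrid
#' @examples
#' fit <- logisticFit(eMax = 1, m = 1, lambda = 2)
#' potency(fit)
#' shape(fit)
NULL

#' @rdname accessors
#' @export
setGeneric("eMin", function(object) standardGeneric("eMin"))

#' @rdname accessors
#' @export
setGeneric("eMax", function(object) standardGeneric("eMax"))

#' @rdname accessors
#' @export
setGeneric("potency", function(object) standardGeneric("potency"))

#' @rdname accessors
#' @export
setGeneric("shape", function(object) standardGeneric("shape"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("concRow", function(object) standardGeneric("concRow"))

#' @rdname accessors
#' @export
setGeneric("concCol", function(object) standardGeneric("concCol"))

#' @rdname accessors
#' @export
setGeneric("drugRow", function(object) standardGeneric("drugRow"))

#' @rdname accessors
#' @export
setGeneric("drugCol", function(object) standardGeneric("drugCol"))

#' @rdname accessors
#' @export
setGeneric("blockId", function(object) standardGeneric("blockId"))

#' @rdname accessors
#' @export
setGeneric("responseMatrix", function(object) standardGeneric("responseMatrix"))

#' @rdname accessors
#' @export
setGeneric("deltaGrid", function(object) standardGeneric("deltaGrid"))

#' Average delta score of an interaction landscape
#'
#' The summary interaction score of a combination block is the arithmetic
#' mean of the per-dose-pair delta values over the combination region
#' (monotherapy wells excluded).
#'
#' @param object an `InteractionLandscape`.
#' @param percent logical; report on the percentage-inhibition scale
#'   (multiplied by 100) instead of the inhibition-fraction scale.
#' @return numeric scalar.
#' @export
setGeneric("summaryDelta", function(object, percent = FALSE)
  standardGeneric("summaryDelta"))
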