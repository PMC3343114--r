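#' Accessors for percap classes
#'
#' Small accessor generics so that user code never touches slots directly:
#' `codingLevel()` and `lagCorrelation()` for [MarkovSpec-class],
#' `nPatterns()`, `nInputs()`, `inputMatrix()` and `targetStates()` for
#' [AssociationSequence-class], `weights()`, `converged()` and
#' `updateCount()` for [TrainResult-class], `thetaUp()`/`thetaDown()` for
#' [NeuronConfig-class], and `silentMass()` for [ReplicaSolution-class].
#'
#' @param object an object of the documented class.
#' @return the corresponding scalar, vector or matrix.
#' @name percap-accessors
#' @examples
#' sp <- markovSpec(f = 0.3, c = 0.6)
#' codingLevel(sp)
#' lagCorrelation(sp)
NULL

#' @rdname percap-accessors
#' @export
setGeneric("codingLevel", function(object) standardGeneric("codingLevel"))
#' @rdname percap-accessors
#' @export
setGeneric("lagCorrelation", function(object) standardGeneric("lagCorrelation"))
#' @rdname percap-accessors
#' @export
setGeneric("nPatterns", function(object) standardGeneric("nPatterns"))
#' @rdname percap-accessors
#' @export
setGeneric("nInputs", function(object) standardGeneric("nInputs"))
#' @rdname percap-accessors
#' @export
setGeneric("inputMatrix", function(object) standardGeneric("inputMatrix"))
#' @rdname percap-accessors
#' @export
setGeneric("targetStates", function(object) standardGeneric("targetStates"))
#' @rdname percap-accessors
#' @export
setGeneric("weights", function(object) standardGeneric("weights"))
#' @rdname percap-accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname percap-accessors
#' @export
setGeneric("updateCount", function(object) standardGeneric("updateCount"))
#' @rdname percap-accessors
#' @export
setGeneric("thetaUp", function(object) standardGeneric("thetaUp"))
#' @rdname percap-accessors
#' @export
setGeneric("thetaDown", function(object) standardGeneric("thetaDown"))
#' @rdname percap-accessors
#' @export
setGeneric("silentMass", function(object) standardGeneric("silentMass"))

#' @rdname percap-accessors
setMethod("codingLevel", "MarkovSpec", function(object) object@f)
#' @rdname percap-accessors
setMethod("lagCorrelation", "MarkovSpec", function(object) object@c)
#' @rdname percap-accessors
setMethod("nPatterns", "AssociationSequence",
          function(object) nrow(object@inputs))
#' @rdname percap-accessors
setMethod("nInputs", "AssociationSequence",
          function(object) ncol(object@inputs))
#' @rdname percap-accessors
setMethod("inputMatrix", "AssociationSequence", function(object) object@inputs)
#' @rdname percap-accessors
setMethod("targetStates", "AssociationSequence",
          function(object) object@targets)
#' @rdname percap-accessors
setMethod("weights", "TrainResult", function(object) object@weights)
#' @rdname percap-accessors
setMethod("converged", "TrainResult", function(object) object@converged)
#' @rdname percap-accessors
setMethod("updateCount", "TrainResult", function(object) object@updates)
#' @rdname percap-accessors
setMethod("thetaUp", "NeuronConfig",
          function(object) object@theta + object@delta / 2)
#' @rdname percap-accessors
setMethod("thetaDown", "NeuronConfig",
          function(object) object@theta - object@delta / 2)
#' @rdname percap-accessors
setMethod("silentMass", "ReplicaSolution",
          function(object) object@silentFraction)

setMethod("show", "MarkovSpec", function(object) {
  cat(sprintf("MarkovSpec: coding level f = %g, lag-1 correlation c = %g\n",
              object@f, object@c))
  tp <- transitionProbabilities(object)
  cat(sprintf("  P(active | active) = %g, P(active | inactive) = %g\n",
              tp[["activeGivenActive"]], tp[["activeGivenInactive"]]))
})

setMethod("show", "AssociationSequence", function(object) {
  cat(sprintf(
    "AssociationSequence: %d patterns x %d inputs (seed %d)\n",
    nPatterns(object), nInputs(object), object@seed))
  cat(sprintf("  input chain:  f = %g, c = %g\n",
              object@inputSpec@f, object@inputSpec@c))
  cat(sprintf("  output chain: f = %g, c = %g; %d/%d active targets\n",
              object@outputSpec@f, object@outputSpec@c,
              sum(object@targets), length(object@targets)))
})

setMethod("show", "NeuronConfig", function(object) {
  cat(sprintf(
    "NeuronConfig: N = %d, theta = %g, delta = %g (up %g / down %g), kappa = %g\n",
    object@N, object@theta, object@delta, thetaUp(object), thetaDown(object),
    object@kappa))
})

setMethod("show", "TrainResult", function(object) {
  cat(sprintf(
    "TrainResult: %s after %d epochs, %.0f updates, %d residual errors\n",
    if (object@converged) "converged" else "NOT converged",
    object@epochs, object@updates, object@finalErrors))
  w <- object@weights
  cat(sprintf("  weights: N = %d, mean = %.4g, max = %.4g, zero = %d\n",
              length(w), mean(w), max(w), sum(w == 0)))
})

setMethod("show", "ScaledParams", function(object) {
  cat(sprintf(
    "ScaledParams: deltaS = %g, kappaS = %g, fOut = %g, cOut = %g, fIn = %g (gamma = %g)\n",
    object@deltaS, object@kappaS, object@fOut, object@cOut, object@fIn,
    object@gamma))
})

setMethod("show", "ReplicaSolution", function(object) {
  cat(sprintf(
    "ReplicaSolution at alpha = %.6g%s\n", object@alpha,
    if (object@atCapacity) " (at capacity, q -> 1)" else ""))
  cat(sprintf("  q = %.6g, G = %.6g, s = %.6g, silent fraction = %.6g\n",
              object@q, object@G, object@s, object@silentFraction))
  cat(sprintf("  max |residual| = %.3g\n", max(abs(object@residuals))))
})

setMethod("show", "CapacityEstimate", function(object) {
  cat(sprintf(
    "CapacityEstimate: alpha = %.4f +/- %.4f (sd over %d trials), N = %d\n",
    object@alpha, object@spread, object@nTrials, object@N))
})

setMethod("show", "DivergenceFit", function(object) {
  cat(sprintf(
    "DivergenceFit: alpha(c) = %.4g + %.4g * (1-c)^(-%.4g)%s, rss = %.3g\n",
    object@A, object@B, object@beta,
    if (object@divergent) "" else " [no divergence detected]", object@rss))
})
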