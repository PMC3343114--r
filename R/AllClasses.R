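#' Two-state Markov stream specification
#'
#' A binary stream is parameterized by its coding level \code{f} (the
#' stationary probability that a unit is active) and its lag-1 correlation
#' \code{c} (the Pearson correlation between successive states).  The unique
#' two-state chain with these stationary moments has transition
#' probabilities \eqn{P(1|1) = f + c(1-f)} and \eqn{P(1|0) = f(1-c)}.
#'
#' @slot f numeric in (0,1); coding level.
#' @slot c numeric in [0,1]; lag-1 correlation.
#' @seealso [markovSpec()], [transitionProbabilities()], [pairProbabilities()]
#' @exportClass MarkovSpec
setClass("MarkovSpec",
  representation(f = "numeric", c = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@f) != 1L || !is.finite(object@f) ||
        object@f <= 0 || object@f >= 1)
      msg <- c(msg, "coding level 'f' must be a single value in (0, 1)")
    if (length(object@c) != 1L || !is.finite(object@c) ||
        object@c < 0 || object@c > 1)
      msg <- c(msg, "lag-1 correlation 'c' must be a single value in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' A sequence of input/output associations
#'
#' Holds a P x N binary input matrix (each column an independent realization
#' of the input Markov chain), the length-P binary target sequence (one
#' realization of the output chain), the two stream specifications and the
#' master seed used for generation.  Patterns are ordered: row \code{mu}
#' follows row \code{mu - 1} in time.
#'
#' @slot inputs integer matrix, P rows (patterns) x N columns (input cells),
#'   entries 0/1.
#' @slot targets integer vector of length P, entries 0/1.
#' @slot inputSpec,outputSpec [MarkovSpec-class] objects.
#' @slot seed integer master seed.
#' @seealso [generateAssociations()]
#' @exportClass AssociationSequence
setClass("AssociationSequence",
  representation(inputs = "matrix", targets = "integer",
                 inputSpec = "MarkovSpec", outputSpec = "MarkovSpec",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!all(object@inputs %in% c(0L, 1L)))
      msg <- c(msg, "'inputs' must contain only 0/1")
    if (!all(object@targets %in% c(0L, 1L)))
      msg <- c(msg, "'targets' must contain only 0/1")
    if (nrow(object@inputs) != length(object@targets))
      msg <- c(msg, "number of patterns and number of targets differ")
    if (length(msg)) msg else TRUE
  })

#' Threshold-unit configuration
#'
#' Describes the output unit: the number of inputs \code{N}, the firing
#' threshold \code{theta} (strictly positive), the bistable range
#' \code{delta} (width of the hysteresis region; the up and down thresholds
#' are placed symmetrically at \code{theta +/- delta/2}) and the robustness
#' margin \code{kappa}, measured in units of \eqn{\|w\|_2/\sqrt{N}}.
#'
#' @slot N integer, number of input synapses.
#' @slot theta numeric > 0, firing threshold.
#' @slot delta numeric >= 0, bistable range; \code{theta - delta/2} must
#'   remain positive.
#' @slot kappa numeric >= 0, robustness margin.
#' @seealso [neuronConfig()], [outputBistable()], [constraintMargins()]
#' @exportClass NeuronConfig
setClass("NeuronConfig",
  representation(N = "integer", theta = "numeric", delta = "numeric",
                 kappa = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@N < 1L) msg <- c(msg, "'N' must be >= 1")
    if (object@theta <= 0) msg <- c(msg, "'theta' must be strictly positive")
    if (object@delta < 0) msg <- c(msg, "'delta' must be nonnegative")
    if (object@kappa < 0) msg <- c(msg, "'kappa' must be nonnegative")
    if (object@theta - object@delta / 2 <= 0)
      msg <- c(msg, "lower threshold theta - delta/2 must stay positive")
    if (length(msg)) msg else TRUE
  })

#' Learning-rule configuration
#'
#' @slot eta numeric learning rate; \code{NA} means "choose automatically"
#'   (see [trainPerceptron()]).
#' @slot rule one of \code{"standard"}, \code{"bistable_switching"} (the
#'   error signal resets the output state to the target after an error) or
#'   \code{"bistable_nss"} (no state switching: the unit keeps its own,
#'   possibly wrong, previous output).
#' @slot maxEpochs integer epoch budget; one epoch is P presentations.
#' @slot seed integer seed for the presentation order.
#' @slot presentation \code{"random"} (uniform with replacement) or
#'   \code{"sequential"}.
#' @slot constrained logical; \code{TRUE} keeps weights nonnegative
#'   (excitatory synapses), \code{FALSE} removes the sign constraint.
#' @seealso [learnerConfig()], [trainPerceptron()]
#' @exportClass LearnerConfig
setClass("LearnerConfig",
  representation(eta = "numeric", rule = "character", maxEpochs = "integer",
                 seed = "integer", presentation = "character",
                 constrained = "logical"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@eta) && object@eta <= 0)
      msg <- c(msg, "'eta' must be positive (or NA for automatic)")
    if (!object@rule %in% c("standard", "bistable_switching", "bistable_nss"))
      msg <- c(msg, "unknown learning rule")
    if (object@maxEpochs < 1L) msg <- c(msg, "'maxEpochs' must be >= 1")
    if (!object@presentation %in% c("random", "sequential"))
      msg <- c(msg, "'presentation' must be 'random' or 'sequential'")
    if (length(msg)) msg else TRUE
  })

#' Result of training a perceptron
#'
#' @slot weights numeric length-N learned weight vector (nonnegative when
#'   the sign constraint is active).
#' @slot converged logical; \code{TRUE} iff a full error-free evaluation was
#'   reached within the epoch budget.
#' @slot updates numeric; number of error-driven weight changes (presented
#'   patterns for which a change had to be made).
#' @slot epochs integer; epochs actually used.
#' @slot finalErrors integer; number of violated constraints at the last
#'   evaluation (0 when converged).
#' @slot errorTrace numeric; violated-constraint count after each epoch.
#' @exportClass TrainResult
setClass("TrainResult",
  representation(weights = "numeric", converged = "logical",
                 updates = "numeric", epochs = "integer",
                 finalErrors = "integer", errorTrace = "numeric"),
  validity = function(object) {
    if (object@converged && object@finalErrors != 0L)
      return("a converged result must have zero final errors")
    TRUE
  })

#' Scaled (size-independent) parameters for the replica theory
#'
#' In the large-N limit with a fixed threshold the synaptic weights scale
#' as 1/N while the bistable range and the robustness margin scale as
#' \eqn{1/\sqrt{N}}.  The theory is therefore expressed in reduced units:
#' \code{deltaS} \eqn{= \Delta\sqrt{N}/\theta} and \code{kappaS}
#' \eqn{= \kappa_{abs}\sqrt{N}/\theta} (with \eqn{\kappa_{abs}} the margin in
#' drive units).  \code{gamma} is the threshold in the same reduced units; it
#' is a pure gauge for the capacity and distribution and defaults to 1.
#'
#' @slot gamma numeric > 0 scaled threshold (gauge).
#' @slot deltaS numeric >= 0 scaled bistable range.
#' @slot kappaS numeric >= 0 scaled robustness.
#' @slot fOut,cOut numeric; output coding level in (0,1) and output lag-1
#'   correlation in [0,1).
#' @slot fIn numeric; input coding level in (0,1).  The theory assumes
#'   uncorrelated inputs.
#' @seealso [scaledParams()], [capacityReplica()]
#' @exportClass ScaledParams
setClass("ScaledParams",
  representation(gamma = "numeric", deltaS = "numeric", kappaS = "numeric",
                 fOut = "numeric", cOut = "numeric", fIn = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@gamma <= 0) msg <- c(msg, "'gamma' must be positive")
    if (object@deltaS < 0) msg <- c(msg, "'deltaS' must be nonnegative")
    if (object@kappaS < 0) msg <- c(msg, "'kappaS' must be nonnegative")
    if (object@fOut <= 0 || object@fOut >= 1)
      msg <- c(msg, "'fOut' must be in (0,1)")
    if (object@fIn <= 0 || object@fIn >= 1)
      msg <- c(msg, "'fIn' must be in (0,1)")
    if (object@cOut < 0 || object@cOut >= 1)
      msg <- c(msg, "'cOut' must be in [0,1)")
    if (length(msg)) msg else TRUE
  })

#' Replica-symmetric saddle-point solution
#'
#' Order parameters of the replica-symmetric solution at load
#' \code{alpha}: the normalized replica overlap \code{q} (self-overlap
#' gauge-fixed to 1), the threshold offset \code{G} (distance from the mean
#' drive to the central threshold in drive-standard-deviation units) and the
#' silent-fraction parameter \code{s} such that the zero-weight mass at
#' capacity is \eqn{\Phi(s)}.
#'
#' @slot params the [ScaledParams-class] solved.
#' @slot alpha numeric load P/N at which the equations were solved.
#' @slot atCapacity logical; \code{TRUE} for solutions of the vanishing
#'   volume (q -> 1) system.
#' @slot q,G,s numeric order parameters (at capacity \code{q} is exactly 1).
#' @slot silentFraction numeric; zero-weight probability mass implied by
#'   \code{s}.
#' @slot orderParams list of auxiliary quantities (conjugate parameters,
#'   per-class constraint margins \code{b}, pair-class weights, ...).
#' @slot residuals numeric; residuals of the saddle equations at the
#'   returned point.
#' @exportClass ReplicaSolution
setClass("ReplicaSolution",
  representation(params = "ScaledParams", alpha = "numeric",
                 atCapacity = "logical", q = "numeric", G = "numeric",
                 s = "numeric", silentFraction = "numeric",
                 orderParams = "list", residuals = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@q < 0 || object@q > 1 + 1e-12)
      msg <- c(msg, "'q' must lie in [0, 1]")
    if (object@silentFraction < 0 || object@silentFraction > 1)
      msg <- c(msg, "'silentFraction' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Simulated capacity estimate
#'
#' @slot alpha numeric; mean maximal load P/N over trials.
#' @slot spread numeric; standard deviation over trials.
#' @slot perTrial numeric; per-trial capacities.
#' @slot nTrials,N integers.
#' @slot protocol list of protocol metadata (bisection resolution, load
#'   ceiling, budget-exhaustion and non-convergence flags, seeds).
#' @exportClass CapacityEstimate
setClass("CapacityEstimate",
  representation(alpha = "numeric", spread = "numeric", perTrial = "numeric",
                 nTrials = "integer", N = "integer", protocol = "list"),
  validity = function(object) {
    if (object@alpha < 0 || object@spread < 0)
      return("'alpha' and 'spread' must be nonnegative")
    TRUE
  })

#' Fit of the capacity divergence law
#'
#' Parameters of the least-squares fit \eqn{\alpha(c) = A + B (1-c)^{-\beta}}
#' describing how the capacity grows as the common input/output correlation
#' \code{c} approaches 1.
#'
#' @slot A,B,beta numeric fitted parameters.
#' @slot residuals numeric fit residuals.
#' @slot rss numeric residual sum of squares.
#' @slot divergent logical; \code{FALSE} flags the degenerate branch
#'   (\code{B} or \code{beta} indistinguishable from 0, i.e. no divergence).
#' @exportClass DivergenceFit
setClass("DivergenceFit",
  representation(A = "numeric", B = "numeric", beta = "numeric",
                 residuals = "numeric", rss = "numeric",
                 divergent = "logical"))
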