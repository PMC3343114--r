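#' Create a learning-rule configuration
#'
#' @param eta learning rate; `NA` (default) picks a conservative rate at
#'   training time: the smaller of [safeLearningRate()] (with a relative
#'   feasibility margin of one tenth of the threshold and the realized
#'   maximal active fraction of the sequence) and
#'   \eqn{0.01\,\theta/(N f_{in})}.
#' @param rule `"standard"`, `"bistable_switching"` or `"bistable_nss"`.
#' @param maxEpochs epoch budget (one epoch = P presentations).
#' @param seed seed for the presentation order.
#' @param presentation `"random"` (uniform with replacement, the default)
#'   or `"sequential"`.  The no-state-switching rule always sweeps
#'   sequentially because its output state is carried across patterns.
#' @param constrained keep weights nonnegative (`TRUE`, excitatory
#'   synapses) or remove the sign constraint (`FALSE`).
#' @return a [LearnerConfig-class].
#' @export
learnerConfig <- function(eta = NA_real_,
                          rule = c("standard", "bistable_switching",
                                   "bistable_nss"),
                          maxEpochs = 500L, seed = 1L,
                          presentation = c("random", "sequential"),
                          constrained = TRUE) {
  rule <- match.arg(rule)
  presentation <- match.arg(presentation)
  new("LearnerConfig", eta = as.numeric(eta), rule = rule,
      maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
      presentation = presentation, constrained = isTRUE(constrained))
}

#' One error-driven weight update
#'
#' The perceptron rule with a hard lower bound at zero:
#' \deqn{w_i \leftarrow \max(0,\; w_i + \eta (y_t - y) x_i).}
#' Nothing changes when the produced output equals the target or the input
#' is silent.  With `constrained = FALSE` the clipping is removed.
#'
#' @param w weight vector.
#' @param x binary input vector.
#' @param y produced output (0/1).
#' @param yTarget target output (0/1).
#' @param eta learning rate.
#' @param constrained clip at zero (default `TRUE`).
#' @return updated weight vector.
#' @examples
#' applyUpdate(c(0.1, 0), c(1, 1), y = 1, yTarget = 0, eta = 0.5)  # LTD, clipped
#' @export
applyUpdate <- function(w, x, y, yTarget, eta, constrained = TRUE) {
  out <- w + eta * (yTarget - y) * x
  if (constrained) out <- pmax(0, out)
  out
}

#' A learning rate guaranteeing convergence on feasible sequences
#'
#' Suppose some nonnegative weight vector satisfies every pattern
#' constraint with absolute margin \eqn{\delta_m} (in drive units) and at
#' most a fraction \eqn{a} of inputs is active in any pattern.  Comparing
#' the squared distance to that solution before and after an error-driven
#' step (clipping at zero is a projection onto a convex set containing the
#' solution, so it never increases the distance) shows the distance
#' decreases by at least \eqn{2\eta\delta_m - \eta^2 a N} per update.  Any
#' \eqn{\eta < 2\delta_m/(aN)} therefore guarantees convergence in finitely
#' many updates; this function returns the midpoint
#' \deqn{\eta_{safe} = \delta_m / (a N),}
#' for which the number of error-driven updates is bounded by
#' \eqn{\|w^*\|^2 a N / \delta_m^2}.  The rate scales as \eqn{1/N} at fixed
#' threshold and margin: order-1/N synaptic changes are the price of
#' reaching maximal capacity.
#'
#' @param neuron a [NeuronConfig-class] (supplies N).
#' @param feasibilityMargin absolute margin \eqn{\delta_m > 0} in drive
#'   units, e.g. the optimal slack reported by [feasibleSequence()].
#' @param maxActiveFraction maximal fraction of simultaneously active
#'   inputs, in (0, 1].
#' @return positive learning rate.
#' @export
safeLearningRate <- function(neuron, feasibilityMargin, maxActiveFraction) {
  stopifnot(is(neuron, "NeuronConfig"),
            feasibilityMargin > 0, maxActiveFraction > 0,
            maxActiveFraction <= 1)
  feasibilityMargin / (maxActiveFraction * neuron@N)
}

## Default eta: conservative, proof-compatible, practical runtimes.  The
## coefficient 0.01 keeps the drive change caused by one update
## (~ eta * fin^2 * N) below the typical constraint margin near capacity;
## coarser rates stall well short of the maximal load (see the methods
## vignette for the step-size-versus-margin analysis).
defaultLearningRate <- function(seqs, neuron) {
  N <- neuron@N
  fin <- seqs@inputSpec@f
  aMax <- max(max(rowSums(seqs@inputs)), 1) / N
  min(safeLearningRate(neuron, 0.1 * neuron@theta, aMax),
      0.01 * neuron@theta / (N * fin))
}

#' Train a perceptron on an association sequence
#'
#' Starts from all-zero weights and presents patterns until a full exact
#' evaluation finds no violated constraint (converged) or the epoch budget
#' is exhausted (reported, not an error).  The three rules differ in how
#' the bistable state enters:
#' \describe{
#'   \item{standard}{plain threshold unit, constraint \eqn{h \gtrless
#'     \theta} per target.}
#'   \item{bistable_switching}{the previous \emph{target} serves as the
#'     reference state: after any error the error signal switches the
#'     output to the target, so the state preceding each pattern is always
#'     correct.  Constraints use \eqn{\theta_{up}} or \eqn{\theta_{down}}
#'     according to the previous target (teacher forcing).}
#'   \item{bistable_nss}{no state switching: the unit keeps its own,
#'     possibly wrong, previous output.  Sequential sweeps; convergence is
#'     judged by free-run replay.}
#' }
#'
#' @param seqs an [AssociationSequence-class].
#' @param neuron a [NeuronConfig-class]; `neuron@N` must equal the number
#'   of input columns.
#' @param learner a [LearnerConfig-class].
#' @return a [TrainResult-class].
#' @examples
#' seqs <- generateAssociations(markovSpec(0.5), markovSpec(0.5),
#'                              N = 30, P = 15, seed = 7)
#' trainPerceptron(seqs, neuronConfig(30), learnerConfig(seed = 7))
#' @export
trainPerceptron <- function(seqs, neuron, learner = learnerConfig()) {
  stopifnot(is(seqs, "AssociationSequence"), is(neuron, "NeuronConfig"),
            is(learner, "LearnerConfig"))
  if (nInputs(seqs) != neuron@N)
    stop("neuron@N does not match the number of input cells")
  eta <- learner@eta
  if (is.na(eta)) eta <- defaultLearningRate(seqs, neuron)
  rule <- match(learner@rule,
                c("standard", "bistable_switching", "bistable_nss")) - 1L
  sequential <- learner@presentation == "sequential" || rule == 2L
  old <- saveRNGState(); on.exit(restoreRNGState(old))
  set.seed(learner@seed)
  res <- .train_cpp(t(seqs@inputs), seqs@targets, neuron@theta,
                    neuron@delta, neuron@kappa, eta, rule,
                    learner@maxEpochs, sequential, learner@constrained)
  new("TrainResult", weights = res$weights, converged = res$converged,
      updates = res$updates, epochs = as.integer(res$epochs),
      finalErrors = as.integer(res$final_errors),
      errorTrace = res$error_trace)
}
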