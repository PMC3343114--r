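#' Create a threshold-unit configuration
#'
#' @param N number of input synapses.
#' @param theta firing threshold (> 0).
#' @param delta bistable range \eqn{\Delta = \theta_{up} - \theta_{down}};
#'   the two switching thresholds are placed symmetrically at
#'   \eqn{\theta \pm \Delta/2}.  `delta = 0` gives a standard unit.
#' @param kappa robustness margin in units of \eqn{\|w\|_2/\sqrt{N}}.
#' @return a [NeuronConfig-class].
#' @examples
#' neuronConfig(100, theta = 1, delta = 0.2)
#' @export
neuronConfig <- function(N, theta = 1, delta = 0, kappa = 0) {
  new("NeuronConfig", N = as.integer(N), theta = as.numeric(theta),
      delta = as.numeric(delta), kappa = as.numeric(kappa))
}

#' Synaptic drive of an input pattern
#'
#' @param w nonnegative weight vector.
#' @param x binary input vector of the same length.
#' @return the weighted input sum \eqn{h = \sum_i w_i x_i}.
#' @export
drive <- function(w, x) {
  if (length(w) != length(x)) stop("'w' and 'x' have different lengths")
  sum(w * x)
}

#' Output of the standard threshold unit
#'
#' Fires (returns 1) iff the drive strictly exceeds the threshold; a drive
#' exactly at threshold gives 0 (the Heaviside convention with
#' \eqn{\Theta(0) = 0}).
#'
#' @param h synaptic drive (may be a vector).
#' @param config a [NeuronConfig-class].
#' @return integer 0/1 of the same length as `h`.
#' @export
outputStandard <- function(h, config) {
  as.integer(h > config@theta)
}

#' Output of the bistable (hysteretic) unit
#'
#' If the previous output is 0, the unit switches to 1 only when the drive
#' exceeds the upper threshold \eqn{\theta_{up} = \theta + \Delta/2}; if the
#' previous output is 1, it switches to 0 only when the drive falls below
#' the lower threshold \eqn{\theta_{down} = \theta - \Delta/2}.  Drives
#' inside the bistable range leave the state unchanged.  With `delta = 0`
#' this reduces exactly to [outputStandard()].
#'
#' @param h synaptic drive (vectorized).
#' @param previous previous output state, 0 or 1 (recycled).
#' @param config a [NeuronConfig-class].
#' @return integer 0/1.
#' @export
outputBistable <- function(h, previous, config) {
  up <- thetaUp(config); dn <- thetaDown(config)
  n <- max(length(h), length(previous))
  h <- rep_len(h, n); previous <- rep_len(previous, n)
  out <- integer(n)
  fromUp <- previous == 1L
  out[fromUp] <- as.integer(h[fromUp] >= dn)   # stays 1 unless below theta_down
  out[!fromUp] <- as.integer(h[!fromUp] > up)  # switches up only above theta_up
  out
}

#' Margin scale for the robustness constraint
#'
#' The robustness `kappa` is measured in scale-invariant units of
#' \eqn{\|w\|_2 / \sqrt{N}}, so a classification counts as robust only if
#' the drive clears the relevant threshold by at least
#' `kappa * marginScale(w)`.
#'
#' @param w weight vector.
#' @return numeric scalar \eqn{\|w\|_2/\sqrt{N}}.
#' @export
marginScale <- function(w) sqrt(sum(w^2) / length(w))

#' Signed slacks of the learning constraints
#'
#' For each pattern the constraint the weight vector must satisfy depends
#' on the target and, for a bistable unit, on the previous target: with
#' \eqn{\theta_{eff} = \theta_{up}} when the previous target is 0 and
#' \eqn{\theta_{down}} when it is 1, the slack is
#' \eqn{h - \theta_{eff} - \kappa s} for target 1 and
#' \eqn{\theta_{eff} - h - \kappa s} for target 0, where
#' `s = marginScale(w)`.  The first pattern has no predecessor; under the
#' default `"midpoint"` rule it is constrained against the central
#' threshold \eqn{\theta}, under `"unconstrained"` its slack is `Inf`.
#'
#' A sequence is learned iff all slacks are positive (`kappa = 0`) or
#' nonnegative (`kappa > 0`).
#'
#' @param w nonnegative weight vector.
#' @param seqs an [AssociationSequence-class].
#' @param config a [NeuronConfig-class].
#' @param firstPatternRule `"midpoint"` or `"unconstrained"`.
#' @return numeric vector of length P with attributes `target` and
#'   `previousTarget` (the latter `NA` for the first pattern); see
#'   [marginsTable()] for a tabular view.
#' @export
constraintMargins <- function(w, seqs, config,
                              firstPatternRule = c("midpoint",
                                                   "unconstrained")) {
  firstPatternRule <- match.arg(firstPatternRule)
  stopifnot(is(seqs, "AssociationSequence"), is(config, "NeuronConfig"))
  if (length(w) != nInputs(seqs))
    stop("weight vector length does not match the number of inputs")
  y <- seqs@targets
  P <- length(y)
  h <- as.numeric(seqs@inputs %*% w)
  ks <- config@kappa * marginScale(w)
  prev <- c(NA_integer_, y[-P])
  thetaEff <- c(config@theta,
                ifelse(y[-P] == 1L, thetaDown(config), thetaUp(config)))
  slack <- ifelse(y == 1L, h - thetaEff - ks, thetaEff - h - ks)
  if (firstPatternRule == "unconstrained") slack[1L] <- Inf
  structure(slack, target = y, previousTarget = prev)
}

#' Tabulate constraint margins
#'
#' @param slack result of [constraintMargins()].
#' @return data.frame with columns `pattern`, `target`, `previousTarget`,
#'   `slack`, suitable for CSV export.
#' @export
marginsTable <- function(slack) {
  data.frame(pattern = seq_along(slack),
             target = attr(slack, "target"),
             previousTarget = attr(slack, "previousTarget"),
             slack = as.numeric(slack))
}

#' Replay a learned sequence through the unit dynamics
#'
#' Runs the sequence through the unit in temporal order.  In free-run mode
#' (`teacherForced = FALSE`) the bistable unit carries its own previous
#' output; in teacher-forced mode the previous *target* is used as the
#' reference state, as during training with the state-switching rule.  The
#' first pattern is evaluated against the central threshold (the two
#' switching thresholds coincide there, "midpoint" rule).
#'
#' @param w weight vector.
#' @param seqs an [AssociationSequence-class].
#' @param config a [NeuronConfig-class].
#' @param teacherForced logical.
#' @return integer vector of outputs, one per pattern.
#' @export
replaySequence <- function(w, seqs, config, teacherForced = FALSE) {
  stopifnot(is(seqs, "AssociationSequence"), is(config, "NeuronConfig"))
  h <- as.numeric(seqs@inputs %*% w)
  y <- seqs@targets
  P <- length(y)
  out <- integer(P)
  out[1L] <- as.integer(h[1L] > config@theta)
  if (P > 1L) for (mu in 2:P) {
    prev <- if (teacherForced) y[mu - 1L] else out[mu - 1L]
    out[mu] <- outputBistable(h[mu], prev, config)
  }
  out
}
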