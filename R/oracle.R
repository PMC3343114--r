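#' Exact feasibility oracle for the learning constraints
#'
#' Decides whether \emph{any} nonnegative weight vector satisfies all
#' pattern constraints of a sequence (the \eqn{\kappa = 0} linear regime):
#' \deqn{\sigma_\mu\,(w\cdot x^\mu - \theta_{eff}(\mu)) > 0,\quad
#'       w \ge 0,\quad \textstyle\sum_i w_i \le N,}
#' where \eqn{\sigma_\mu = +1} for target 1 and \eqn{-1} for target 0, and
#' \eqn{\theta_{eff}} is the upper/lower switching threshold selected by
#' the previous target (the first pattern uses the central threshold under
#' the `"midpoint"` rule).  The norm cap \eqn{\sum w_i \le N} bounds the
#' problem; by the scale structure of the constraint system its particular
#' value is immaterial to the feasibility verdict.
#'
#' The open system is realized as "maximize the minimal slack z, declare
#' feasible iff the optimum exceeds `tol * theta`".  Each candidate margin
#' z is tested with a strictly convex quadratic program (minimal
#' \eqn{\|w\|^2} subject to the closed constraints at slack z), whose
#' active-set solver certifies infeasibility exactly; the maximal slack is
#' then bracketed and bisected.
#'
#' Intended for small instances (roughly \eqn{N \cdot P \le 10^3}
#' constraints) where it serves as ground truth for the learning rule and
#' as an alternative capacity probe.
#'
#' @param seqs an [AssociationSequence-class].
#' @param neuron a [NeuronConfig-class] with `kappa = 0` (a norm-coupled
#'   robustness margin makes the problem conic, not linear, and is
#'   unsupported).
#' @param tol relative slack tolerance, default `1e-9`.
#' @param firstPatternRule `"midpoint"` (default) or `"unconstrained"`.
#' @return list with elements `feasible` (logical), `witness` (a feasible
#'   nonnegative weight vector achieving the reported slack, or `NULL`)
#'   and `slack` (the maximal minimal slack found, bisected to a relative
#'   precision of 1e-6; `-Inf` when even the zero-margin closed system is
#'   empty).
#' @examples
#' seqs <- generateAssociations(markovSpec(0.5), markovSpec(0.5),
#'                              N = 12, P = 6, seed = 3)
#' feasibleSequence(seqs, neuronConfig(12))$feasible
#' @export
feasibleSequence <- function(seqs, neuron, tol = 1e-9,
                             firstPatternRule = c("midpoint",
                                                  "unconstrained")) {
  firstPatternRule <- match.arg(firstPatternRule)
  stopifnot(is(seqs, "AssociationSequence"), is(neuron, "NeuronConfig"))
  if (neuron@kappa > 0)
    stop("feasibleSequence supports only the kappa = 0 linear regime")
  X <- seqs@inputs
  y <- seqs@targets
  N <- ncol(X); P <- nrow(X)
  thetaEff <- c(neuron@theta,
                ifelse(y[-P] == 1L, thetaDown(neuron), thetaUp(neuron)))
  keep <- rep(TRUE, P)
  if (firstPatternRule == "unconstrained" && P > 1L) keep[1L] <- FALSE
  sgn <- ifelse(y[keep] == 1L, 1, -1)
  ## constraints in quadprog convention t(Amat) %*% w >= bvec:
  ##   sigma * (X w) >= sigma * thetaEff + z
  ##   w_i >= 0
  ##   -sum(w) >= -N
  Amat <- t(rbind(sgn * X[keep, , drop = FALSE], diag(N), -rep(1, N)))
  b0 <- c(sgn * thetaEff[keep], rep(0, N), -N)
  zMask <- c(rep(1, sum(keep)), rep(0, N), 0)
  solveAt <- function(z) {
    tryCatch(
      quadprog::solve.QP(Dmat = diag(N), dvec = rep(0, N),
                         Amat = Amat, bvec = b0 + z * zMask),
      error = function(e) NULL)
  }
  zTol <- tol * neuron@theta
  sol <- solveAt(zTol)
  if (is.null(sol)) {
    ## distinguish "strictly infeasible" from "empty even at zero margin"
    empty <- is.null(solveAt(0))
    return(list(feasible = FALSE, witness = NULL,
                slack = if (empty) -Inf else 0))
  }
  ## bracket and bisect the maximal minimal slack
  lo <- zTol
  wLo <- sol$solution
  hi <- max(2 * zTol, 0.1 * neuron@theta)
  while (!is.null(s <- solveAt(hi))) {
    lo <- hi; wLo <- s$solution; hi <- hi * 2
    if (hi > 1e6 * neuron@theta) break  # norm cap guarantees boundedness
  }
  while (hi - lo > 1e-6 * max(lo, neuron@theta)) {
    mid <- (lo + hi) / 2
    s <- solveAt(mid)
    if (is.null(s)) hi <- mid else { lo <- mid; wLo <- s$solution }
  }
  list(feasible = TRUE, witness = pmax(wLo, 0), slack = lo)
}
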