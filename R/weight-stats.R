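#' Fraction of silent synapses in a trained weight vector
#'
#' A synapse counts as silent when its weight falls below a threshold that
#' is \emph{relative} to the typical nonzero weight (the learning rule's
#' absolute weight scale depends on the learning rate and on N, so an
#' absolute cut would not transfer across settings).  The default cut is
#' `rel = 1e-3` times the mean weight among weights above `rel` times the
#' overall mean; sensitivity at `1e-2` and `1e-4` is part of the test
#' suite.
#'
#' For weights produced by the discrete learning rule, pass the learning
#' rate `eta`: the rule quantizes weights in steps of `eta`, so a synapse
#' pinned at the zero bound jitters on the first few multiples of `eta`
#' rather than sitting at exactly zero.  The threshold is then raised to
#' `10 * eta`, which sits above that boundary jitter but far below the
#' positive (truncated-Gaussian) branch whose scale is the typical weight
#' -- the two populations are cleanly separated at the package's default
#' rates.
#'
#' @param w nonnegative weight vector.
#' @param rel relative threshold (default `1e-3`).
#' @param eta optional learning-rate of the rule that produced `w`; raises
#'   the cut to `max(rel * mean nonzero, 10 * eta)`.
#' @return fraction in \[0, 1\]; an all-zero vector returns 1 with
#'   attribute `degenerate = TRUE`.
#' @examples
#' silentFraction(c(0, 0, 1, 1))  # 0.5
#' @export
silentFraction <- function(w, rel = 1e-3, eta = NULL) {
  if (any(w < 0)) stop("'w' must be nonnegative")
  if (all(w == 0)) return(structure(1, degenerate = TRUE))
  pos <- w[w > rel * mean(w)]
  thr <- rel * mean(pos)
  if (!is.null(eta)) thr <- max(thr, 10 * eta)
  mean(w < thr)
}

#' Moments of the positive part of the weight distribution
#'
#' Returns mean and standard deviation of the above-threshold weights and
#' their scale-invariant ratio.  For a perceptron trained to maximal
#' capacity the positive branch is a zero-mean Gaussian truncated at zero,
#' whose sd/mean ratio is \eqn{\sqrt{\pi/2 - 1} \approx 0.7555},
#' independent of the correlation structure of the stored sequences.
#'
#' @param w nonnegative weight vector with at least 2 nonzero weights.
#' @param rel relative silent threshold, as in [silentFraction()].
#' @param eta optional learning rate, as in [silentFraction()]: excludes
#'   the boundary-jitter population below `10 * eta` from the positive
#'   branch.
#' @return list with `mean`, `sd`, `ratio`, `nPositive`.
#' @examples
#' truncatedGaussianSummary(abs(rnorm(1e4)))$ratio  # ~ 0.7555
#' @export
truncatedGaussianSummary <- function(w, rel = 1e-3, eta = NULL) {
  if (any(w < 0)) stop("'w' must be nonnegative")
  pos <- w[w > 0]
  if (length(pos) >= 2L) {
    thr <- rel * mean(pos)
    if (!is.null(eta)) thr <- max(thr, 10 * eta)
    pos <- w[w >= thr & w > 0]
  }
  if (length(pos) < 2L)
    stop("need at least 2 nonzero weights")
  m <- mean(pos); s <- sd(pos)
  list(mean = m, sd = s, ratio = s / m, nPositive = length(pos))
}

#' Histogram export of a weight distribution
#'
#' @param w nonnegative weight vector.
#' @param breaks number of bins (default 40).
#' @return data.frame with columns `lower`, `upper`, `count`, suitable for
#'   CSV export.
#' @export
weightHistogram <- function(w, breaks = 40L) {
  h <- graphics::hist(w, breaks = breaks, plot = FALSE)
  data.frame(lower = h$breaks[-length(h$breaks)],
             upper = h$breaks[-1L], count = h$counts)
}
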