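#' Estimate the maximal storage capacity by simulation
#'
#' For each trial a fresh association sequence of length
#' `ceiling(alphaMax * N)` is generated; learnability of its length-P
#' prefixes is monotone (appending a pattern can only remove solutions), so
#' the largest learnable prefix is located by bracketing and bisection.  A
#' prefix counts as learnable when [trainPerceptron()] converges within its
#' epoch budget (or, with `probe = "oracle"`, when [feasibleSequence()]
#' finds a solution; small N only).  The per-trial capacity is the largest
#' learnable P divided by N; the estimate is the mean over trials and the
#' spread its standard deviation, matching the usual
#' mean-over-10-independent-samples protocol.
#'
#' The run is deterministic given `seed`: trial sequences and presentation
#' orders use seeds derived from it.
#'
#' @param inputSpec,outputSpec [MarkovSpec-class] stream specifications.
#' @param neuron a [NeuronConfig-class]; `N` is taken from it.
#' @param learner a [LearnerConfig-class]; its `seed` slot is overridden by
#'   derived per-trial seeds.
#' @param nTrials number of independent trials (default 10).
#' @param seed master seed.
#' @param alphaMax load ceiling for the search bracket (default 3; raise it
#'   for strongly correlated streams).  Hitting the ceiling is flagged in
#'   the protocol metadata, not silently absorbed.
#' @param resolution bisection resolution in patterns; default
#'   `max(1, round(N/100))`.
#' @param attempts training restarts (with fresh presentation orders)
#'   allowed before a prefix is declared unlearnable (default 2).  Near
#'   the capacity edge a single unlucky presentation order can stall
#'   within the epoch budget; a restart makes the bisection robust to
#'   such false negatives while leaving genuinely unlearnable prefixes
#'   unaffected.
#' @param probe `"train"` (default) or `"oracle"`.
#' @return a [CapacityEstimate-class].
#' @examples
#' \donttest{
#' est <- estimateCapacity(markovSpec(0.5), markovSpec(0.5),
#'                         neuronConfig(50), learnerConfig(maxEpochs = 300),
#'                         nTrials = 3, seed = 1)
#' est
#' }
#' @export
estimateCapacity <- function(inputSpec, outputSpec, neuron,
                             learner = learnerConfig(), nTrials = 10L,
                             seed = 1L, alphaMax = 3,
                             resolution = NULL, attempts = 2L,
                             probe = c("train", "oracle")) {
  probe <- match.arg(probe)
  stopifnot(nTrials >= 1)
  N <- neuron@N
  if (is.null(resolution)) resolution <- max(1L, round(N / 100))
  Pmax <- as.integer(ceiling(alphaMax * N))
  perTrial <- numeric(nTrials)
  exhausted <- logical(nTrials)
  trialSeeds <- vapply(seq_len(nTrials), function(i) childSeed(seed, i), 1L)

  for (trial in seq_len(nTrials)) {
    ts <- trialSeeds[trial]
    seqFull <- generateAssociations(inputSpec, outputSpec, N, Pmax, seed = ts)
    learnable <- function(P) {
      pre <- prefixSequence(seqFull, P)
      if (probe == "oracle") {
        feasibleSequence(pre, neuron)$feasible
      } else {
        for (att in seq_len(max(1L, attempts))) {
          lc <- learner
          lc@seed <- childSeed(ts, P + (att - 1L) * 1000003L)
          if (converged(trainPerceptron(pre, neuron, lc))) return(TRUE)
        }
        FALSE
      }
    }
    lo <- max(2L, as.integer(round(N / 4)))
    while (lo > 2L && !learnable(lo)) lo <- max(2L, lo %/% 2L)
    if (!learnable(lo)) { perTrial[trial] <- 0; next }
    hi <- lo
    repeat {
      nxt <- min(Pmax, as.integer(ceiling(hi * 1.5)))
      if (nxt == hi) { exhausted[trial] <- TRUE; break }
      if (learnable(nxt)) hi <- nxt else { lo <- hi; hi <- nxt; break }
    }
    if (!exhausted[trial]) {
      ## invariant: lo learnable, hi not; shrink to the resolution
      lo2 <- lo
      while (hi - lo2 > resolution) {
        mid <- (lo2 + hi) %/% 2L
        if (learnable(mid)) lo2 <- mid else hi <- mid
      }
      perTrial[trial] <- lo2 / N
    } else {
      perTrial[trial] <- hi / N
    }
  }
  new("CapacityEstimate",
      alpha = mean(perTrial),
      spread = if (nTrials > 1L) sd(perTrial) else 0,
      perTrial = perTrial, nTrials = as.integer(nTrials), N = N,
      protocol = list(resolution = resolution, alphaMax = alphaMax,
                      attempts = attempts,
                      budgetExhausted = exhausted, seed = seed,
                      trialSeeds = trialSeeds, probe = probe,
                      rule = learner@rule, maxEpochs = learner@maxEpochs,
                      eta = learner@eta, constrained = learner@constrained))
}

#' Capacity estimates over a parameter grid
#'
#' Runs [estimateCapacity()] for every row of a parameter grid and returns
#' one table row per grid point.  When `cacheFile` is given, completed rows
#' are appended to it as CSV after each point and previously cached rows
#' are reused, so an interrupted sweep resumes where it stopped.  A failed
#' point is flagged (`ok = FALSE`) and the sweep continues.
#'
#' @param grid data.frame with columns among `cIn`, `cOut`, `fIn`, `fOut`,
#'   `kappa`, `delta`, `N` (missing columns get the defaults `0, 0, 0.5,
#'   0.5, 0, 0, 200`).
#' @param learner shared [LearnerConfig-class].
#' @param nTrials,seed,alphaMax as in [estimateCapacity()].
#' @param theta threshold for every point (default 1).
#' @param cacheFile optional CSV path for resumable sweeps.
#' @return data.frame with the grid columns plus `alphaMean`, `alphaSd`,
#'   `nTrials`, `seed`, `ok`.
#' @export
capacitySurface <- function(grid, learner = learnerConfig(), nTrials = 10L,
                            seed = 1L, alphaMax = 3, theta = 1,
                            cacheFile = NULL) {
  defaults <- list(cIn = 0, cOut = 0, fIn = 0.5, fOut = 0.5,
                   kappa = 0, delta = 0, N = 200L)
  for (nm in names(defaults))
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  keyCols <- names(defaults)
  cache <- NULL
  if (!is.null(cacheFile) && file.exists(cacheFile))
    cache <- read.csv(cacheFile)
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    if (!is.null(cache)) {
      hit <- which(vapply(seq_len(nrow(cache)), function(j)
        all(abs(as.numeric(cache[j, keyCols]) - as.numeric(g[keyCols])) <
              1e-12), TRUE))
      if (length(hit)) { out[[i]] <- cache[hit[1L], ]; next }
    }
    row <- as.data.frame(g[keyCols])
    est <- tryCatch(
      estimateCapacity(markovSpec(g$fIn, g$cIn), markovSpec(g$fOut, g$cOut),
                       neuronConfig(g$N, theta = theta, delta = g$delta,
                                    kappa = g$kappa),
                       learner, nTrials = nTrials,
                       seed = childSeed(seed, i), alphaMax = alphaMax),
      error = function(e) NULL)
    if (is.null(est)) {
      row$alphaMean <- NA_real_; row$alphaSd <- NA_real_
      row$nTrials <- 0L; row$seed <- childSeed(seed, i); row$ok <- FALSE
    } else {
      row$alphaMean <- est@alpha; row$alphaSd <- est@spread
      row$nTrials <- est@nTrials; row$seed <- childSeed(seed, i)
      row$ok <- TRUE
    }
    out[[i]] <- row
    if (!is.null(cacheFile)) {
      done <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
      write.csv(done, cacheFile, row.names = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the capacity divergence law
#'
#' Least-squares fit of \eqn{\alpha(c) = A + B (1-c)^{-\beta}} to a
#' capacity-versus-correlation curve.  As the common input/output
#' correlation approaches 1, patterns become ever more similar and the
#' capacity diverges; `beta` quantifies the divergence.  A curve with no
#' detectable divergence (`B` or `beta` collapsing to 0) is flagged via
#' the `divergent` slot rather than treated as an error.
#'
#' @param c numeric vector of correlations, all < 1, length >= 4.
#' @param alpha numeric vector of capacities.
#' @return a [DivergenceFit-class].
#' @examples
#' cc <- seq(0, 0.9, by = 0.1)
#' fit <- fitDivergence(cc, 0 + 1 * (1 - cc)^(-0.5))
#' fit
#' @export
fitDivergence <- function(c, alpha) {
  if (length(c) < 4L) stop("need at least 4 points")
  if (length(c) != length(alpha)) stop("'c' and 'alpha' lengths differ")
  if (any(c >= 1)) stop("all correlations must be < 1")
  if (sd(alpha) < 1e-12)
    return(new("DivergenceFit", A = mean(alpha), B = 0, beta = 0,
               residuals = alpha - mean(alpha),
               rss = sum((alpha - mean(alpha))^2), divergent = FALSE))
  df <- data.frame(c = c, alpha = alpha)
  fit <- tryCatch(
    minpack.lm::nlsLM(alpha ~ A + B * (1 - c)^(-beta), data = df,
                      start = list(A = 0, B = max(alpha[which.min(c)], 0.5),
                                   beta = 0.5),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(new("DivergenceFit", A = NA_real_, B = NA_real_, beta = NA_real_,
               residuals = rep(NA_real_, length(c)), rss = NA_real_,
               divergent = FALSE))
  cf <- coef(fit)
  new("DivergenceFit", A = unname(cf["A"]), B = unname(cf["B"]),
      beta = unname(cf["beta"]), residuals = as.numeric(resid(fit)),
      rss = sum(resid(fit)^2),
      divergent = unname(abs(cf["B"]) > 1e-6 && cf["beta"] > 1e-6))
}
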