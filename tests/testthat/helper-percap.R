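## shared fixtures and independent oracles for the test suite

## exact statistics of the two-state chain with transition probabilities
## (a = P(1|1), b = P(1|0)), by direct enumeration of the 2x2 chain:
## independent of the package's closed forms.
chainStatsOracle <- function(a, b, piFrozen = NULL) {
  Tm <- matrix(c(1 - b, b, 1 - a, a), 2, 2, byrow = TRUE)  # rows: from 0, 1
  if (a == 1 && b == 0) {
    ## reducible (frozen) chain: every distribution is stationary; the
    ## caller supplies the initial distribution, which we verify is fixed
    stopifnot(!is.null(piFrozen),
              max(abs(drop(piFrozen %*% Tm) - piFrozen)) < 1e-14)
    pi <- piFrozen
  } else {
    ev <- eigen(t(Tm))
    i <- which.min(abs(ev$values - 1))
    pi <- Re(ev$vectors[, i]); pi <- pi / sum(pi)
  }
  f <- pi[2]
  ## E[s_t s_{t+1}] = pi(1) * P(1|1)
  e11 <- pi[2] * a
  corr <- (e11 - f^2) / (f * (1 - f))
  joint <- c(p00 = pi[1] * Tm[1, 1], p01 = pi[1] * Tm[1, 2],
             p10 = pi[2] * Tm[2, 1], p11 = pi[2] * Tm[2, 2])
  list(f = f, corr = corr, joint = joint)
}

## small random association problem for oracle/learner cross checks
randomInstance <- function(seed, N = 16, P = NULL, cIn = 0, cOut = 0.3,
                           fIn = 0.5, fOut = 0.5) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (is.null(P)) P <- sample(8:32, 1)
  generateAssociations(markovSpec(fIn, cIn), markovSpec(fOut, cOut),
                       N = N, P = P, seed = seed)
}

## build an AssociationSequence directly from a matrix and targets
sequenceFromMatrix <- function(X, y, fIn = 0.5, cIn = 0, fOut = 0.5,
                               cOut = 0) {
  methods::new("AssociationSequence",
               inputs = matrix(as.integer(X), nrow(X), ncol(X)),
               targets = as.integer(y),
               inputSpec = markovSpec(fIn, cIn),
               outputSpec = markovSpec(fOut, cOut), seed = 0L)
}
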