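#' Create a two-state Markov stream specification
#'
#' @param f coding level: stationary probability that the unit is active,
#'   in (0,1).
#' @param c lag-1 correlation between successive states, in \[0,1\].
#' @return a [MarkovSpec-class] object.
#' @examples
#' markovSpec(0.2, 0.5)
#' @export
markovSpec <- function(f, c = 0) {
  new("MarkovSpec", f = as.numeric(f), c = as.numeric(c))
}

#' Transition probabilities of a correlated binary stream
#'
#' The unique two-state Markov chain with stationary activity probability
#' `f` and lag-1 Pearson correlation `c` has
#' \deqn{P(\mathrm{active}\mid\mathrm{active}) = f + c(1-f), \qquad
#'       P(\mathrm{active}\mid\mathrm{inactive}) = f(1-c).}
#' With `c = 0` the states are i.i.d. Bernoulli(f); with `c = 1` the chain
#' never changes state.
#'
#' @param spec a [MarkovSpec-class].
#' @return named numeric vector with elements `activeGivenActive` and
#'   `activeGivenInactive`.
#' @examples
#' transitionProbabilities(markovSpec(0.2, 0.5))  # 0.6, 0.1
#' @export
transitionProbabilities <- function(spec) {
  stopifnot(is(spec, "MarkovSpec"))
  validObject(spec)
  c(activeGivenActive = spec@f + spec@c * (1 - spec@f),
    activeGivenInactive = spec@f * (1 - spec@c))
}

#' Stationary pair probabilities of successive states
#'
#' Joint distribution of (previous state, current state) under
#' stationarity:
#' \deqn{p_{11} = f(f + c(1-f)),\quad p_{10} = p_{01} = f(1-f)(1-c),\quad
#'       p_{00} = (1-f)((1-f) + cf).}
#' These four weights classify the constraints a bistable unit must satisfy
#' and sum to one; the chain is reversible so \eqn{p_{01} = p_{10}}.
#'
#' @param spec a [MarkovSpec-class].
#' @return named numeric vector `c(p00, p01, p10, p11)`; names give
#'   (previous, current).
#' @examples
#' pairProbabilities(markovSpec(0.2, 0.5))
#' @export
pairProbabilities <- function(spec) {
  stopifnot(is(spec, "MarkovSpec"))
  validObject(spec)
  f <- spec@f; cc <- spec@c
  c(p00 = (1 - f) * ((1 - f) + cc * f),
    p01 = f * (1 - f) * (1 - cc),
    p10 = f * (1 - f) * (1 - cc),
    p11 = f * (f + cc * (1 - f)))
}

## deterministic 32-bit child seed; exact in double arithmetic
childSeed <- function(master, id) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 + id * 7919) %%
               2147483629)
}

## save/restore the global RNG state so seeded generators do not clobber
## the caller's stream
saveRNGState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restoreRNGState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

## one chain realization per column of a P x n matrix of uniforms
chainFromUniforms <- function(U, spec) {
  tp <- transitionProbabilities(spec)
  P <- nrow(U); n <- ncol(U)
  S <- matrix(0L, P, n)
  S[1, ] <- as.integer(U[1, ] < spec@f)
  if (P > 1L) for (t in 2:P) {
    prev <- S[t - 1L, ]
    thr <- ifelse(prev == 1L, tp[["activeGivenActive"]],
                  tp[["activeGivenInactive"]])
    S[t, ] <- as.integer(U[t, ] < thr)
  }
  S
}

#' Generate a correlated input/output association sequence
#'
#' Each of the `N` input cells is an independent realization of the input
#' Markov chain; the targets are one realization of the output chain,
#' independent of all inputs.  The first state of every stream is drawn
#' from the stationary distribution (probability `f` of being active), so
#' no burn-in is needed.  Each column uses its own deterministically
#' derived child seed, so the same `(seed, column)` pair always yields the
#' same stream regardless of `N` and `P`.
#'
#' @param inputSpec,outputSpec [MarkovSpec-class] objects for the input
#'   cells and the target output.
#' @param N number of input cells (columns), >= 1.
#' @param P number of patterns (sequence length), >= 1.
#' @param seed integer master seed; identical seeds reproduce the sequence
#'   bit for bit.
#' @return an [AssociationSequence-class].
#' @examples
#' seqs <- generateAssociations(markovSpec(0.5, 0.8), markovSpec(0.5, 0.5),
#'                              N = 20, P = 50, seed = 1)
#' seqs
#' @export
generateAssociations <- function(inputSpec, outputSpec, N, P, seed = 1L) {
  stopifnot(is(inputSpec, "MarkovSpec"), is(outputSpec, "MarkovSpec"))
  if (!is.finite(N) || N < 1) stop("'N' must be a positive count")
  if (!is.finite(P) || P < 1) stop("'P' must be a positive count")
  N <- as.integer(N); P <- as.integer(P); seed <- as.integer(seed)
  old <- saveRNGState(); on.exit(restoreRNGState(old))
  U <- matrix(0, P, N)
  for (k in seq_len(N)) {
    set.seed(childSeed(seed, k))
    U[, k] <- runif(P)
  }
  X <- chainFromUniforms(U, inputSpec)
  set.seed(childSeed(seed, 0L))
  y <- drop(chainFromUniforms(matrix(runif(P), P, 1), outputSpec))
  new("AssociationSequence", inputs = X, targets = as.integer(y),
      inputSpec = inputSpec, outputSpec = outputSpec, seed = seed)
}

## first P patterns of a sequence (time order preserved)
prefixSequence <- function(seqs, P) {
  stopifnot(P >= 1, P <= nPatterns(seqs))
  new("AssociationSequence",
      inputs = seqs@inputs[seq_len(P), , drop = FALSE],
      targets = seqs@targets[seq_len(P)],
      inputSpec = seqs@inputSpec, outputSpec = seqs@outputSpec,
      seed = seqs@seed)
}

#' Empirical mean and lag-1 correlation of a binary stream
#'
#' @param stream numeric/integer vector of 0/1 states, length >= 2.
#' @return list with elements `mean`, `lag1` (sample Pearson correlation of
#'   successive states; `NA` for constant streams) and `degenerate`
#'   (`TRUE` when the correlation is undefined).
#' @examples
#' empiricalStats(c(0, 1, 0, 1, 0, 1))  # mean 0.5, lag1 -1
#' empiricalStats(rep(1, 4))            # degenerate
#' @export
empiricalStats <- function(stream) {
  if (length(stream) < 2L) stop("'stream' must have length >= 2")
  if (!all(stream %in% c(0, 1))) stop("'stream' must be binary 0/1")
  m <- mean(stream)
  n <- length(stream)
  if (sd(stream) == 0)
    return(list(mean = m, lag1 = NA_real_, degenerate = TRUE))
  list(mean = m,
       lag1 = cor(stream[-n], stream[-1]),
       degenerate = FALSE)
}

#' Write / read an association sequence as plain text
#'
#' The matrix format has one pattern per row: `N` space-separated 0/1 input
#' states followed by the target state in the final column.  A JSON sidecar
#' (`<file>.json`) stores the stream specifications and the master seed so
#' the object can be reconstructed exactly.  A `.gz` suffix on `file`
#' compresses transparently.
#'
#' @param seqs an [AssociationSequence-class].
#' @param file path of the matrix file.
#' @return `writeAssociations` returns `file` invisibly; `readAssociations`
#'   returns the reconstructed [AssociationSequence-class].
#' @export
writeAssociations <- function(seqs, file) {
  stopifnot(is(seqs, "AssociationSequence"))
  M <- cbind(seqs@inputs, seqs@targets)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "w") else file(file, "w")
  on.exit(close(con))
  writeLines(apply(M, 1L, paste, collapse = " "), con)
  meta <- list(
    f_in = seqs@inputSpec@f, c_in = seqs@inputSpec@c,
    f_out = seqs@outputSpec@f, c_out = seqs@outputSpec@c,
    seed = seqs@seed, N = nInputs(seqs), P = nPatterns(seqs))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname writeAssociations
#' @export
readAssociations <- function(file) {
  side <- paste0(file, ".json")
  if (!file.exists(side))
    stop("metadata sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "r") else file(file, "r")
  on.exit(close(con))
  rows <- strsplit(trimws(readLines(con)), "\\s+")
  M <- do.call(rbind, lapply(rows, as.integer))
  N <- ncol(M) - 1L
  if (N != meta$N || nrow(M) != meta$P)
    stop("matrix dimensions disagree with the metadata sidecar")
  new("AssociationSequence",
      inputs = M[, seq_len(N), drop = FALSE],
      targets = M[, N + 1L],
      inputSpec = markovSpec(meta$f_in, meta$c_in),
      outputSpec = markovSpec(meta$f_out, meta$c_out),
      seed = as.integer(meta$seed))
}
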