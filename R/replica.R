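## ---------------------------------------------------------------------
## Replica-symmetric theory for the excitatory (sign-constrained) bistable
## perceptron storing Markov-correlated outputs with uncorrelated inputs.
##
## Gardner volume formulation.  The drive of pattern mu is Gaussian in the
## large-N limit; its mean locks onto the threshold and the fluctuations
## set the scale.  Each pattern falls into one of four classes (previous
## target, current target) with stationary pair probabilities p01, p11,
## p00, p10; class k imposes a one-sided constraint with reduced margin
##   b_01 = K + G + D,  b_11 = K + G - D,
##   b_00 = K - G - D,  b_10 = K - G + D,
## where G is the (order-parameter) offset between mean drive and central
## threshold, D the half bistable range and K the robustness, all in units
## of the drive standard deviation.  External scaled controls deltaS =
## Delta*sqrt(N)/theta and kappaS = kappa_abs*sqrt(N)/theta map onto D and
## K through D = (deltaS/2) * sqrt(fIn/(1-fIn)) * r and likewise for K,
## with r = m/sqrt(rho) the mean-to-rms weight ratio fixed by the
## single-site measure.
##
## At the capacity limit (replica overlap q -> 1) the system reduces to
## three equations in (s, G, alpha):
##   (i)   sum_k p_k sigma_k J(b_k) = 0                  [threshold locking]
##   (ii)  alpha * sum_k p_k Phi(b_k) = H(s)             [overlap collapse]
##   (iii) alpha * (sum_k p_k Phi(b_k))^2 = I2(s) * Lbar [scale consistency]
## with J(b) = b Phi(b) + phi(b), L(b) = (1+b^2) Phi(b) + b phi(b),
## I1(s) = phi(s) - s H(s), I2(s) = (1+s^2) H(s) - s phi(s), H = 1 - Phi.
## The capacity alpha_c is the root of F(alpha) = alpha*Phibar^2 - I2*Lbar
## after solving (i)-(ii); the weight distribution at capacity is a delta
## mass Phi(s) at zero plus a Gaussian truncated at zero (untruncated mean
## -s, unit sd, in units of the scale lambda).
## ---------------------------------------------------------------------

## class bookkeeping: order (01, 11, 00, 10); sigma = +1 for target 1
.classSigma <- c(1, 1, -1, -1)

.classWeights <- function(fOut, cOut) {
  p <- pairProbabilities(markovSpec(fOut, cOut))
  c(p[["p01"]], p[["p11"]], p[["p00"]], p[["p10"]])
}

.bvals <- function(G, D, K) c(K + G + D, K + G - D, K - G - D, K - G + D)

## Gaussian tail helpers (stable in both tails)
.Hfun <- function(s) pnorm(s, lower.tail = FALSE)
.Jfun <- function(b) b * pnorm(b) + dnorm(b)
.Lfun <- function(b) (1 + b^2) * pnorm(b) + b * dnorm(b)
.I1fun <- function(s) dnorm(s) - s * .Hfun(s)
.I2fun <- function(s) pmax((1 + s^2) * .Hfun(s) - s * dnorm(s), 1e-300)
## inverse Mills ratio phi/H computed in log space
.mills <- function(x)
  exp(dnorm(x, log = TRUE) - pnorm(x, lower.tail = FALSE, log.p = TRUE))

.SMAX <- 7.5  # silent-parameter search range; Phi(7.5) is 1 to 1e-14

#' Scaled parameters for the replica theory
#'
#' @param deltaS scaled bistable range \eqn{\Delta\sqrt{N}/\theta}.
#' @param kappaS scaled robustness margin \eqn{\kappa_{abs}\sqrt{N}/\theta}
#'   (absolute drive-unit margin; see [kappaScaledFromNorm()] for the
#'   norm-referenced simulation convention).
#' @param fOut,cOut output coding level and lag-1 correlation.
#' @param fIn input coding level (inputs are uncorrelated in the theory).
#' @param gamma scaled threshold; a pure gauge, default 1.
#' @return a [ScaledParams-class].
#' @export
scaledParams <- function(deltaS = 0, kappaS = 0, fOut = 0.5, cOut = 0,
                         fIn = 0.5, gamma = 1) {
  new("ScaledParams", gamma = as.numeric(gamma), deltaS = as.numeric(deltaS),
      kappaS = as.numeric(kappaS), fOut = as.numeric(fOut),
      cOut = as.numeric(cOut), fIn = as.numeric(fIn))
}

## reduced capacity-limit system: given alpha solve (i)-(ii) for (G, s)
.reducedSolve <- function(params, alpha) {
  p <- .classWeights(params@fOut, params@cOut)
  phif <- sqrt(params@fIn / (1 - params@fIn))
  DKof <- function(s) {
    r <- .I1fun(s) / sqrt(.I2fun(s))
    c(D = params@deltaS / 2 * phif * r, K = params@kappaS * phif * r)
  }
  Gof <- function(s) {
    dk <- DKof(s)
    uniroot(function(G) sum(p * .classSigma * .Jfun(.bvals(G, dk[1], dk[2]))),
            c(-80, 80), tol = 1e-14)$root
  }
  gap <- function(s) {
    dk <- DKof(s)
    .Hfun(s) - alpha * sum(p * pnorm(.bvals(Gof(s), dk[1], dk[2])))
  }
  gLo <- gap(-.SMAX)
  if (gLo <= 0) return(NULL)     # alpha*Phibar >= 1 on full support: above capacity
  gHi <- gap(.SMAX)
  if (gHi >= 0) return(NULL)     # pathological; treat as unsolvable
  s <- uniroot(gap, c(-.SMAX, .SMAX), tol = 1e-14)$root
  dk <- DKof(s)
  G <- Gof(s)
  b <- .bvals(G, dk[1], dk[2])
  Phibar <- sum(p * pnorm(b))
  Lbar <- sum(p * .Lfun(b))
  list(s = s, G = G, b = b, D = dk[["D"]], K = dk[["K"]], p = p,
       Phibar = Phibar, Lbar = Lbar,
       F = alpha * Phibar^2 - .I2fun(s) * Lbar)
}

#' Replica-theory maximal capacity
#'
#' Locates the load at which the typical volume of compatible nonnegative
#' weight vectors vanishes, by bisection on the sign of the rescaled
#' vanishing-volume residual of the replica-symmetric saddle equations in
#' their q -> 1 limit (direct substitution of q = 1 is singular; the
#' residual form stays finite).
#'
#' @param params a [ScaledParams-class].
#' @param tol relative bracketing tolerance on the capacity (default
#'   `1e-8`; the result is converged far beyond `1e-6`).
#' @return numeric capacity \eqn{\alpha_c} (associations per synapse).
#' @examples
#' capacityReplica(scaledParams())                 # 1: the excitatory perceptron
#' capacityReplica(scaledParams(cOut = 0.8))       # unchanged by output correlation
#' @export
capacityReplica <- function(params, tol = 1e-8) {
  stopifnot(is(params, "ScaledParams"))
  validObject(params)
  Ff <- function(a) {
    z <- .reducedSolve(params, a)
    if (is.null(z)) -1 else z$F
  }
  lo <- 1e-3
  if (Ff(lo) <= 0) stop("no volume even at alpha = 0.001; scan trace: F(0.001) <= 0")
  hi <- 1
  while (Ff(hi) > 0) {
    lo <- hi; hi <- hi * 1.5
    if (hi > 1e5)
      stop("bracketing failure: volume still positive at alpha = 1e5")
  }
  uniroot(Ff, c(lo, hi), tol = tol * max(1, hi))$root
}

#' Replica solution at maximal capacity
#'
#' Solves the q -> 1 (vanishing volume) form of the saddle-point system at
#' the capacity returned by [capacityReplica()] and packages the order
#' parameters, in particular the silent-synapse parameter `s`: the weight
#' distribution at capacity is \eqn{\Phi(s)\,\delta(w)} plus a Gaussian of
#' untruncated mean \eqn{-s\lambda} and sd \eqn{\lambda} truncated at zero.
#'
#' @param params a [ScaledParams-class].
#' @return a [ReplicaSolution-class] with `atCapacity = TRUE`.
#' @export
capacitySolution <- function(params) {
  alphaC <- capacityReplica(params)
  z <- .reducedSolve(params, alphaC)
  if (is.null(z)) stop("internal: no reduced solution at the located capacity")
  resid <- c(locking = sum(z$p * .classSigma * .Jfun(z$b)),
             overlap = .Hfun(z$s) - alphaC * z$Phibar,
             volume = z$F)
  new("ReplicaSolution", params = params, alpha = alphaC, atCapacity = TRUE,
      q = 1, G = z$G, s = z$s, silentFraction = pnorm(z$s),
      orderParams = list(b = z$b, D = z$D, K = z$K, classWeights = z$p,
                         Phibar = z$Phibar, Lbar = z$Lbar),
      residuals = resid)
}

## ---------------------------------------------------------------------
## full RS system at finite load (replica overlap q < 1), gauge rho = 1
## unknowns: q, conjugates A, C, mhat, and threshold offset G
## ---------------------------------------------------------------------

.ghCache <- new.env(parent = emptyenv())
.ghNodes <- function(n = 240L) {
  key <- as.character(n)
  if (is.null(.ghCache[[key]])) {
    gh <- pracma::gaussHermite(n)
    .ghCache[[key]] <- list(t = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .ghCache[[key]]
}

## truncated-at-zero Gaussian moments of the single-site measure
.siteMoments <- function(A, C, mhat, gh) {
  mu <- (sqrt(C) * gh$t - mhat) / A
  tau <- 1 / sqrt(A)
  beta <- mu / tau
  rm_ <- .mills(-beta)                    # phi(beta)/Phi(beta)
  w1 <- mu + tau * rm_
  w2 <- mu^2 + tau^2 + mu * tau * rm_
  list(M1 = sum(gh$w * w1), M2 = sum(gh$w * w2), Q = sum(gh$w * w1^2))
}

.energyIntegrals <- function(b, q, gh) {
  x <- 1 - q
  u <- outer(-sqrt(q) * gh$t, b, `+`) / sqrt(x)   # rows t, cols classes
  R <- .mills(u)
  list(Ra = colSums(gh$w * R),
       Rp = colSums(gh$w * R * (R - u)),
       Ru = colSums(gh$w * R * u))
}

#' Solve the replica-symmetric saddle equations at a given load
#'
#' Damped fixed-point iteration for the full coupled system at load
#' `alpha` below capacity: the replica overlap `q`, the three conjugate
#' parameters of the single-site (truncated Gaussian) measure, and the
#' threshold offset `G`, in the gauge where the mean square weight is 1.
#' Gaussian integrals use Gauss-Hermite quadrature (240 nodes by default).
#' The damping factor halves automatically when the iteration oscillates.
#' Near capacity the overlap approaches 1 and the conjugates diverge;
#' loads at or above capacity make the iteration collapse, which is
#' reported as an error carrying the residual trace.
#'
#' @param params a [ScaledParams-class].
#' @param alpha load P/N, must be positive and below the capacity.
#' @param damp initial damping factor (default 0.5).
#' @param maxit iteration budget.
#' @param tol fixed-point tolerance on the relative update (default 1e-12;
#'   the re-substitution residuals of the returned solution are below
#'   1e-10).
#' @param nodes number of Gauss-Hermite nodes.
#' @return a [ReplicaSolution-class] with `atCapacity = FALSE`.
#' @examples
#' \donttest{
#' solveSaddle(scaledParams(), alpha = 0.6)
#' }
#' @export
solveSaddle <- function(params, alpha, damp = 0.5, maxit = 6000L,
                        tol = 1e-12, nodes = 240L) {
  stopifnot(is(params, "ScaledParams"), alpha > 0)
  alphaC <- capacityReplica(params)
  if (alpha >= alphaC)
    stop("load alpha = ", alpha, " is at or above the capacity alpha_c = ",
         signif(alphaC, 8), "; the finite-overlap saddle point exists only ",
         "below capacity")
  gh <- .ghNodes(nodes)
  p <- .classWeights(params@fOut, params@cOut)
  phif <- sqrt(params@fIn / (1 - params@fIn))
  q <- 0.3; A <- 3; C <- 1; mhat <- 0; G <- 0
  lastStep <- Inf
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    x <- 1 - q
    mo <- .siteMoments(A, C, mhat, gh)
    ## rescale to the gauge M2 = 1 (w -> w/sqrt(M2))
    sc <- mo$M2
    A <- A * sc; C <- C * sc; mhat <- mhat * sqrt(sc)
    M1 <- mo$M1 / sqrt(sc); Qe <- mo$Q / sc
    r <- M1
    D <- params@deltaS / 2 * phif * r
    K <- params@kappaS * phif * r
    Gn <- uniroot(function(Gv) {
      ei <- .energyIntegrals(.bvals(Gv, D, K), q, gh)
      sum(p * .classSigma * ei$Ra)
    }, c(-80, 80), tol = 1e-13)$root
    ei <- .energyIntegrals(.bvals(Gn, D, K), q, gh)
    An <- alpha / x * sum(p * ei$Rp)
    Cn <- An + alpha / x * sum(p * ei$Ru)
    qn <- Qe
    ## mhat from the gauge equation M2 = 1 at the updated conjugates
    mhn <- tryCatch(uniroot(function(mh)
      .siteMoments(An, Cn, mh, gh)$M2 - 1,
      c(-60 * sqrt(Cn) - 60, 60 * sqrt(Cn) + 60), tol = 1e-13)$root,
      error = function(e) mhat)
    step <- max(abs(c(qn - q, An - A, Cn - C, mhn - mhat, Gn - G)) /
                  pmax(1, abs(c(q, A, C, mhat, G))))
    trace <- c(trace, step)
    if (!is.finite(step) || qn >= 1 - 1e-10)
      stop("saddle iteration collapsed (q -> 1): load at or above capacity; ",
           "residual trace tail: ",
           paste(signif(tail(trace, 5), 3), collapse = ", "))
    if (step > lastStep * 1.5) damp <- max(damp / 2, 0.02)  # oscillation guard
    lastStep <- step
    q <- q + damp * (qn - q); A <- A + damp * (An - A)
    C <- C + damp * (Cn - C); mhat <- mhat + damp * (mhn - mhat)
    G <- G + damp * (Gn - G)
    if (step < tol) break
  }
  if (step >= sqrt(tol))
    stop("saddle iteration did not converge at alpha = ", alpha,
         "; last relative updates: ",
         paste(signif(tail(trace, 5), 3), collapse = ", "))
  resid <- .saddleResiduals(params, alpha, q, A, C, mhat, G, gh)
  new("ReplicaSolution", params = params, alpha = alpha, atCapacity = FALSE,
      q = q, G = G, s = mhat / sqrt(C),
      silentFraction = pnorm(mhat / sqrt(C)),
      orderParams = list(A = A, C = C, mhat = mhat, x = 1 - q,
                         r = .siteMoments(A, C, mhat, gh)$M1,
                         classWeights = p),
      residuals = resid)
}

## re-substitution residuals of the five coupled equations (same quadrature)
.saddleResiduals <- function(params, alpha, q, A, C, mhat, G, gh) {
  p <- .classWeights(params@fOut, params@cOut)
  phif <- sqrt(params@fIn / (1 - params@fIn))
  mo <- .siteMoments(A, C, mhat, gh)
  r <- mo$M1
  D <- params@deltaS / 2 * phif * r
  K <- params@kappaS * phif * r
  ei <- .energyIntegrals(.bvals(G, D, K), q, gh)
  x <- 1 - q
  c(gauge = mo$M2 - 1,
    overlap = mo$Q - q,
    conjA = A - alpha / x * sum(p * ei$Rp),
    conjC = C - (alpha / x * sum(p * ei$Rp) + alpha / x * sum(p * ei$Ru)),
    locking = sum(p * .classSigma * ei$Ra))
}

#' Capacity-maximizing bistable range
#'
#' Scans and then refines the scaled bistable range `deltaS >= 0`
#' maximizing the replica capacity at fixed output statistics.  With
#' uncorrelated outputs the maximum sits at zero; it moves to positive
#' ranges, and grows, as the output correlation increases.
#'
#' @param params a [ScaledParams-class]; its `deltaS` slot is ignored.
#' @param deltaMax upper end of the scan (default adapts to `cOut`).
#' @param gridPoints coarse-scan resolution before refinement.
#' @return list with `deltaStar`, `alphaStar`, and the scanned grid
#'   (`grid`, `alphaGrid`).
#' @examples
#' \donttest{
#' optimalBistableRange(scaledParams(cOut = 0.4))
#' }
#' @export
optimalBistableRange <- function(params, deltaMax = NULL, gridPoints = 17L) {
  stopifnot(is(params, "ScaledParams"))
  if (is.null(deltaMax))
    deltaMax <- max(3, 10 * params@cOut / sqrt(1 - params@cOut)) *
      sqrt((1 - params@fIn) / params@fIn)
  withDelta <- function(d) {
    p <- params; p@deltaS <- d; p
  }
  grid <- seq(0, deltaMax, length.out = gridPoints)
  ag <- vapply(grid, function(d) capacityReplica(withDelta(d)), 1)
  iBest <- which.max(ag)
  if (iBest == 1L) {
    ## interior refinement near zero in case the true optimum is small
    op <- optimize(function(d) capacityReplica(withDelta(d)),
                   c(0, grid[2L]), maximum = TRUE, tol = 1e-7)
    if (op$objective > ag[1L] + 1e-10)
      return(list(deltaStar = op$maximum, alphaStar = op$objective,
                  grid = grid, alphaGrid = ag))
    return(list(deltaStar = 0, alphaStar = ag[1L], grid = grid,
                alphaGrid = ag))
  }
  lo <- grid[max(1L, iBest - 1L)]
  hi <- grid[min(gridPoints, iBest + 1L)]
  op <- optimize(function(d) capacityReplica(withDelta(d)), c(lo, hi),
                 maximum = TRUE, tol = 1e-7)
  list(deltaStar = op$maximum, alphaStar = op$objective, grid = grid,
       alphaGrid = ag)
}

#' Theoretical synaptic weight distribution at capacity
#'
#' At maximal capacity the weight distribution of the excitatory
#' perceptron is a delta mass at zero (silent synapses) plus the positive
#' part of a Gaussian: in units of the Gaussian sd \eqn{\lambda}, the
#' untruncated mean is \eqn{-s} where `s` is the solution's
#' silent-fraction parameter; the zero-weight mass is \eqn{\Phi(s)}
#' (equivalently \eqn{H(-s)}).  The positive-branch moments follow in
#' closed form; their sd/mean ratio is scale invariant and equals
#' \eqn{\sqrt{\pi/2 - 1} \approx 0.7555} whenever `s = 0`.
#'
#' @param solution a [ReplicaSolution-class] with `atCapacity = TRUE`.
#' @return list with `silentFraction`, `mu` (untruncated mean, units of
#'   sd), `sd` (= 1, the scale unit), `meanPositive`, `sdPositive`, and
#'   `ratio` (= sdPositive/meanPositive).
#' @examples
#' weightDistributionTheory(capacitySolution(scaledParams()))
#' @export
weightDistributionTheory <- function(solution) {
  stopifnot(is(solution, "ReplicaSolution"))
  if (!solution@atCapacity)
    stop("the weight distribution formula applies at capacity; ",
         "use capacitySolution()")
  s <- solution@s
  H <- .Hfun(s)
  m1 <- .I1fun(s) / H            # E[w | w > 0] in units of lambda
  m2 <- .I2fun(s) / H
  v <- m2 - m1^2
  list(silentFraction = pnorm(s), mu = -s, sd = 1,
       meanPositive = m1, sdPositive = sqrt(v), ratio = sqrt(v) / m1)
}

#' Bridges between scaled theory units and simulation units
#'
#' `deltaSimFromScaled` converts a scaled bistable range into the absolute
#' range for a simulated neuron (\eqn{\Delta = \delta_S\,\theta/\sqrt{N}});
#' `kappaScaledFromNorm` converts the norm-referenced simulation
#' robustness (margin `kappa * ||w||/sqrt(N)`) into the drive-sd units `K`
#' used internally by the theory, \eqn{K = \kappa/\sqrt{f_{in}(1-f_{in})N}}.
#'
#' @param deltaS scaled bistable range.
#' @param theta,N simulation threshold and input count.
#' @param kappa norm-referenced robustness of [neuronConfig()].
#' @param fIn input coding level.
#' @return numeric scalar.
#' @export
deltaSimFromScaled <- function(deltaS, theta, N) deltaS * theta / sqrt(N)

#' @rdname deltaSimFromScaled
#' @export
kappaScaledFromNorm <- function(kappa, fIn, N)
  kappa / sqrt(fIn * (1 - fIn) * N)
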