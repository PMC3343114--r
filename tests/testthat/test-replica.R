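test_that("replica capacity reproduces the classical excitatory results", {
  ## sign-constrained, unbiased, uncorrelated: capacity 1 exactly
  expect_equal(capacityReplica(scaledParams()), 1, tolerance = 1e-7)
  ## independent of the output correlation when delta = 0
  expect_equal(capacityReplica(scaledParams(cOut = 0.8)), 1,
               tolerance = 1e-7)
  expect_equal(capacityReplica(scaledParams(cOut = 0.4, fOut = 0.3)),
               capacityReplica(scaledParams(cOut = 0, fOut = 0.3)),
               tolerance = 1e-7)
  ## sparser outputs store more
  expect_gt(capacityReplica(scaledParams(fOut = 0.2)), 1.2)
  ## robustness reduces capacity monotonically
  aK <- vapply(c(0, 0.5, 1), function(k)
    capacityReplica(scaledParams(kappaS = k)), 1)
  expect_true(all(diff(aK) < 0))
})

test_that("the capacity solution satisfies its own saddle equations", {
  sol <- capacitySolution(scaledParams(deltaS = 1.2, cOut = 0.5))
  expect_true(sol@atCapacity)
  expect_lt(max(abs(sol@residuals)), 1e-10)
  expect_equal(sum(sol@orderParams$classWeights), 1, tolerance = 1e-12)
  ## silent fraction is one half without robustness at delta = 0
  s0 <- capacitySolution(scaledParams())
  expect_equal(s0@silentFraction, 0.5, tolerance = 1e-9)
  expect_equal(s0@G, 0, tolerance = 1e-9)
})

test_that("the finite-load saddle solver converges with tiny residuals", {
  sol <- solveSaddle(scaledParams(), alpha = 0.6)
  expect_false(sol@atCapacity)
  expect_lt(max(abs(sol@residuals)), 1e-10)
  expect_gt(sol@q, 0)
  expect_lt(sol@q, 1)
  ## overlap grows toward 1 as the load approaches capacity
  sol2 <- solveSaddle(scaledParams(), alpha = 0.9)
  expect_gt(sol2@q, sol@q)
  ## a load above capacity collapses with diagnostics
  expect_error(solveSaddle(scaledParams(), alpha = 1.3), "capacity")
})

test_that("the general solver reduces to an independent two-class solver", {
  ## independently coded standard (non-bistable, uncorrelated) solver:
  ## two constraint classes, adaptive quadrature instead of Gauss-Hermite
  standardSolver <- function(alpha, fOut = 0.5, maxit = 4000, damp = 0.5) {
    mills <- function(x)
      exp(dnorm(x, log = TRUE) - pnorm(x, lower.tail = FALSE, log.p = TRUE))
    gint <- function(fn) {
      for (tol in c(1e-11, 1e-10, 1e-9)) {
        v <- tryCatch(
          integrate(function(t) dnorm(t) * fn(t), -12, 12, rel.tol = tol,
                    abs.tol = tol, subdivisions = 800L)$value,
          error = function(e) NULL)
        if (!is.null(v)) return(v)
      }
      stop("adaptive quadrature failed")
    }
    q <- 0.3; A <- 3; C <- 1; mh <- 0; G <- 0
    for (it in seq_len(maxit)) {
      x <- 1 - q
      mom <- function(A, C, mh, what) gint(function(t) {
        mu <- (sqrt(C) * t - mh) / A
        beta <- mu * sqrt(A)
        w1 <- mu + mills(-beta) / sqrt(A)
        switch(what, M1 = w1, M2 = mu^2 + 1 / A + mu * mills(-beta) / sqrt(A),
               Q = w1^2)
      })
      sc <- mom(A, C, mh, "M2")
      A <- A * sc; C <- C * sc; mh <- mh * sqrt(sc)
      ei <- function(G, what) {
        uP <- function(t) (G - sqrt(q) * t) / sqrt(x)     # target-1 class
        uM <- function(t) (-G - sqrt(q) * t) / sqrt(x)    # target-0 class
        gint(function(t) {
          RP <- mills(uP(t)); RM <- mills(uM(t))
          switch(what,
                 lock = fOut * RP - (1 - fOut) * RM,
                 Rp = fOut * RP * (RP - uP(t)) + (1 - fOut) * RM * (RM - uM(t)),
                 Ru = fOut * RP * uP(t) + (1 - fOut) * RM * uM(t))
        })
      }
      Gn <- uniroot(function(g) ei(g, "lock"), c(-40, 40), tol = 1e-13)$root
      An <- alpha / x * ei(Gn, "Rp")
      Cn <- An + alpha / x * ei(Gn, "Ru")
      qn <- mom(A, C, mh, "Q")
      mhn <- uniroot(function(m) mom(An, Cn, m, "M2") - 1,
                     c(-5 * sqrt(Cn) - 5, 5 * sqrt(Cn) + 5),
                     tol = 1e-13)$root
      step <- max(abs(c(qn - q, An - A, Cn - C, mhn - mh, Gn - G)) /
                    pmax(1, abs(c(q, A, C, mh, G))))
      q <- q + damp * (qn - q); A <- A + damp * (An - A)
      C <- C + damp * (Cn - C); mh <- mh + damp * (mhn - mh)
      G <- G + damp * (Gn - G)
      if (step < 1e-12) break
    }
    list(q = q, G = G, s = mh / sqrt(C))
  }
  ref <- standardSolver(0.6)
  sol <- solveSaddle(scaledParams(), alpha = 0.6)
  expect_equal(sol@q, ref$q, tolerance = 1e-8)
  expect_equal(sol@G, ref$G, tolerance = 1e-8)
  expect_equal(sol@s, ref$s, tolerance = 1e-8)
})

test_that("bistability helps only when the output is correlated", {
  opt0 <- optimalBistableRange(scaledParams(cOut = 0))
  expect_equal(opt0$deltaStar, 0, tolerance = 1e-6)
  expect_equal(opt0$alphaStar, 1, tolerance = 1e-6)
  opts <- lapply(c(0.2, 0.4, 0.6), function(co)
    optimalBistableRange(scaledParams(cOut = co)))
  dStar <- vapply(opts, `[[`, 1, "deltaStar")
  aStar <- vapply(opts, `[[`, 1, "alphaStar")
  expect_true(all(dStar > 0))
  expect_true(all(diff(c(opt0$deltaStar, dStar)) > 0))
  expect_true(all(diff(c(opt0$alphaStar, aStar)) > 0))
  ## silent synapses at the optimal range: one half, for every correlation
  for (i in seq_along(opts)) {
    sol <- capacitySolution(scaledParams(deltaS = dStar[i],
                                         cOut = c(0.2, 0.4, 0.6)[i]))
    expect_equal(sol@silentFraction, 0.5, tolerance = 1e-4)
  }
})

test_that("optimal range scales with input sparsity but capacity does not", {
  oHalf <- optimalBistableRange(scaledParams(cOut = 0.4, fIn = 0.5))
  oSparse <- optimalBistableRange(scaledParams(cOut = 0.4, fIn = 0.2))
  expect_gt(oSparse$deltaStar, oHalf$deltaStar)
  expect_equal(oSparse$alphaStar, oHalf$alphaStar, tolerance = 1e-5)
  ## at fixed delta the capacity does depend on the input coding level
  expect_gt(abs(capacityReplica(scaledParams(deltaS = 1.2, cOut = 0.4,
                                             fIn = 0.2)) -
                capacityReplica(scaledParams(deltaS = 1.2, cOut = 0.4,
                                             fIn = 0.5))), 1e-3)
})

test_that("theoretical weight distribution is a truncated Gaussian plus a delta", {
  wd <- weightDistributionTheory(capacitySolution(scaledParams()))
  expect_equal(wd$silentFraction, 0.5, tolerance = 1e-9)
  expect_equal(wd$ratio, sqrt(pi / 2 - 1), tolerance = 1e-9)
  ## normalization: delta mass plus positive-branch integral equals 1
  sol <- capacitySolution(scaledParams(kappaS = 0.8))
  s <- sol@s
  posMass <- integrate(function(w) dnorm(w + s), 0, Inf,
                       rel.tol = 1e-12)$value
  expect_equal(sol@silentFraction + posMass, 1, tolerance = 1e-8)
  ## robustness silences more synapses, independently of the correlation
  silK <- vapply(c(0, 0.5, 1), function(k)
    capacitySolution(scaledParams(kappaS = k))@silentFraction, 1)
  expect_true(all(diff(silK) > 0))
  expect_equal(capacitySolution(scaledParams(kappaS = 1,
                                             cOut = 0.6))@silentFraction,
               silK[3], tolerance = 1e-6)
})

test_that("simulated bistable capacity tracks the replica prediction", {
  ## theory overlay at N = 200, c_out = 0.5: simulation within a couple of
  ## error bars of the large-N value, and the bistable gain is visible
  N <- 200
  sims <- lapply(c(0, 1.2), function(ds)
    estimateCapacity(markovSpec(0.5), markovSpec(0.5, 0.5),
                     neuronConfig(N, delta = deltaSimFromScaled(ds, 1, N)),
                     learnerConfig(rule = "bistable_switching",
                                   maxEpochs = 3000),
                     nTrials = 4, seed = 900 + ds * 10, alphaMax = 4))
  theos <- vapply(c(0, 1.2), function(ds)
    capacityReplica(scaledParams(deltaS = ds, cOut = 0.5)), 1)
  for (i in 1:2)
    expect_lt(abs(sims[[i]]@alpha - theos[i]),
              max(2.5 * sims[[i]]@spread, 0.15))
  expect_gt(sims[[2]]@alpha, sims[[1]]@alpha)
})
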