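test_that("the update rule clips at zero and leaves correct outputs alone", {
  expect_equal(applyUpdate(c(0.3, 0.1), c(1, 1), y = 1, yTarget = 1,
                           eta = 0.5), c(0.3, 0.1))
  ## LTD driven below zero is clipped (hard bound of excitatory synapses)
  expect_equal(applyUpdate(c(0.1, 0.2), c(1, 0), y = 1, yTarget = 0,
                           eta = 0.5), c(0, 0.2))
  expect_equal(applyUpdate(c(0, 0), c(1, 0), y = 0, yTarget = 1, eta = 0.5),
               c(0.5, 0))
  ## unconstrained mode keeps the negative excursion
  expect_equal(applyUpdate(c(0.1, 0), c(1, 0), y = 1, yTarget = 0, eta = 0.5,
                           constrained = FALSE), c(-0.4, 0))
})

test_that("weights stay nonnegative under random update streams", {
  set.seed(99)
  w <- rep(0, 20)
  for (i in 1:500) {
    x <- rbinom(20, 1, 0.5)
    w <- applyUpdate(w, x, y = rbinom(1, 1, 0.5), yTarget = rbinom(1, 1, 0.5),
                     eta = runif(1, 0, 0.3))
    expect_true(all(w >= 0))
  }
})

test_that("single-pattern and contradictory sequences behave as expected", {
  ## one constraint with an active input: learnable
  s <- sequenceFromMatrix(matrix(c(1L, 0L, 1L), 1, 3), 1L)
  tr <- trainPerceptron(s, neuronConfig(3), learnerConfig(eta = 0.5, seed = 1))
  expect_true(converged(tr))
  expect_gt(drive(weights(tr), inputMatrix(s)[1, ]), 1)
  ## identical inputs, identical previous-target states, opposite targets
  X <- rbind(c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 0L), c(1L, 1L, 0L))
  y <- c(0L, 1L, 0L, 0L)   # patterns 2 and 4 share previous target 0
  s2 <- sequenceFromMatrix(X[c(1, 2, 1, 3), ], c(0L, 1L, 0L, 0L))
  tr2 <- trainPerceptron(s2, neuronConfig(3),
                         learnerConfig(eta = 0.1, maxEpochs = 50, seed = 2))
  expect_false(converged(tr2))
  expect_gt(tr2@finalErrors, 0)
})

test_that("a converged result certifies all constraints", {
  for (seed in c(2, 5, 8, 13)) {
    s <- randomInstance(seed, N = 20, P = 14, cOut = 0.4)
    nc <- neuronConfig(20)
    tr <- trainPerceptron(s, nc, learnerConfig(maxEpochs = 2000, seed = seed))
    if (converged(tr)) {
      expect_true(all(constraintMargins(weights(tr), s, nc) > 0))
      expect_true(all(weights(tr) >= 0))
    }
  }
})

test_that("the safe learning rate scales as 1/N and certifies convergence", {
  n1 <- neuronConfig(100); n2 <- neuronConfig(200)
  e1 <- safeLearningRate(n1, feasibilityMargin = 0.05,
                         maxActiveFraction = 0.6)
  e2 <- safeLearningRate(n2, feasibilityMargin = 0.05,
                         maxActiveFraction = 0.6)
  expect_gt(e1, 0)
  expect_lte(e2, e1 / 2 + 1e-15)
  ## oracle-feasible instances + safe rate: convergence every time, with
  ## the update count below the distance-contraction bound |w*|^2 a N / d^2
  nOK <- 0; nTot <- 0
  for (seed in 1:40) {
    s <- randomInstance(seed + 100, N = 20, P = 15, cOut = 0.3)
    nc <- neuronConfig(20)
    fz <- feasibleSequence(s, nc)
    if (!fz$feasible) next
    nTot <- nTot + 1
    a <- max(rowSums(inputMatrix(s))) / 20
    eta <- safeLearningRate(nc, fz$slack, a)
    tr <- trainPerceptron(s, nc, learnerConfig(eta = eta, maxEpochs = 20000,
                                               seed = seed))
    if (converged(tr)) nOK <- nOK + 1
    bound <- sum(fz$witness^2) * a * 20 / fz$slack^2
    expect_lte(updateCount(tr), bound)
  }
  expect_gt(nTot, 10)
  expect_equal(nOK, nTot)
})

test_that("state switching by the error signal beats the NSS control", {
  ## bistable unit, correlated output: the rule whose error signal resets
  ## the state to the target converges where the no-switching control fails
  N <- 60; P <- 66
  nSwitch <- 0; nNss <- 0
  for (seed in 1:6) {
    s <- generateAssociations(markovSpec(0.5), markovSpec(0.5, 0.6),
                              N = N, P = P, seed = seed)
    nc <- neuronConfig(N, theta = 1,
                       delta = deltaSimFromScaled(1.5, 1, N))
    sw <- trainPerceptron(s, nc, learnerConfig(rule = "bistable_switching",
                                               maxEpochs = 2000, seed = seed))
    ns <- trainPerceptron(s, nc, learnerConfig(rule = "bistable_nss",
                                               maxEpochs = 2000, seed = seed))
    nSwitch <- nSwitch + converged(sw)
    nNss <- nNss + converged(ns)
  }
  expect_gte(nSwitch, nNss)
  expect_gt(nSwitch, 0)
})

test_that("teacher-forced training implies a correct free-run replay", {
  for (seed in c(3, 9)) {
    N <- 40
    s <- generateAssociations(markovSpec(0.5), markovSpec(0.5, 0.5),
                              N = N, P = 30, seed = seed)
    nc <- neuronConfig(N, delta = deltaSimFromScaled(1, 1, N))
    tr <- trainPerceptron(s, nc, learnerConfig(rule = "bistable_switching",
                                               maxEpochs = 3000, seed = seed))
    if (converged(tr))
      expect_identical(replaySequence(weights(tr), s, nc),
                       targetStates(s))
  }
})
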