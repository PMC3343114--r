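test_that("transition probabilities reproduce coding level and correlation", {
  ## i.i.d. and frozen limits
  expect_equal(unname(transitionProbabilities(markovSpec(0.5, 0))),
               c(0.5, 0.5))
  expect_equal(unname(transitionProbabilities(markovSpec(0.3, 1))), c(1, 0))
  ## frozen values verified against exact chain enumeration
  tp <- transitionProbabilities(markovSpec(0.2, 0.5))
  expect_equal(unname(tp), c(0.6, 0.1))
  or <- chainStatsOracle(tp[["activeGivenActive"]],
                         tp[["activeGivenInactive"]])
  expect_equal(or$f, 0.2, tolerance = 1e-12)
  expect_equal(or$corr, 0.5, tolerance = 1e-12)
  ## stationarity and correlation hold across a parameter grid
  for (f in seq(0.1, 0.9, by = 0.2)) for (cc in seq(0, 1, by = 0.25)) {
    tp <- transitionProbabilities(markovSpec(f, cc))
    or <- chainStatsOracle(tp[[1]], tp[[2]], piFrozen = c(1 - f, f))
    expect_equal(or$f, f, tolerance = 1e-10)
    if (cc < 1) expect_equal(or$corr, cc, tolerance = 1e-10)
  }
  expect_error(markovSpec(0, 0.5), "coding level")
  expect_error(markovSpec(0.5, 1.2), "correlation")
})

test_that("pair probabilities match exact chain enumeration and marginals", {
  expect_equal(unname(pairProbabilities(markovSpec(0.5, 0))), rep(0.25, 4))
  p <- pairProbabilities(markovSpec(0.3, 1))
  expect_equal(unname(p[c("p11", "p00", "p01", "p10")]), c(0.3, 0.7, 0, 0))
  p <- pairProbabilities(markovSpec(0.2, 0.5))
  expect_equal(unname(p[c("p10", "p11", "p00", "p01")]),
               c(0.08, 0.12, 0.72, 0.08))
  for (f in seq(0.1, 0.9, by = 0.2)) for (cc in seq(0, 1, by = 0.25)) {
    sp <- markovSpec(f, cc)
    p <- pairProbabilities(sp)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p["p01"]), unname(p["p10"]))
    ## marginals: current active and previous active both equal f
    expect_equal(unname(p["p11"] + p["p01"]), f, tolerance = 1e-12)
    expect_equal(unname(p["p11"] + p["p10"]), f, tolerance = 1e-12)
    tp <- transitionProbabilities(sp)
    expect_equal(unname(p[c("p00", "p01", "p10", "p11")]),
                 unname(chainStatsOracle(tp[[1]], tp[[2]],
                                         piFrozen = c(1 - f, f))$joint),
                 tolerance = 1e-12)
  }
})

test_that("generated sequences have the prescribed structure", {
  ## single pattern: no transitions, stationary start
  s1 <- generateAssociations(markovSpec(0.4), markovSpec(0.5), 3, 1, seed = 5)
  expect_equal(dim(inputMatrix(s1)), c(1L, 3L))
  ## frozen chains replicate the first pattern
  sf <- generateAssociations(markovSpec(0.5, 1), markovSpec(0.3, 1),
                             N = 7, P = 20, seed = 2)
  X <- inputMatrix(sf)
  expect_true(all(apply(X, 2, function(col) all(col == col[1]))))
  expect_true(all(targetStates(sf) == targetStates(sf)[1]))
  ## determinism: identical seeds, bit-for-bit
  a <- generateAssociations(markovSpec(0.5, 0.8), markovSpec(0.5), 11, 40, 9)
  b <- generateAssociations(markovSpec(0.5, 0.8), markovSpec(0.5), 11, 40, 9)
  expect_identical(inputMatrix(a), inputMatrix(b))
  expect_identical(targetStates(a), targetStates(b))
  ## growing N leaves earlier columns untouched (per-column child streams)
  big <- generateAssociations(markovSpec(0.5, 0.8), markovSpec(0.5), 15, 40, 9)
  expect_identical(inputMatrix(big)[, 1:11], inputMatrix(a))
  expect_error(generateAssociations(markovSpec(0.5), markovSpec(0.5), 0, 5),
               "positive")
})

test_that("long streams match their Markov statistics within 3 SE", {
  s <- generateAssociations(markovSpec(0.5, 0.8), markovSpec(0.3, 0.6),
                            N = 200, P = 2000, seed = 31)
  X <- inputMatrix(s)
  ## column means: chain CLT variance f(1-f)(1+c)/(1-c) / P
  seMean <- sqrt(0.25 * (1 + 0.8) / (1 - 0.8) / 2000)
  expect_lt(abs(mean(colMeans(X)) - 0.5), 3 * seMean / sqrt(200))
  ## pooled lag-1 correlation across columns
  lag1 <- vapply(seq_len(200), function(k) empiricalStats(X[, k])$lag1, 1)
  seCor <- sqrt((1 - 0.8^2) / 2000)
  expect_lt(abs(mean(lag1, na.rm = TRUE) - 0.8), 3 * seCor / sqrt(200))
  ## output stream statistics
  es <- empiricalStats(targetStates(s))
  expect_lt(abs(es$mean - 0.3), 3 * sqrt(0.21 * (1.6 / 0.4) / 2000))
  expect_lt(abs(es$lag1 - 0.6), 3 * sqrt((1 - 0.36) / 2000))
  ## empirical pair frequencies approach the stationary pair law
  y <- targetStates(generateAssociations(markovSpec(0.5), markovSpec(0.3, 0.6),
                                         N = 1, P = 10000, seed = 77))
  emp <- table(factor(paste0(y[-10000], y[-1]),
                      levels = c("00", "01", "10", "11"))) / 9999
  th <- pairProbabilities(markovSpec(0.3, 0.6))
  for (k in names(th))
    expect_lt(abs(emp[[substring(k, 2)]] - th[[k]]),
              3 * sqrt(th[[k]] * (1 - th[[k]]) / 9999) *
                sqrt((1 + 0.6) / (1 - 0.6)))
})

test_that("uncorrelated generation is indistinguishable from iid Bernoulli", {
  ## chi-square goodness of fit on the 8 patterns of 3 cells
  s <- generateAssociations(markovSpec(0.4, 0), markovSpec(0.5),
                            N = 3, P = 6000, seed = 123)
  X <- inputMatrix(s)
  lab <- X[, 1] * 4 + X[, 2] * 2 + X[, 3]
  obs <- tabulate(lab + 1, nbins = 8)
  pcell <- vapply(0:7, function(v) {
    bits <- as.integer(intToBits(v))[3:1]
    prod(ifelse(bits == 1, 0.4, 0.6))
  }, 1)
  pv <- suppressWarnings(chisq.test(obs, p = pcell)$p.value)
  expect_gt(pv, 0.001)
})

test_that("empirical stats handle degenerate and alternating streams", {
  es <- empiricalStats(c(0, 1, 0, 1, 0, 1))
  expect_equal(es$mean, 0.5)
  expect_equal(es$lag1, -1)
  expect_false(es$degenerate)
  es <- empiricalStats(rep(1, 4))
  expect_equal(es$mean, 1)
  expect_true(es$degenerate)
  expect_true(is.na(es$lag1))
  expect_error(empiricalStats(1), "length")
})

test_that("plain-text serialization round-trips exactly", {
  s <- generateAssociations(markovSpec(0.3, 0.4), markovSpec(0.6, 0.2),
                            N = 9, P = 17, seed = 42)
  f <- tempfile(fileext = ".txt")
  writeAssociations(s, f)
  r <- readAssociations(f)
  expect_identical(inputMatrix(r), inputMatrix(s))
  expect_identical(targetStates(r), targetStates(s))
  expect_equal(codingLevel(r@inputSpec), 0.3)
  expect_equal(lagCorrelation(r@outputSpec), 0.2)
  ## gz round trip
  fz <- tempfile(fileext = ".txt.gz")
  writeAssociations(s, fz)
  expect_identical(inputMatrix(readAssociations(fz)), inputMatrix(s))
  unlink(c(f, paste0(f, ".json"), fz, paste0(fz, ".json")))
})
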