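test_that("model prediction follows the closed-form network equation", {
  # empty set -> zero tensor
  empty <- new("NetworkSet", networks = list(), explainedVariance = 0,
               freqs = seq(50, 400, 50), gcdFreq = 50,
               neuronIds = c("a", "b"), trialIds = "t1", fitMeta = list())
  expect_true(all(modelPredict(empty) == 0))

  # single network, two neurons, 1 ms separation: phase -2 pi f 0.001
  g <- 50
  net <- new("SpikeNetwork", neuronProfile = c(1, 1) / sqrt(2),
             timeProfile = c(0, 0.001), freqProfile = rep(1 / sqrt(8), 8),
             trialProfile = 1, scale = 2, gcdFreq = g, neuronIds = c("a", "b"))
  ns <- new("NetworkSet", networks = list(net), explainedVariance = 1,
            freqs = seq(g, by = g, length.out = 8), gcdFreq = g,
            neuronIds = c("a", "b"), trialIds = "t1", fitMeta = list())
  xh <- modelPredict(ns)
  expect_equal(Arg(xh[1, 2, , 1]), -2 * pi * ns@freqs * 0.001,
               tolerance = 1e-12)
  expect_equal(xh[1, 1, , 1], rep(2 * 0.5 * (1 / 8) + 0i, 8)) # lambda a^2 b2 c2

  # Hermitian, real nonnegative diagonal for random valid profiles
  rs <- randomNetworkSet(3, F = 3)
  xh <- modelPredict(rs)
  for (k in seq_len(dim(xh)[3])) for (l in seq_len(dim(xh)[4])) {
    expect_equal(xh[, , k, l], Conj(t(xh[, , k, l])))
    expect_true(all(Re(diag(xh[, , k, l])) >= 0))
  }
})

test_that("explained variance has its fixed points", {
  x <- modelPredict(randomNetworkSet(5))
  expect_equal(explVariance(x, x), 1)
  expect_equal(explVariance(x, array(0 + 0i, dim(x))), 0)
  expect_error(explVariance(array(0 + 0i, c(1, 1, 1, 1)),
                            array(0 + 0i, c(1, 1, 1, 1))), "all-zero")
})

test_that("time-profile offsets and whole cycles leave the model unchanged", {
  rs <- randomNetworkSet(7, F = 2)
  x0 <- modelPredict(rs)
  shifted <- rs
  shifted@networks <- lapply(rs@networks, function(n) {
    n@timeProfile <- n@timeProfile + 0.0123   # constant offset
    n
  })
  expect_equal(modelPredict(shifted), x0, tolerance = 1e-10)
  cycled <- rs
  cycled@networks <- lapply(rs@networks, function(n) {
    n@timeProfile <- n@timeProfile + 1 / n@gcdFreq  # one full cycle
    n
  })
  expect_equal(modelPredict(cycled), x0, tolerance = 1e-10)
})

test_that("indeterminacy resolution preserves the prediction exactly", {
  rs <- randomNetworkSet(11, F = 2)
  x0 <- modelPredict(rs)
  rere <- rs
  rere@networks <- lapply(rs@networks, function(n) {
    # scramble the resolved form: offset sigma, flip sign, rescale
    m <- stnets:::resolveNetwork(-3 * n@neuronProfile,
                                 n@timeProfile + 0.004 + 1 / n@gcdFreq,
                                 5 * n@freqProfile^2, 2 * n@trialProfile^2,
                                 n@gcdFreq, n@neuronIds)
    m@scale <- m@scale * n@scale / (9 * 5 * 2)
    m
  })
  expect_equal(modelPredict(rere), x0, tolerance = 1e-10)
  # and resolving an already-resolved network is the identity
  n <- rs@networks[[1]]
  m <- stnets:::resolveNetwork(n@neuronProfile, n@timeProfile,
                               n@freqProfile^2, n@trialProfile^2,
                               n@gcdFreq, n@neuronIds)
  expect_equal(m@neuronProfile, n@neuronProfile)
  expect_equal(m@timeProfile, n@timeProfile)
})

test_that("fitting recovers noiseless networks and model-generated tensors", {
  # a 3-neuron sequence (plus one silent neuron), no noise, F = 1
  cfg <- simConfig(nNeurons = 4, nTrials = 30,
                   networks = list(list(members = 1:3,
                                        timeline = c(0, 1, 2) / 1e3)),
                   repeats = matrix(rep(1:3, 10), 30, 1), seed = 5)
  sim <- simulateRecording(cfg)
  x <- computeCrossSpectra(sim$recording)
  ns <- fitSpace(x, 1, nInit = 5, seed = 2)
  rep <- recoveryReport(ns, sim$truth)
  expect_gte(rep$neuronR, 0.99)
  expect_gte(rep$timeCoef, 0.99)
  expect_equal(unname(diff(timeProfile(networks(ns)[[1]])[1:3])),
               c(0.001, 0.001), tolerance = 5e-5)
  # F = 0 returns an empty set
  ns0 <- fitSpace(x, 0)
  expect_length(networks(ns0), 0)
  expect_equal(explainedVariance(ns0), 0)

  # parameter recovery on exact model-generated tensors
  for (s in 1:10) {
    Fn <- 1 + s %% 3
    rs <- randomNetworkSet(100 + s, J = 10, F = Fn, K = 10, L = 12)
    x <- new("CrossSpectra", values = modelPredict(rs), freqs = rs@freqs,
             neuronIds = rs@neuronIds, trialIds = rs@trialIds,
             config = SpectralConfig(freqs = rs@freqs), provenance = list())
    fit <- fitSpace(x, Fn, nInit = 8, seed = s)
    expect_gt(explainedVariance(fit), 1 - 1e-6)
    m <- matchNetworks(rs, fit)
    expect_true(all(!is.na(m$b)))
    expect_true(all(m$neuron >= 0.99))
    expect_true(all(m$time >= 0.99))
    expect_true(all(m$trial >= 0.99))
  }
})

test_that("the ALS loss never increases across iterations", {
  for (s in 1:3) {
    rec <- randomRecording(20 + s, J = 5, L = 4, nSpk = 30, fs = 20000)
    x <- computeCrossSpectra(rec)
    fit <- fitSpace(x, 3, nInit = 4, seed = s, maxIter = 200)
    expect_lte(fit@fitMeta$worstLossIncrease, 1e-10)
  }
})

test_that("fitted profiles satisfy the stated conventions", {
  sim <- simulateRecording(twoNetworkConfig(3))
  x <- computeCrossSpectra(sim$recording)
  ns <- fitSpace(x, 2, nInit = 5, seed = 1)
  g <- gcdFreq(ns)
  for (n in networks(ns)) {
    expect_equal(sqrt(sum(n@neuronProfile^2)), 1, tolerance = 1e-10)
    expect_gte(mean(n@neuronProfile), 0)
    expect_equal(sum(freqProfile(n)), 1, tolerance = 1e-10)
    expect_equal(sum(trialProfile(n)), 1, tolerance = 1e-10)
    expect_true(all(n@freqProfile >= 0) && all(n@trialProfile >= 0))
    expect_equal(n@timeProfile[which.max(abs(n@neuronProfile))], 0)
    expect_true(all(n@timeProfile > -1 / (2 * g) - 1e-12 &
                    n@timeProfile <= 1 / (2 * g) + 1e-12))
    expect_gt(n@scale, 0)
  }
})

test_that("trial-profile refit updates only trial profiles and scales", {
  sim <- simulateRecording(twoNetworkConfig(9))
  x <- computeCrossSpectra(sim$recording)
  ns <- fitSpace(x, 2, nInit = 5, seed = 1)
  # refit against the same tensor: a fixed point
  same <- refitTrialProfiles(x, ns)
  for (f in 1:2) {
    expect_identical(same@networks[[f]]@neuronProfile,
                     ns@networks[[f]]@neuronProfile)
    expect_identical(same@networks[[f]]@timeProfile,
                     ns@networks[[f]]@timeProfile)
    expect_identical(same@networks[[f]]@freqProfile,
                     ns@networks[[f]]@freqProfile)
    expect_equal(same@networks[[f]]@trialProfile,
                 ns@networks[[f]]@trialProfile, tolerance = 1e-6)
  }
  # refit against trial-normalized spectra changes c but not a, sigma
  xt <- trialwiseNormalize(x, guardSeed = 1)
  ref <- refitTrialProfiles(xt, ns)
  for (f in 1:2)
    expect_identical(ref@networks[[f]]@timeProfile,
                     ns@networks[[f]]@timeProfile)
})
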