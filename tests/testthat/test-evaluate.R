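test_that("Pearson recovery matches the textbook formula and rejects constants", {
  expect_equal(pearsonRecovery(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearsonRecovery(c(1, 2, 3), -c(1, 2, 3)), -1)
  x <- c(0.1, 0.2, 0.4); y <- c(0, 1, 3)
  byHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonRecovery(x, y), byHand)
  expect_error(pearsonRecovery(c(1, 1, 1), y), "constant")
})

test_that("time recovery is offset- and cycle-invariant with closed forms", {
  g <- 50
  s <- c(0, 0.001, 0.002); A <- c(1, 1, 1)
  expect_equal(timeRecovery(s, s, A, g), 1)
  expect_equal(timeRecovery(s + 0.007, s, A, g), 1)
  expect_equal(timeRecovery(s + 1 / g, s, A, g), 1, tolerance = 1e-12)
  # two equal members 10 ms apart at 50 Hz: |1 - 1| / 2 = 0
  expect_equal(timeRecovery(c(0, 0.01), c(0, 0), c(1, 1), g), 0,
               tolerance = 1e-12)
  expect_error(timeRecovery(s, s, c(0, 0, 0), g), "zero")
})

test_that("trial-profile CoV uses the population SD", {
  expect_equal(trialProfileCoV(rep(2, 10)), 0)
  expect_equal(trialProfileCoV(c(1, 1, 3, 3)), 50)
  withr::with_seed(2, {
    for (i in 1:5) {
      v <- runif(20, 0.1, 2)
      twoPass <- sqrt(sum((v - mean(v))^2) / length(v))
      expect_equal(trialProfileCoV(v), 100 * twoPass / mean(v))
    }
  })
  expect_error(trialProfileCoV(numeric(0)), "empty")
  expect_error(trialProfileCoV(c(0, 0)), "positive")
})

test_that("recovery reports pair greedily and mark unmatched truths", {
  sim <- simulateRecording(simConfig(seed = 8))
  truthNets <- truthAsNetworks(sim$truth)
  rep <- recoveryReport(truthNets, sim$truth)    # extracted equal to truth
  expect_equal(rep$matched, 1:4)
  expect_true(all(abs(rep$timeCoef - 1) < 1e-10))
  expect_true(all(rep$trialR > 0.999))
  # fewer extracted than simulated: absent rows
  two <- truthNets; two@networks <- two@networks[1:2]
  rep2 <- recoveryReport(two, sim$truth)
  expect_equal(sum(is.na(rep2$matched)), 2)
})

test_that("cross-correlograms are symmetric with peaks at the pair delay", {
  rec <- SpikeRecording(list(list(0.500, 0.501)), 1)
  cc <- crossCorrelogram(rec, c(1, 2))
  expect_equal(cc$lag[which.max(cc$value)], 0.001)
  cc21 <- crossCorrelogram(rec, c(2, 1))
  expect_equal(cc$value, rev(cc21$value), tolerance = 1e-12)
  r2 <- randomRecording(5, J = 2, nSpk = 12, fs = 20000)
  a <- crossCorrelogram(r2, c(1, 2)); b <- crossCorrelogram(r2, c(2, 1))
  expect_equal(a$value, rev(b$value), tolerance = 1e-9)
  # empty train -> all-zero curve
  r3 <- SpikeRecording(list(list(c(0.1, 0.2), numeric(0))), 1)
  expect_true(all(crossCorrelogram(r3, c(1, 2))$value == 0))
})

test_that("cross-correlograms equal a brute-force convolution oracle", {
  rec <- randomRecording(6, J = 2, L = 1, dur = 0.2, nSpk = 6, fs = 20000)
  fwhm <- 5e-4; fs <- 20000
  sdS <- (fwhm / (2 * sqrt(2 * log(2)))) * fs
  half <- as.integer(ceiling(4 * sdS))
  n1 <- round(spikeTimes(rec, 1, 1) * fs); n2 <- round(spikeTimes(rec, 1, 2) * fs)
  N <- round(0.2 * fs) + 1 + 2 * half
  g1 <- g2 <- numeric(N + 800)
  kn <- (-half):half
  for (n in n1) g1[n + half + 1 + kn + 400] <-
    g1[n + half + 1 + kn + 400] + exp(-kn^2 / (2 * sdS^2))
  for (n in n2) g2[n + half + 1 + kn + 400] <-
    g2[n + half + 1 + kn + 400] + exp(-kn^2 / (2 * sdS^2))
  lags <- seq(-400, 400, 20)
  brute <- vapply(lags, function(tau) {
    idx <- seq_along(g1)
    ok <- idx + tau >= 1 & idx + tau <= length(g2)
    sum(g1[idx[ok]] * g2[idx[ok] + tau])
  }, 0)
  cc <- crossCorrelogram(rec, c(1, 2), maxLag = 0.020, step = 20 / fs)
  expect_equal(cc$value, brute, tolerance = 1e-9)
})

test_that("extracted delays agree with correlogram peaks on a toy recording", {
  # two 3-neuron sequences at 1 ms steps sharing the middle neuron
  cfg <- simConfig(nNeurons = 5, nTrials = 40,
                   networks = list(list(members = 1:3, timeline = c(0, 1, 2) / 1e3),
                                   list(members = 3:5, timeline = c(0, 1, 2) / 1e3)),
                   repeats = cbind(rep(1:2, 20), rep(2:1, 20)), seed = 12)
  sim <- simulateRecording(cfg)
  ns <- fitSpace(computeCrossSpectra(sim$recording), 2, nInit = 5, seed = 3)
  m <- matchNetworks(truthAsNetworks(sim$truth), ns)
  for (f in 1:2) {
    net <- networks(ns)[[m$b[m$a == f]]]
    mem <- which(sim$truth@membership[, f] == 1)
    for (i in 1:2) {
      pair <- mem[c(i, i + 1)]
      cc <- crossCorrelogram(sim$recording, pair)
      peak <- cc$lag[which.max(cc$value)]
      dsig <- timeProfile(net)[pair[2]] - timeProfile(net)[pair[1]]
      expect_lt(abs(peak - dsig), 5e-5 + 1e-9)   # within one lag step
    }
  }
})
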