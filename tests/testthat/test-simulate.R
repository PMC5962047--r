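test_that("the default design encodes the stated networks and schedules", {
  nets <- defaultNetworks()
  expect_length(nets, 4)
  expect_equal(nets[[4]]$timeline, c(0, 2.5, 7.5) / 1e3)
  expect_equal(nets[[1]]$timeline, c(0, 0, 1, 1.5, 2.5, 3, 4.5, 6.5) / 1e3)
  expect_equal(nets[[3]]$timeline, rep(0, 4))
  # overlap topology: net2 subset of net1; single shared neurons 1&3, 3&4
  expect_true(all(nets[[2]]$members %in% nets[[1]]$members))
  expect_length(intersect(nets[[1]]$members, nets[[3]]$members), 1)
  expect_length(intersect(nets[[3]]$members, nets[[4]]$members), 1)
  expect_length(setdiff(1:15, unlist(lapply(nets, `[[`, "members"))), 2)

  sched <- defaultRepeatSchedule(100, 4)
  expect_true(all(sched %in% 0:3))
  expect_equal(colMeans(sched), rep(1.2, 4))
  # network 4: 0 repeats on trials 1-20, 1 on 21-60, 2 on 61-100
  expect_equal(unname(sched[, 4]),
               rep(c(0L, 1L, 2L), times = c(20, 40, 40)))
})

test_that("noiseless spike counts equal membership times repeats", {
  cfg <- simConfig(seed = 3)
  sim <- simulateRecording(cfg)
  for (l in c(1, 25, 50, 99)) {
    expected <- as.vector(cfg@repeats[l, ] %*% t(sim$truth@membership))
    got <- lengths(sim$recording@spikes[[l]])
    expect_equal(got, expected)
  }
})

test_that("sequence placement respects edge margins and minimum gaps", {
  for (s in 1:10) {
    cfg <- simConfig(seed = s)
    sim <- simulateRecording(cfg)
    for (l in seq_len(cfg@nTrials)) {
      on <- sim$truth@onsets[[l]]
      if (!nrow(on)) next
      spans <- vapply(on$network, function(f) max(cfg@networks[[f]]$timeline), 0)
      expect_true(all(on$onset_s >= cfg@edgeMargin - 1e-12))
      expect_true(all(on$onset_s + spans <= cfg@trialLen - cfg@edgeMargin + 1e-12))
      if (nrow(on) > 1) {
        o <- order(on$onset_s)
        gaps <- on$onset_s[o][-1] - (on$onset_s + spans)[o][-nrow(on)]
        expect_true(all(gaps >= cfg@minGap - 1e-12))
      }
    }
  }
  # infeasible packing errors out
  tight <- simConfig(nNeurons = 3, nTrials = 1, trialLen = 0.3,
                     networks = list(list(members = 1:3,
                                          timeline = c(0, 1, 2) / 1e3)),
                     repeats = matrix(3L, 1, 1), minGap = 0.2, seed = 1)
  expect_error(simulateRecording(tight), "place|fit")
})

test_that("noise, jitter and deletion follow their stated distributions", {
  # Poisson noise volume: 15 neurons x 100 s at 20 Hz
  cfg <- simConfig(noiseRate = 20, seed = 4,
                   networks = list(), repeats = matrix(0L, 100, 0))
  sim <- simulateRecording(cfg)
  tot <- sum(vapply(sim$recording@spikes, function(tr) sum(lengths(tr)), 0))
  lam <- 15 * 100 * 20
  expect_lt(abs(tot - lam), 3 * sqrt(lam))

  # jitter bound: realized sequence spikes within jitterMax of nominal
  cfgJ <- simConfig(jitterMax = 2e-3, seed = 5)
  simJ <- simulateRecording(cfgJ)
  for (l in c(2, 30, 77)) {
    sp <- simJ$truth@seqSpikes[[l]]
    on <- simJ$truth@onsets[[l]]
    if (!nrow(sp)) next
    for (i in seq_len(nrow(sp))) {
      f <- sp$network[i]
      tl <- cfgJ@networks[[f]]$timeline
      mem <- cfgJ@networks[[f]]$members
      nominal <- on$onset_s[on$network == f] # any repeat
      devs <- abs(outer(nominal, tl[mem == sp$neuron[i]], `+`) - sp$time_s[i])
      expect_lte(min(devs), 2e-3 + 1e-12)
    }
  }

  # deletion: realized / expected -> (1 - p) within a binomial interval
  p <- 0.4
  cfgD <- simConfig(deletionProb = p, seed = 6)
  simD <- simulateRecording(cfgD)
  nExp <- sum(cfgD@repeats %*% vapply(cfgD@networks,
                                      function(n) length(n$members), 0))
  nGot <- sum(vapply(simD$truth@seqSpikes, nrow, 0))
  se <- sqrt(nExp * p * (1 - p))
  expect_lt(abs(nGot - nExp * (1 - p)), 4 * se)
})

test_that("identical seeds reproduce identical recordings", {
  a <- simulateRecording(simConfig(noiseRate = 10, jitterMax = 1e-3,
                                   deletionProb = 0.2, seed = 42))
  b <- simulateRecording(simConfig(noiseRate = 10, jitterMax = 1e-3,
                                   deletionProb = 0.2, seed = 42))
  expect_identical(a$recording@spikes, b$recording@spikes)
  expect_identical(a$truth@onsets, b$truth@onsets)
  d <- simulateRecording(simConfig(noiseRate = 10, jitterMax = 1e-3,
                                   deletionProb = 0.2, seed = 43))
  expect_false(identical(a$recording@spikes, d$recording@spikes))
})

test_that("differential-rate helpers target the stated neurons and trials", {
  cfgN <- differentialNeuronNoiseConfig(seed = 1)
  expect_equal(unname(cfgN@noiseRate[5, 1]), 100)
  expect_equal(unname(cfgN@noiseRate[12, 50]), 100)
  expect_equal(unname(cfgN@noiseRate[1, 1]), 5)
  cfgT <- differentialTrialNoiseConfig(seed = 1)
  expect_true(all(cfgT@noiseRate[, 21:60] == 10))
  expect_true(all(cfgT@noiseRate[, c(1:20, 61:100)] == 5))
  expect_equal(cfgT@jitterMax, 0.25e-3)
  expect_equal(cfgT@deletionProb, 0.1)
})
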