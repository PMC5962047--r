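mkNet <- function(a, s = rep(0, length(a)), c2 = c(1, 1, 1), g = 50) {
  cc <- sqrt(c2 / sum(c2))
  new("SpikeNetwork", neuronProfile = a / sqrt(sum(a^2)),
      timeProfile = stnets:::wrapTime(s - s[which.max(abs(a))], g),
      freqProfile = rep(1 / sqrt(4), 4), trialProfile = cc, scale = 1,
      gcdFreq = g, neuronIds = character(0))
}

mkSet <- function(nets, g = 50) {
  new("NetworkSet", networks = nets, explainedVariance = 1,
      freqs = seq(g, by = g, length.out = 4), gcdFreq = g,
      neuronIds = character(0), trialIds = character(0), fitMeta = list())
}

test_that("similarity coefficients match closed forms and are symmetric", {
  expect_equal(neuronSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(neuronSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(neuronSimilarity(c(1, 0), c(1, 1) / sqrt(2)), 1 / sqrt(2))
  expect_error(neuronSimilarity(c(0, 0), c(1, 0)), "zero")

  expect_equal(trialSimilarity(c(1, 2, 0), c(0, 2, 1)), 4 / 5)
  expect_equal(trialSimilarity(c(1, 0), c(0, 2)), 0)

  g <- 50
  n1 <- mkNet(c(1, 1), c(0, 0.002))
  expect_equal(timeSimilarity(n1, n1), 1)
  # constant offset: phases cancel to a global rotation
  n2 <- mkNet(c(1, 1), c(0, 0.002) + 0.003)
  expect_equal(timeSimilarity(n1, n2), 1, tolerance = 1e-12)
  # half a cycle (10 ms at 50 Hz) on one neuron: |1 + exp(i pi)| / 2 = 0
  n3 <- mkNet(c(1, 1), c(0, 0.012))
  expect_equal(timeSimilarity(n1, n3), 0, tolerance = 1e-12)
  # circularity: shifting one sigma by 1/g changes nothing
  n4 <- mkNet(c(1, 1), c(0, 0.002 + 1 / g))
  expect_equal(timeSimilarity(n1, n4), 1, tolerance = 1e-12)
  # symmetry of all three
  a <- c(0.8, 0.6); b <- c(0.3, 0.95)
  expect_equal(neuronSimilarity(a, b), neuronSimilarity(b, a))
  expect_equal(trialSimilarity(a, b), trialSimilarity(b, a))
  n5 <- mkNet(c(1, 2), c(0, 0.004))
  expect_equal(timeSimilarity(n1, n5), timeSimilarity(n5, n1))
})

test_that("greedy matching recovers permutations and handles size mismatch", {
  setA <- mkSet(list(mkNet(c(1, 0, 0), c2 = c(3, 1, 1)),
                     mkNet(c(0, 1, 0), c2 = c(1, 3, 1)),
                     mkNet(c(0, 0, 1), c2 = c(1, 1, 3))))
  m <- matchNetworks(setA, setA)
  expect_equal(m$b, 1:3)
  expect_true(all(m$neuron == 1 & m$time == 1 & abs(m$trial - 1) < 1e-12))

  setB <- mkSet(setA@networks[c(3, 1, 2)])
  m <- matchNetworks(setA, setB)
  expect_equal(m$b, c(2, 3, 1))

  # 3 vs 2: two pairs, one unmatched
  setC <- mkSet(setA@networks[1:2])
  m <- matchNetworks(setA, setC)
  expect_equal(sum(is.na(m$b)), 1)
  expect_true(is.na(m$b[3]))
})

test_that("greedy matching agrees with an independent step-by-step oracle", {
  greedyOracle <- function(S) {
    out <- NULL
    repeat {
      if (!any(is.finite(S))) break
      ij <- which(S == max(S[is.finite(S)]), arr.ind = TRUE)
      ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
      out <- rbind(out, ij)
      S[ij[1], ] <- -Inf; S[, ij[2]] <- -Inf
    }
    out
  }
  for (s in 1:10) {
    withr::with_seed(s, {
      nA <- sample(2:4, 1); nB <- sample(2:4, 1)
      J <- 6
      mk <- function() mkNet(abs(rnorm(J)) + 0.05,
                             runif(J, -0.01, 0.01),
                             c2 = runif(3) + 0.1)
      A <- mkSet(lapply(seq_len(nA), function(i) mk()))
      B <- mkSet(lapply(seq_len(nB), function(i) mk()))
      S <- matrix(NA_real_, nA, nB)
      for (i in seq_len(nA)) for (j in seq_len(nB))
        S[i, j] <- mean(stnets:::similarityTriplet(A@networks[[i]],
                                                   B@networks[[j]]))
      ref <- greedyOracle(S)
      m <- matchNetworks(A, B)
      m <- m[!is.na(m$b), ]
      expect_equal(unname(cbind(m$a, m$b)),
                   unname(ref[order(ref[, 1]), , drop = FALSE]))
    })
  }
})

test_that("the artefact ratio flags power-driven single-neuron profiles", {
  r <- artefactRatio(c(0.99, 0.099, 0.02))
  expect_equal(r$ratio, 10)
  expect_true(r$flag)
  r <- artefactRatio(c(0.7, 0.7, 0.14))
  expect_equal(r$ratio, 1)
  expect_false(r$flag)
  r <- artefactRatio(c(1, 0, 0))
  expect_true(is.infinite(r$ratio) && r$flag)
  expect_error(artefactRatio(0.5), "two neurons")
})

test_that("an unsatisfiable cutoff selects zero networks", {
  sim <- simulateRecording(twoNetworkConfig(2, nTrials = 16))
  rel <- splitReliability(sim$recording, cutoff = 1.01, nInit = 3, maxF = 2,
                          neuronRoot = 32, tol = 1e-6, maxIter = 100)
  expect_equal(chosenF(rel), 0)
  expect_length(networks(rel), 0)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeReliabilityReport(rel, p)
  expect_true(file.exists(p) && nrow(read.delim(p)) >= 2)
})
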