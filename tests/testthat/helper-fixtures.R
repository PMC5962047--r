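# Shared fixtures: small recordings and simulation configurations built in
# code at test time.

# a random small recording for property tests
randomRecording <- function(seed, J = 3, L = 2, dur = 0.3, nSpk = 8,
                            fs = 2000) {
  withr::with_seed(seed, SpikeRecording(
    lapply(seq_len(L), function(l)
      lapply(seq_len(J), function(j) sort(runif(nSpk, 0, dur)))),
    durations = rep(dur, L), samplingRate = fs))
}

# matching low-rate spectral config for the random recordings
smallConfig <- function(fs = 2000, K = 10) {
  SpectralConfig(windowLen = 0.020, freqs = seq(50, by = 50, length.out = K),
                 samplingRate = fs)
}

# two clearly embedded networks (5 + 3 neurons, disjoint members, repeats
# interleaved over trial blocks) for model-selection tests
twoNetworkConfig <- function(seed, noiseRate = 10, nTrials = 40) {
  simConfig(nNeurons = 8, nTrials = nTrials,
            networks = list(
              list(members = 1:5, timeline = c(0, 1, 2, 3, 4) / 1e3),
              list(members = 6:8, timeline = c(0, 2.5, 5) / 1e3)),
            repeats = cbind(rep(c(1L, 2L, 0L, 0L), length.out = nTrials),
                            rep(c(0L, 0L, 1L, 2L), length.out = nTrials)),
            noiseRate = noiseRate, jitterMax = 0.25e-3, seed = seed)
}

# a valid random network set for model-identity tests
randomNetworkSet <- function(seed, J = 6, F = 2, K = 8, L = 10, g = 50) {
  withr::with_seed(seed, {
    nets <- lapply(seq_len(F), function(f) {
      a <- abs(rnorm(J)); a <- a / sqrt(sum(a^2))
      b <- runif(K); b <- b / sqrt(sum(b^2))
      cc <- runif(L); cc <- cc / sqrt(sum(cc^2))
      s <- runif(J, -1 / (2 * g), 1 / (2 * g))
      s <- s - s[which.max(a)]
      new("SpikeNetwork", neuronProfile = a,
          timeProfile = stnets:::wrapTime(s, g),
          freqProfile = b, trialProfile = cc, scale = runif(1, 0.5, 2),
          gcdFreq = g, neuronIds = paste0("n", seq_len(J)))
    })
    new("NetworkSet", networks = nets, explainedVariance = 1,
        freqs = seq(g, by = g, length.out = K), gcdFreq = g,
        neuronIds = paste0("n", seq_len(J)),
        trialIds = paste0("t", seq_len(L)), fitMeta = list())
  })
}

# random Hermitian PSD cross-spectra tensor (from random complex factors)
randomCrossSpectra <- function(seed, J = 4, K = 3, L = 5) {
  withr::with_seed(seed, {
    v <- array(0 + 0i, c(J, J, K, L))
    for (k in seq_len(K)) for (l in seq_len(L)) {
      Z <- matrix(complex(real = rnorm(J * 3), imaginary = rnorm(J * 3)), J, 3)
      v[, , k, l] <- Z %*% Conj(t(Z))
    }
    new("CrossSpectra", values = v, freqs = seq(50, by = 50, length.out = K),
        neuronIds = paste0("n", seq_len(J)), trialIds = paste0("t", seq_len(L)),
        config = SpectralConfig(freqs = seq(50, by = 50, length.out = K)),
        provenance = list())
  })
}
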