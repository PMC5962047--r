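test_that("kernels are untapered complex exponentials on the symmetric grid", {
  cfg <- SpectralConfig()
  k <- makeKernel(50, cfg)
  expect_length(k, 401)                         # round(t*fs) + 1
  expect_equal(k[201], 1 + 0i)                  # T = 0
  expect_true(all(abs(Mod(k) - 1) < 1e-12))     # constant magnitude
  expect_equal(k[301], complex(argument = -pi / 2), tolerance = 1e-12) # +5 ms
})

test_that("cross spectra match closed forms for isolated spikes and pairs", {
  cfg <- SpectralConfig()
  # spikes pairwise > 20 ms apart: diagonal power = n * M
  rec <- SpikeRecording(list(list(c(0.1, 0.2, 0.3))), 1)
  x <- computeCrossSpectra(rec, cfg)
  expect_equal(csValues(x)[1, 1, , 1], rep(3 * 401 + 0i, 20))
  # two neurons, spikes 1 ms apart: (M - 20) * exp(-i 2 pi f 0.001)
  rec2 <- SpikeRecording(list(list(0.500, 0.501)), 1)
  x2 <- computeCrossSpectra(rec2, cfg)
  f <- x2@freqs
  expect_equal(csValues(x2)[1, 2, , 1],
               381 * exp(-1i * 2 * pi * f * 0.001), tolerance = 1e-12)
  expect_equal(Arg(csValues(x2)[1, 2, 5, 1]), -pi / 2, tolerance = 1e-12)
  # no spikes at all -> all-zero tensor
  rec3 <- SpikeRecording(list(list(numeric(0), numeric(0))), 1)
  expect_true(all(csValues(computeCrossSpectra(rec3, cfg)) == 0))
  expect_error(computeCrossSpectra(SpikeRecording(list(), numeric(0)), cfg),
               "empty")
})

test_that("overlap weighting is linear: 2:1 for zero versus half-window delay", {
  cfg <- SpectralConfig()
  same <- SpikeRecording(list(list(0.5, 0.5)), 1)
  half <- SpikeRecording(list(list(0.5, 0.51)), 1)
  m0 <- Mod(csValues(computeCrossSpectra(same, cfg))[1, 2, 1, 1])
  m1 <- Mod(csValues(computeCrossSpectra(half, cfg))[1, 2, 1, 1])
  expect_equal(m0 / m1, 401 / 201)
  # the inclusive +-t/2 grid leaves a single overlapping sample at
  # exactly the window length, and none one sample beyond
  apart <- SpikeRecording(list(list(0.5, 0.52)), 1)
  expect_equal(Mod(csValues(computeCrossSpectra(apart, cfg))[1, 2, 1, 1]), 1)
  gone <- SpikeRecording(list(list(0.5, 0.52005)), 1)
  expect_equal(Mod(csValues(computeCrossSpectra(gone, cfg))[1, 2, 1, 1]), 0)
})

test_that("cross spectra equal the dense-convolution oracle", {
  for (s in 1:4) {
    rec <- randomRecording(s)
    cfg <- smallConfig()
    a <- csValues(computeCrossSpectra(rec, cfg))
    b <- csValues(oracleCrossSpectra(rec, cfg))
    expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-9)
  }
  # duration scaling agrees too
  rec <- randomRecording(9, L = 2)
  a <- csValues(computeCrossSpectra(rec, smallConfig(), scaleByDuration = TRUE))
  b <- csValues(oracleCrossSpectra(rec, smallConfig(), scaleByDuration = TRUE))
  expect_lt(max(Mod(a - b)) / max(Mod(b)), 1e-9)
  expect_error(oracleCrossSpectra(rec, smallConfig(), maxSpikes = 3), "refuses")
})

test_that("cross spectra are Hermitian with nonnegative real diagonal", {
  for (s in 5:7) {
    x <- csValues(computeCrossSpectra(randomRecording(s, J = 4), smallConfig()))
    for (k in seq_len(dim(x)[3])) for (l in seq_len(dim(x)[4])) {
      expect_equal(x[, , k, l], Conj(t(x[, , k, l])))
      expect_true(all(Im(diag(x[, , k, l])) == 0))
      expect_true(all(Re(diag(x[, , k, l])) >= 0))
    }
  }
})

test_that("frequencies at multiples of the gcd null uniform delay noise", {
  # expected phasor over pair delays uniform on (-t, t), weighted by overlap,
  # vanishes at any multiple of 1/t = 50 Hz
  withr::with_seed(11, {
    fs <- 20000; M <- 401
    d <- round(runif(40000, -(M - 1), M - 1))
    w <- M - abs(d)
    for (f in c(50, 100, 250)) {
      ph <- sum(w * exp(-1i * 2 * pi * f * d / fs)) / sum(w)
      expect_lt(Mod(ph), 0.02)
    }
    # an off-grid frequency leaves the closed-form triangular-window
    # leakage (Fejer kernel), well away from zero
    ph <- sum(w * exp(-1i * 2 * pi * 37 * d / fs)) / sum(w)
    fejer <- (sin(pi * 37 * 0.02) / (pi * 37 * 0.02))^2
    expect_equal(Mod(ph), fejer, tolerance = 0.2)
    expect_gt(Mod(ph), 0.05)
  })
})

test_that("cross spectra persist through the container round-trip", {
  x <- computeCrossSpectra(randomRecording(3), smallConfig(),
                           scaleByDuration = TRUE)
  p <- withr::local_tempfile(fileext = ".rds")
  saveCrossSpectra(x, p)
  y <- loadCrossSpectra(p)
  expect_equal(csValues(y), csValues(x))
  expect_equal(y@freqs, x@freqs)
  expect_equal(y@provenance$scale_by_duration, TRUE)
})
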