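# Complex-exponential kernels and trial-/frequency-resolved cross spectra.

#' Construct a SpectralConfig
#'
#' Defaults follow the short-delay regime for spike sequences: a 20 ms
#' untapered kernel and 20 frequencies from 50 to 1000 Hz in steps of 50 Hz.
#' The window length trades sensitivity (long windows sum more spike pairs)
#' against bias toward short delays (the pair weighting is linear in overlap,
#' giving a 2:1 weighting of 0 ms versus half-window delays); frequencies at
#' integer multiples of 1/window cancel the expected contribution of
#' nonconsistent delays.
#'
#' @param windowLen kernel time-domain length in seconds (default 0.020).
#' @param freqs analysis frequencies in Hz (default `seq(50, 1000, by = 50)`).
#' @param samplingRate sampling rate in Hz (default 20000).
#' @return a [SpectralConfig-class]
#' @export
SpectralConfig <- function(windowLen = 0.020, freqs = seq(50, 1000, by = 50),
                           samplingRate = 20000) {
  new("SpectralConfig", windowLen = windowLen, freqs = as.numeric(freqs),
      samplingRate = samplingRate)
}

#' Complex-exponential kernel at one frequency
#'
#' Untapered (constant magnitude 1) complex exponential on the symmetric
#' sample grid from -t/2 to +t/2, with `round(t * fs) + 1` samples. The sign
#' convention `exp(-i 2 pi f T)` makes later-spiking neurons receive larger
#' fitted time coefficients.
#'
#' @param freq frequency in Hz (one of `cfg@freqs`).
#' @param cfg a [SpectralConfig-class]
#' @return complex vector of kernel samples
#' @export
makeKernel <- function(freq, cfg) {
  T <- kernelTime(cfg)
  exp(-1i * 2 * pi * freq * T)
}

# spike times -> integer sample indices (0-based), duplicates in one sample
# bin merged with a warning
binarizeSamples <- function(rec) {
  fs <- rec@samplingRate
  collided <- FALSE
  out <- lapply(rec@spikes, function(tr) lapply(tr, function(s) {
    n <- as.integer(round(s * fs))
    u <- unique(n)
    if (length(u) < length(n)) collided <<- TRUE
    u
  }))
  if (collided)
    warning("spikes falling in the same sample bin were merged")
  out
}

#' Cross spectra of a spike recording
#'
#' Binarizes each neuron's spike train at the recording's sampling rate,
#' convolves it with the untapered complex-exponential kernel at every
#' analysis frequency (full zero-padded convolution: every spike contributes
#' its whole kernel, also near trial boundaries), and forms the cross
#' products over time, yielding a Hermitian neuron-by-neuron matrix per
#' frequency and trial. Computation uses the equivalent closed form over
#' spike pairs: a pair at sample offset d (|d| < M) contributes
#' `(M - |d|) * exp(-i 2 pi f d / fs)`.
#'
#' @param rec a [SpikeRecording-class]
#' @param cfg a [SpectralConfig-class]; its sampling rate is taken from `rec`.
#' @param scaleByDuration if `TRUE`, each trial's cross spectra are divided
#'   by that trial's duration in seconds (for recordings with unequal trials).
#' @return a [CrossSpectra-class]
#' @export
computeCrossSpectra <- function(rec, cfg = SpectralConfig(),
                                scaleByDuration = FALSE) {
  if (nNeurons(rec) == 0 || nTrials(rec) == 0)
    stop("empty recording: no neurons or no trials")
  cfg@samplingRate <- rec@samplingRate
  validObject(cfg)
  M <- as.integer(round(cfg@windowLen * cfg@samplingRate) + 1)
  samp <- binarizeSamples(rec)
  v <- cross_spectra_cpp(samp, nNeurons(rec), M, cfg@freqs, cfg@samplingRate,
                         rec@durations, scaleByDuration)
  dim(v) <- c(nNeurons(rec), nNeurons(rec), length(cfg@freqs), nTrials(rec))
  new("CrossSpectra", values = v, freqs = cfg@freqs,
      neuronIds = rec@neuronIds, trialIds = rec@trialIds, config = cfg,
      provenance = if (scaleByDuration) list(scale_by_duration = TRUE) else list())
}

#' Cross spectra by the literal definition (verification oracle)
#'
#' Independently recomputes cross spectra exactly as defined: builds the
#' dense binary spike train per trial, performs the full zero-padded
#' convolution with the complex-exponential kernel in the time domain, and
#' sums the cross products over time samples. Intended for small inputs;
#' equals [computeCrossSpectra()] to numerical tolerance.
#'
#' @inheritParams computeCrossSpectra
#' @param maxSpikes refuse recordings with more spikes than this.
#' @return a [CrossSpectra-class]
#' @export
oracleCrossSpectra <- function(rec, cfg = SpectralConfig(),
                               scaleByDuration = FALSE, maxSpikes = 1000) {
  if (nNeurons(rec) == 0 || nTrials(rec) == 0)
    stop("empty recording: no neurons or no trials")
  total <- sum(vapply(rec@spikes, function(tr) sum(lengths(tr)), 0))
  if (total > maxSpikes)
    stop("oracle refuses recordings with more than ", maxSpikes, " spikes")
  cfg@samplingRate <- rec@samplingRate
  fs <- cfg@samplingRate
  M <- as.integer(round(cfg@windowLen * fs) + 1)
  J <- nNeurons(rec); K <- length(cfg@freqs); L <- nTrials(rec)
  samp <- binarizeSamples(rec)
  X <- array(0 + 0i, c(J, J, K, L))
  for (l in seq_len(L)) {
    N <- as.integer(round(rec@durations[l] * fs) + 1)
    Tlen <- N + M - 1L
    sc <- if (scaleByDuration) 1 / rec@durations[l] else 1
    for (k in seq_len(K)) {
      ker <- makeKernel(cfg@freqs[k], cfg)
      Z <- matrix(0 + 0i, J, Tlen)
      for (j in seq_len(J))
        for (n in samp[[l]][[j]])            # 0-based sample index
          Z[j, (n + 1L):(n + M)] <- Z[j, (n + 1L):(n + M)] + ker
      X[, , k, l] <- sc * (Z %*% Conj(t(Z)))
    }
  }
  new("CrossSpectra", values = X, freqs = cfg@freqs,
      neuronIds = rec@neuronIds, trialIds = rec@trialIds, config = cfg,
      provenance = list(oracle = TRUE,
                        scale_by_duration = scaleByDuration))
}

#' Save / load cross spectra
#'
#' Persists the complex array together with its dimension identifiers,
#' spectral configuration and provenance as a named-list container in R
#' native serialization.
#'
#' @param x a [CrossSpectra-class]
#' @param path file path
#' @return `path` invisibly; `loadCrossSpectra` returns the
#'   [CrossSpectra-class]
#' @export
saveCrossSpectra <- function(x, path) {
  saveRDS(list(values = x@values, freqs = x@freqs, neuron_ids = x@neuronIds,
               trial_ids = x@trialIds,
               config = list(window_len_s = x@config@windowLen,
                             freqs_hz = x@config@freqs,
                             sampling_rate_hz = x@config@samplingRate),
               provenance = x@provenance,
               version = as.character(utils::packageVersion("stnets"))),
          path)
  invisible(path)
}

#' @rdname saveCrossSpectra
#' @export
loadCrossSpectra <- function(path) {
  obj <- readRDS(path)
  cfg <- SpectralConfig(obj$config$window_len_s, obj$config$freqs_hz,
                        obj$config$sampling_rate_hz)
  new("CrossSpectra", values = obj$values, freqs = obj$freqs,
      neuronIds = obj$neuron_ids, trialIds = obj$trial_ids, config = cfg,
      provenance = obj$provenance)
}
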