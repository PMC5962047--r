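#' @useDynLib stnets, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor rpois runif sd setNames
#' @importFrom utils read.delim write.table modifyList
NULL

#' Multi-trial spike recording
#'
#' Per-neuron spike times in seconds, relative to trial start, for a set of
#' trials of possibly unequal duration. The neuron set is identical across
#' trials (empty spike lists are allowed). Spike times are sorted ascending
#' within each neuron and trial.
#'
#' @slot neuronIds character vector of neuron identifiers.
#' @slot trialIds character vector of trial identifiers.
#' @slot durations numeric vector of trial durations in seconds.
#' @slot spikes list over trials; each element a list over neurons of sorted
#'   numeric spike-time vectors (seconds, relative to trial start).
#' @slot samplingRate sampling rate in Hz used when spike trains are
#'   binarized for spectral analysis.
#' @export
setClass("SpikeRecording",
  slots = c(neuronIds = "character", trialIds = "character",
            durations = "numeric", spikes = "list", samplingRate = "numeric"))

setValidity("SpikeRecording", function(object) {
  J <- length(object@neuronIds)
  L <- length(object@trialIds)
  if (length(object@durations) != L) return("durations must match trialIds")
  if (length(object@spikes) != L) return("spikes must have one element per trial")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  if (anyDuplicated(object@neuronIds)) return("duplicated neuron ids")
  if (anyDuplicated(object@trialIds)) return("duplicated trial ids")
  for (l in seq_len(L)) {
    tr <- object@spikes[[l]]
    if (length(tr) != J)
      return(sprintf("trial %s: spike list must have one entry per neuron",
                     object@trialIds[l]))
    for (j in seq_len(J)) {
      s <- tr[[j]]
      if (length(s) == 0) next
      if (anyNA(s)) return(sprintf("trial %s, neuron %s: NA spike time",
                                   object@trialIds[l], object@neuronIds[j]))
      if (is.unsorted(s)) return(sprintf("trial %s, neuron %s: unsorted spikes",
                                         object@trialIds[l], object@neuronIds[j]))
      if (s[1] < 0 || s[length(s)] > object@durations[l])
        return(sprintf("trial %s, neuron %s: spike outside [0, %g]",
                       object@trialIds[l], object@neuronIds[j],
                       object@durations[l]))
    }
  }
  TRUE
})

#' Spectral-transform configuration
#'
#' Parameters of the complex-exponential (untapered wavelet) transform used
#' to build cross spectra: kernel time-domain length, analysis frequencies,
#' and sampling rate. The kernel time grid runs symmetrically from -t/2 to
#' +t/2 inclusive; the greatest common divisor of the frequencies sets the
#' cycle length (period) of the circular time profiles.
#'
#' @slot windowLen kernel time-domain length t in seconds.
#' @slot freqs analysis frequencies in Hz (positive, strictly increasing,
#'   all integer multiples of their greatest common divisor).
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("SpectralConfig",
  slots = c(windowLen = "numeric", freqs = "numeric", samplingRate = "numeric"))

setValidity("SpectralConfig", function(object) {
  f <- object@freqs
  if (length(f) < 1 || any(f <= 0)) return("freqs must be positive")
  if (is.unsorted(f, strictly = TRUE)) return("freqs must be strictly increasing")
  g <- Reduce(gcd2, f)
  if (any(abs(f / g - round(f / g)) > 1e-9))
    return("every frequency must be an integer multiple of the gcd")
  if (object@windowLen * object@samplingRate < 2)
    return("windowLen * samplingRate must be at least 2")
  TRUE
})

#' Trial- and frequency-resolved cross spectra
#'
#' Complex 4-way array over (neuron, neuron, frequency, trial). Each
#' (frequency, trial) slice is Hermitian with real nonnegative diagonal
#' (power); off-diagonal phases encode between-neuron spike time delays as
#' frequency-proportional phase differences.
#'
#' @slot values complex array of dimension J x J x K x L.
#' @slot freqs analysis frequencies in Hz.
#' @slot neuronIds,trialIds dimension identifiers.
#' @slot config the [SpectralConfig-class] used to compute the values.
#' @slot provenance list recording scaling/normalization steps applied.
#' @export
setClass("CrossSpectra",
  slots = c(values = "array", freqs = "numeric", neuronIds = "character",
            trialIds = "character", config = "SpectralConfig",
            provenance = "list"))

setValidity("CrossSpectra", function(object) {
  d <- dim(object@values)
  if (length(d) != 4) return("values must be a 4-way array")
  if (d[1] != d[2]) return("values must be square in the neuron dimensions")
  if (d[1] != length(object@neuronIds)) return("neuronIds length mismatch")
  if (d[3] != length(object@freqs)) return("freqs length mismatch")
  if (d[4] != length(object@trialIds)) return("trialIds length mismatch")
  if (!is.complex(object@values)) return("values must be complex")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' A single spike timing network
#'
#' One rank-one Hermitian component of the cross-spectra decomposition. The
#' neuron profile weights network membership, the circular time profile gives
#' one time coefficient per neuron in seconds (period 1 / gcd(freqs), anchored
#' so the strongest neuron is at 0 s), and the frequency and trial profiles
#' are stored unsquared (nonnegative, unit L2 norm); the model and all
#' reported quantities use their squares.
#'
#' @slot neuronProfile numeric length J, unit L2 norm, nonnegative mean.
#' @slot timeProfile numeric length J, seconds, in (-1/(2 gamma), +1/(2 gamma)].
#' @slot freqProfile numeric length K, nonnegative, unit L2 norm (unsquared).
#' @slot trialProfile numeric length L, nonnegative, unit L2 norm (unsquared).
#' @slot scale positive scalar multiplicative network strength.
#' @slot gcdFreq greatest common divisor of the analysis frequencies (Hz).
#' @slot neuronIds neuron identifiers.
#' @export
setClass("SpikeNetwork",
  slots = c(neuronProfile = "numeric", timeProfile = "numeric",
            freqProfile = "numeric", trialProfile = "numeric",
            scale = "numeric", gcdFreq = "numeric", neuronIds = "character"))

setValidity("SpikeNetwork", function(object) {
  J <- length(object@neuronProfile)
  if (length(object@timeProfile) != J) return("timeProfile length mismatch")
  if (length(object@neuronIds) > 0 && length(object@neuronIds) != J)
    return("neuronIds length mismatch")
  if (length(object@scale) != 1L || object@scale < 0)
    return("scale must be a nonnegative scalar")
  if (length(object@gcdFreq) != 1L || object@gcdFreq <= 0)
    return("gcdFreq must be positive")
  half <- 1 / (2 * object@gcdFreq)
  if (any(object@timeProfile <= -half - 1e-12 | object@timeProfile > half + 1e-12))
    return("timeProfile outside (-1/(2 gamma), +1/(2 gamma)]")
  TRUE
})

#' A fitted set of spike timing networks
#'
#' @slot networks list of [SpikeNetwork-class] objects.
#' @slot explainedVariance 1 - ||X - Xhat||^2 / ||X||^2 for the reported fit.
#' @slot freqs analysis frequencies (Hz).
#' @slot gcdFreq gcd of the frequencies (Hz).
#' @slot neuronIds,trialIds dimension identifiers.
#' @slot fitMeta list of fit metadata (per-init losses, iterations, seed, ...).
#' @export
setClass("NetworkSet",
  slots = c(networks = "list", explainedVariance = "numeric",
            freqs = "numeric", gcdFreq = "numeric",
            neuronIds = "character", trialIds = "character",
            fitMeta = "list"))

#' Simulation configuration for spike timing networks
#'
#' Defines a multi-trial recording with embedded spike-sequence networks,
#' Poisson spiking noise, per-spike timing jitter, and per-spike deletion.
#'
#' @slot nNeurons,nTrials,trialLen recording geometry (trials in seconds).
#' @slot networks list of `list(members = <neuron indices>,
#'   timeline = <seconds, starting at 0>)`.
#' @slot repeats integer matrix (nTrials x nNetworks) of sequence repeats per
#'   trial, values 0-3.
#' @slot noiseRate matrix (nNeurons x nTrials) of Poisson noise rates in Hz.
#' @slot jitterMax per-spike uniform jitter bound in seconds.
#' @slot deletionProb per-spike deletion probability.
#' @slot edgeMargin minimum offset of sequence onsets from trial boundaries (s).
#' @slot minGap minimum gap between sequence spans within a trial (s).
#' @slot samplingRate sampling rate in Hz carried to the recording.
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig",
  slots = c(nNeurons = "numeric", nTrials = "numeric", trialLen = "numeric",
            networks = "list", repeats = "matrix", noiseRate = "matrix",
            jitterMax = "numeric", deletionProb = "numeric",
            edgeMargin = "numeric", minGap = "numeric",
            samplingRate = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  Fn <- length(object@networks)
  if (nrow(object@repeats) != object@nTrials || ncol(object@repeats) != Fn)
    return("repeats must be nTrials x nNetworks")
  if (any(object@repeats < 0 | object@repeats > 3))
    return("repeats must lie in 0..3")
  for (net in object@networks) {
    if (length(net$members) != length(net$timeline))
      return("members and timeline must have equal length")
    if (abs(min(net$timeline)) > 1e-12) return("timelines must start at 0")
    if (any(net$members < 1 | net$members > object@nNeurons))
      return("network members out of range")
  }
  if (any(dim(object@noiseRate) != c(object@nNeurons, object@nTrials)))
    return("noiseRate must be nNeurons x nTrials")
  if (object@jitterMax < 0 || object@deletionProb < 0 || object@deletionProb > 1)
    return("invalid jitter or deletion parameter")
  TRUE
})

#' Ground truth of a simulated recording
#'
#' @slot membership binary matrix J x F of network membership.
#' @slot timelines matrix J x F of sequence time coefficients in seconds
#'   (nonmembers 0).
#' @slot repeats integer matrix L x F of per-trial sequence repeats.
#' @slot onsets list per trial of data.frames (network, rep, onset_s).
#' @slot seqSpikes list per trial of data.frames (network, neuron, time_s)
#'   of realized (post-jitter, post-deletion) sequence spikes.
#' @export
setClass("GroundTruth",
  slots = c(membership = "matrix", timelines = "matrix", repeats = "matrix",
            onsets = "list", seqSpikes = "list"))

#' Result of the split-half reliability procedure
#'
#' @slot chosenF number of reliable networks.
#' @slot networks [NetworkSet-class] fitted on the full data at `chosenF`
#'   (empty set when `chosenF` is 0).
#' @slot table data.frame with one row per (F tried, full-data network,
#'   split): the three similarity coefficients and pass/fail.
#' @slot cutoff similarity cutoff used.
#' @export
setClass("ReliabilityResult",
  slots = c(chosenF = "numeric", networks = "NetworkSet",
            table = "data.frame", cutoff = "numeric"))

# ---- show methods ----------------------------------------------------------

setMethod("show", "SpikeRecording", function(object) {
  n <- sum(vapply(object@spikes, function(tr) sum(lengths(tr)), 0))
  cat(sprintf("SpikeRecording: %d neurons, %d trials (total %.3g s), %d spikes\n",
              length(object@neuronIds), length(object@trialIds),
              sum(object@durations), n))
  cat(sprintf("  sampling rate: %g Hz\n", object@samplingRate))
})

setMethod("show", "SpectralConfig", function(object) {
  cat(sprintf("SpectralConfig: window %g ms, %d freqs (%g-%g Hz, gcd %g Hz), fs %g Hz\n",
              1e3 * object@windowLen, length(object@freqs), min(object@freqs),
              max(object@freqs), gcdFreq(object), object@samplingRate))
})

setMethod("show", "CrossSpectra", function(object) {
  d <- dim(object@values)
  cat(sprintf("CrossSpectra: %d x %d neurons, %d freqs, %d trials\n",
              d[1], d[2], d[3], d[4]))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

setMethod("show", "SpikeNetwork", function(object) {
  ord <- order(abs(object@neuronProfile), decreasing = TRUE)
  top <- ord[seq_len(min(5, length(ord)))]
  ids <- if (length(object@neuronIds)) object@neuronIds else as.character(seq_along(object@neuronProfile))
  cat(sprintf("SpikeNetwork (scale %.3g):\n", object@scale))
  cat("  strongest neurons:",
      paste(sprintf("%s (a=%.2f, sigma=%.2f ms)", ids[top],
                    object@neuronProfile[top], 1e3 * object@timeProfile[top]),
            collapse = ", "), "\n")
})

setMethod("show", "NetworkSet", function(object) {
  cat(sprintf("NetworkSet: %d networks, explained variance %.3f\n",
              length(object@networks), object@explainedVariance))
  for (i in seq_along(object@networks)) {
    cat(sprintf(" [%d] ", i)); show(object@networks[[i]])
  }
})

setMethod("show", "ReliabilityResult", function(object) {
  cat(sprintf("ReliabilityResult: chosen F = %d (cutoff %.2f)\n",
              object@chosenF, object@cutoff))
})
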