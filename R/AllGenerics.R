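# Accessor generics and small shared utilities.

#' @describeIn SpikeRecording-class number of neurons
#' @param x,object an object of the documented class
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
#' @describeIn SpikeRecording-class number of trials
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @describeIn SpikeRecording-class neuron identifiers
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))
#' @describeIn SpikeRecording-class trial identifiers
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @describeIn SpikeRecording-class trial durations in seconds
#' @export
setGeneric("trialDurations", function(x) standardGeneric("trialDurations"))
#' @describeIn SpikeRecording-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @describeIn SpikeRecording-class spike times (s) of one neuron in one trial
#' @param trial,neuron trial / neuron identifier or index
#' @export
setGeneric("spikeTimes", function(x, trial, neuron) standardGeneric("spikeTimes"))
#' @describeIn SpikeRecording-class average firing rate per neuron (Hz) over
#'   the whole recording
#' @export
setGeneric("firingRates", function(x) standardGeneric("firingRates"))

#' @describeIn SpectralConfig-class greatest common divisor of the analysis
#'   frequencies in Hz; 1/gcdFreq is the period of the circular time profile
#' @param x a `SpectralConfig` (or object carrying frequencies)
#' @export
setGeneric("gcdFreq", function(x) standardGeneric("gcdFreq"))
#' @describeIn SpectralConfig-class symmetric kernel time grid from -t/2 to
#'   +t/2 (seconds)
#' @export
setGeneric("kernelTime", function(x) standardGeneric("kernelTime"))

#' @describeIn CrossSpectra-class the complex J x J x K x L array
#' @param x a `CrossSpectra`
#' @export
setGeneric("csValues", function(x) standardGeneric("csValues"))

#' @describeIn NetworkSet-class list of fitted networks
#' @param x a `NetworkSet`
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))
#' @describeIn NetworkSet-class fraction of tensor variance explained
#' @export
setGeneric("explainedVariance", function(x, ...) standardGeneric("explainedVariance"))

#' @describeIn SpikeNetwork-class membership weights (unit L2 norm)
#' @param x a `SpikeNetwork`
#' @export
setGeneric("neuronProfile", function(x) standardGeneric("neuronProfile"))
#' @describeIn SpikeNetwork-class per-neuron time coefficients in seconds
#' @export
setGeneric("timeProfile", function(x) standardGeneric("timeProfile"))
#' @describeIn SpikeNetwork-class squared frequency profile (sums to 1)
#' @export
setGeneric("freqProfile", function(x) standardGeneric("freqProfile"))
#' @describeIn SpikeNetwork-class squared trial profile (sums to 1); this is
#'   the reported parameterization, proportional to each trial's share of the
#'   network's cross-spectral energy
#' @export
setGeneric("trialProfile", function(x) standardGeneric("trialProfile"))
#' @describeIn SpikeNetwork-class multiplicative network strength
#' @export
setGeneric("networkScale", function(x) standardGeneric("networkScale"))

#' @describeIn ReliabilityResult-class chosen number of networks
#' @param x a `ReliabilityResult`
#' @export
setGeneric("chosenF", function(x) standardGeneric("chosenF"))

setMethod("nNeurons", "SpikeRecording", function(x) length(x@neuronIds))
setMethod("nTrials", "SpikeRecording", function(x) length(x@trialIds))
setMethod("neuronIds", "SpikeRecording", function(x) x@neuronIds)
setMethod("trialIds", "SpikeRecording", function(x) x@trialIds)
setMethod("trialDurations", "SpikeRecording",
          function(x) setNames(x@durations, x@trialIds))
setMethod("samplingRate", "SpikeRecording", function(x) x@samplingRate)
setMethod("spikeTimes", "SpikeRecording", function(x, trial, neuron) {
  l <- if (is.character(trial)) match(trial, x@trialIds) else as.integer(trial)
  j <- if (is.character(neuron)) match(neuron, x@neuronIds) else as.integer(neuron)
  if (is.na(l) || is.na(j)) stop("unknown trial or neuron")
  x@spikes[[l]][[j]]
})
setMethod("firingRates", "SpikeRecording", function(x) {
  counts <- Reduce(`+`, lapply(x@spikes, lengths))
  setNames(counts / sum(x@durations), x@neuronIds)
})

setMethod("gcdFreq", "SpectralConfig", function(x) Reduce(gcd2, x@freqs))
setMethod("gcdFreq", "numeric", function(x) Reduce(gcd2, x))
setMethod("kernelTime", "SpectralConfig", function(x) {
  M <- round(x@windowLen * x@samplingRate) + 1
  (seq_len(M) - (M + 1) / 2) / x@samplingRate
})

setMethod("nNeurons", "CrossSpectra", function(x) dim(x@values)[1])
setMethod("nTrials", "CrossSpectra", function(x) dim(x@values)[4])
setMethod("neuronIds", "CrossSpectra", function(x) x@neuronIds)
setMethod("trialIds", "CrossSpectra", function(x) x@trialIds)
setMethod("csValues", "CrossSpectra", function(x) x@values)
setMethod("gcdFreq", "CrossSpectra", function(x) Reduce(gcd2, x@freqs))

setMethod("networks", "NetworkSet", function(x) x@networks)
setMethod("explainedVariance", "NetworkSet", function(x, ...) x@explainedVariance)
setMethod("gcdFreq", "NetworkSet", function(x) x@gcdFreq)
setMethod("neuronIds", "NetworkSet", function(x) x@neuronIds)
setMethod("trialIds", "NetworkSet", function(x) x@trialIds)

setMethod("neuronProfile", "SpikeNetwork", function(x) {
  setNames(x@neuronProfile, if (length(x@neuronIds)) x@neuronIds else NULL)
})
setMethod("timeProfile", "SpikeNetwork", function(x) {
  setNames(x@timeProfile, if (length(x@neuronIds)) x@neuronIds else NULL)
})
setMethod("freqProfile", "SpikeNetwork", function(x) x@freqProfile^2)
setMethod("trialProfile", "SpikeNetwork", function(x) x@trialProfile^2)
setMethod("networkScale", "SpikeNetwork", function(x) x@scale)
setMethod("gcdFreq", "SpikeNetwork", function(x) x@gcdFreq)

setMethod("chosenF", "ReliabilityResult", function(x) x@chosenF)
setMethod("networks", "ReliabilityResult", function(x) x@networks@networks)

# ---- internal helpers ------------------------------------------------------

# gcd of two positive reals that are (near-)integer multiples of a common base
gcd2 <- function(a, b) {
  while (b > 1e-9) { t <- a %% b; a <- b; b <- t }
  a
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

l2norm <- function(x) sqrt(sum(x^2))
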