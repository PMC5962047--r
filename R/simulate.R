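# Simulation of spike recordings containing spike timing networks, with
# Poisson spiking noise, per-spike uniform jitter and per-spike deletion,
# plus the ground truth needed to score recovery.

#' Default embedded networks
#'
#' Four networks over 15 neurons with overlapping membership: network 2's
#' neurons are a subset of network 1's, network 3 shares one neuron with
#' network 1, network 4 shares one neuron with network 3, and two neurons
#' belong to no network. Timelines span 0 (synchronous) to 7.5 ms.
#'
#' @return list of `list(members, timeline)` (timeline in seconds)
#' @export
defaultNetworks <- function() {
  list(list(members = 1:8,  timeline = c(0, 0, 1, 1.5, 2.5, 3, 4.5, 6.5) / 1e3),
       list(members = 1:5,  timeline = c(0, 1, 2, 3, 4) / 1e3),
       list(members = 8:11, timeline = c(0, 0, 0, 0)),
       list(members = 11:13, timeline = c(0, 2.5, 7.5) / 1e3))
}

#' Default per-trial sequence-repeat schedule
#'
#' Block designs over trials with repeat counts in 0..3 and mean 1.2
#' repeats per trial for every network. The trials in the middle block
#' (fractions 0.2-0.6 of the recording) carry all of networks 1, 2 and 4's
#' single- and double-repeat trials and half of network 3's, which is what
#' the differential-trial-noise condition exploits. Network 4 runs
#' 0 repeats on the first fifth of trials, 1 on the next two fifths and 2
#' on the last two fifths.
#'
#' @param nTrials number of trials (the stated means are exact when
#'   divisible by 5).
#' @param nNetworks number of networks (at most 4 defaults are defined).
#' @return integer matrix `nTrials x nNetworks`
#' @export
defaultRepeatSchedule <- function(nTrials = 100, nNetworks = 4) {
  blocks <- list(c(0, 1, 2, 0, 3),
                 c(0, 0, 1, 2, 3),
                 c(1, 1, 2, 2, 0),
                 c(0, 1, 1, 2, 2))
  stopifnot(nNetworks <= length(blocks))
  breaks <- round(seq(0, nTrials, length.out = 6))
  out <- matrix(0L, nTrials, nNetworks)
  for (f in seq_len(nNetworks))
    for (b in 1:5)
      if (breaks[b + 1] > breaks[b])
        out[(breaks[b] + 1):breaks[b + 1], f] <- blocks[[f]][b]
  out
}

# scalar / J-vector / J x L matrix -> J x L matrix of noise rates
expandNoiseRate <- function(noiseRate, nNeurons, nTrials) {
  if (is.matrix(noiseRate)) {
    stopifnot(nrow(noiseRate) == nNeurons, ncol(noiseRate) == nTrials)
    return(noiseRate)
  }
  if (length(noiseRate) == 1) return(matrix(noiseRate, nNeurons, nTrials))
  if (length(noiseRate) == nNeurons)
    return(matrix(noiseRate, nNeurons, nTrials))
  stop("noiseRate must be a scalar, a per-neuron vector, or a J x L matrix")
}

#' Construct a simulation configuration
#'
#' Defaults reproduce the reference simulation design: 15 neurons, 100
#' trials of 1 s, four embedded networks with fixed spike-sequence
#' timelines repeated 0-3 times per trial (mean 1.2 per network), sequence
#' onsets uniform within trials with a 25 ms offset from trial boundaries
#' and a minimum of 25 ms between sequence spans.
#'
#' @param nNeurons,nTrials,trialLen recording geometry.
#' @param networks list of `list(members, timeline)`; timeline in seconds
#'   starting at 0.
#' @param repeats integer matrix `nTrials x length(networks)` of per-trial
#'   sequence repeats (0-3).
#' @param noiseRate Poisson spiking noise in Hz: scalar, per-neuron vector,
#'   or `nNeurons x nTrials` matrix.
#' @param jitterMax per-spike uniform jitter bound in seconds (spikes move
#'   by U(-jitterMax, +jitterMax)).
#' @param deletionProb independent per-spike deletion probability.
#' @param edgeMargin,minGap onset placement constraints in seconds.
#' @param samplingRate sampling rate carried to the recording (Hz).
#' @param seed RNG seed; identical seeds give identical recordings.
#' @return a [SimulationConfig-class]
#' @export
simConfig <- function(nNeurons = 15, nTrials = 100, trialLen = 1,
                      networks = defaultNetworks(),
                      repeats = defaultRepeatSchedule(nTrials, length(networks)),
                      noiseRate = 0, jitterMax = 0, deletionProb = 0,
                      edgeMargin = 0.025, minGap = 0.025,
                      samplingRate = 20000, seed = 1) {
  new("SimulationConfig", nNeurons = nNeurons, nTrials = nTrials,
      trialLen = trialLen, networks = networks,
      repeats = matrix(as.integer(repeats), nTrials, length(networks)),
      noiseRate = expandNoiseRate(noiseRate, nNeurons, nTrials),
      jitterMax = jitterMax, deletionProb = deletionProb,
      edgeMargin = edgeMargin, minGap = minGap,
      samplingRate = samplingRate, seed = seed)
}

#' Differential-rate condition helpers
#'
#' `differentialNeuronNoiseConfig` gives two neurons (one member of
#' networks 1-2, one of networks 3-4) a high noise rate against a low-rate
#' background, the regime where power differences between neurons distort
#' extraction unless neuron-wise normalization is applied.
#' `differentialTrialNoiseConfig` raises the noise rate on a middle block
#' of trials (fractions 0.2-0.6), the regime addressed by trial-wise
#' normalization.
#'
#' @param highRate,lowRate noise rates in Hz.
#' @param ... passed to [simConfig()].
#' @return a [SimulationConfig-class]
#' @export
differentialNeuronNoiseConfig <- function(highRate = 100, lowRate = 5, ...) {
  cfg <- simConfig(jitterMax = 0.25e-3, deletionProb = 0.1, ...)
  rates <- rep(lowRate, cfg@nNeurons)
  rates[c(5, 12)] <- highRate
  cfg@noiseRate <- expandNoiseRate(rates, cfg@nNeurons, cfg@nTrials)
  cfg
}

#' @rdname differentialNeuronNoiseConfig
#' @export
differentialTrialNoiseConfig <- function(highRate = 10, lowRate = 5, ...) {
  cfg <- simConfig(jitterMax = 0.25e-3, deletionProb = 0.1, ...)
  noisy <- (round(0.2 * cfg@nTrials) + 1):round(0.6 * cfg@nTrials)
  m <- matrix(lowRate, cfg@nNeurons, cfg@nTrials)
  m[, noisy] <- highRate
  cfg@noiseRate <- m
  cfg
}

# place n sequence spans in [margin, len - margin] by rejection sampling,
# keeping at least minGap between spans
placeOnsets <- function(spans, trialLen, margin, minGap, maxTries = 1000) {
  n <- length(spans)
  if (n == 0) return(numeric(0))
  hi <- trialLen - margin - spans
  if (any(hi < margin)) stop("sequence span does not fit in trial")
  for (try in seq_len(maxTries)) {
    on <- runif(n, margin, hi)
    o <- order(on)
    if (n == 1 || all(on[o][-1] - (on[o] + spans[o])[-n] >= minGap))
      return(on)
  }
  stop("could not place ", n, " sequences with the required gaps; ",
       "fewer repeats or a longer trial needed")
}

#' Simulate a spike recording with embedded spike timing networks
#'
#' Sequence onsets are placed uniformly at random within each trial
#' (respecting the edge margin and minimum gap; the order of sequences
#' from different networks is thereby random), each sequence spike gets
#' independent uniform jitter and an independent deletion draw, and
#' independent Poisson noise spikes are superimposed over the full trial
#' for every neuron. All randomness derives from `cfg@seed`.
#'
#' @param cfg a [SimulationConfig-class]
#' @return list with `recording` (a [SpikeRecording-class]) and `truth`
#'   (a [GroundTruth-class])
#' @export
simulateRecording <- function(cfg) {
  validObject(cfg)
  J <- cfg@nNeurons; L <- cfg@nTrials; Fn <- length(cfg@networks)
  with_seed(cfg@seed, {
    spikes <- vector("list", L)
    onsets <- vector("list", L)
    seqSpikes <- vector("list", L)
    for (l in seq_len(L)) {
      inst <- do.call(rbind, lapply(seq_len(Fn), function(f) {
        r <- cfg@repeats[l, f]
        if (r == 0) return(NULL)
        data.frame(network = f, rep = seq_len(r))
      }))
      trialSpikes <- lapply(seq_len(J), function(j) numeric(0))
      onRows <- NULL; spkRows <- NULL
      if (!is.null(inst)) {
        spans <- vapply(inst$network, function(f)
          max(cfg@networks[[f]]$timeline), 0)
        on <- placeOnsets(spans, cfg@trialLen, cfg@edgeMargin, cfg@minGap)
        onRows <- data.frame(network = inst$network, rep = inst$rep,
                             onset_s = on)
        for (i in seq_len(nrow(inst))) {
          f <- inst$network[i]
          mem <- cfg@networks[[f]]$members
          tl <- cfg@networks[[f]]$timeline
          tms <- on[i] + tl
          if (cfg@jitterMax > 0)
            tms <- tms + runif(length(tms), -cfg@jitterMax, cfg@jitterMax)
          keep <- if (cfg@deletionProb > 0)
            runif(length(tms)) >= cfg@deletionProb else rep(TRUE, length(tms))
          if (any(keep)) {
            spkRows <- rbind(spkRows, data.frame(network = f,
                                                 neuron = mem[keep],
                                                 time_s = tms[keep]))
            for (ii in which(keep))
              trialSpikes[[mem[ii]]] <- c(trialSpikes[[mem[ii]]], tms[ii])
          }
        }
      }
      for (j in seq_len(J)) {
        rate <- cfg@noiseRate[j, l]
        if (rate > 0) {
          n <- rpois(1, rate * cfg@trialLen)
          if (n > 0)
            trialSpikes[[j]] <- c(trialSpikes[[j]],
                                  runif(n, 0, cfg@trialLen))
        }
        trialSpikes[[j]] <- sort(trialSpikes[[j]])
      }
      spikes[[l]] <- trialSpikes
      onsets[[l]] <- if (is.null(onRows))
        data.frame(network = integer(), rep = integer(), onset_s = numeric())
        else onRows
      seqSpikes[[l]] <- if (is.null(spkRows))
        data.frame(network = integer(), neuron = integer(), time_s = numeric())
        else spkRows
    }
    membership <- matrix(0L, J, Fn)
    timelines <- matrix(0, J, Fn)
    for (f in seq_len(Fn)) {
      membership[cfg@networks[[f]]$members, f] <- 1L
      timelines[cfg@networks[[f]]$members, f] <- cfg@networks[[f]]$timeline
    }
    list(recording = SpikeRecording(spikes, rep(cfg@trialLen, L),
                                    samplingRate = cfg@samplingRate),
         truth = new("GroundTruth", membership = membership,
                     timelines = timelines, repeats = cfg@repeats,
                     onsets = onsets, seqSpikes = seqSpikes))
  })
}
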