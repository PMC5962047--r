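# Recovery quantification against simulated ground truth, and continuous
# cross-correlograms for validating extracted time delays.

#' Pearson recovery of a profile
#'
#' Standard Pearson correlation between an extracted profile and its
#' simulated equivalent. For trial profiles the extracted profile is the
#' squared trial profile and the simulated one the per-trial sequence
#' repeat count.
#'
#' @param extracted,simulated numeric vectors of equal length, neither
#'   constant.
#' @return Pearson r in `[-1, 1]`
#' @export
pearsonRecovery <- function(extracted, simulated) {
  stopifnot(length(extracted) == length(simulated))
  if (sd(extracted) == 0 || sd(simulated) == 0)
    stop("constant profile: Pearson recovery undefined")
  cor(extracted, simulated)
}

#' Circular time-profile recovery coefficient
#'
#' `|sum_j exp(i 2 pi g sigmaE_j) * conj(exp(i 2 pi g sigmaS_j)) * As_j| /
#' sum_j As_j`, with `As` the simulated (binary) neuron profile; ranges
#' from 0 to 1 (perfect recovery) and is invariant to global time offsets
#' and to shifts by whole cycles 1/g of either argument.
#'
#' @param sigmaE,sigmaS extracted and simulated time profiles in seconds.
#' @param As simulated neuron profile weights (nonnegative, sum > 0).
#' @param g gcd of the analysis frequencies in Hz.
#' @return coefficient in `[0, 1]`
#' @export
timeRecovery <- function(sigmaE, sigmaS, As, g) {
  stopifnot(length(sigmaE) == length(sigmaS), length(As) == length(sigmaE))
  if (sum(As) <= 0) stop("simulated neuron profile sums to zero")
  Mod(sum(exp(1i * 2 * pi * g * (sigmaE - sigmaS)) * As)) / sum(As)
}

#' Cast simulated ground truth as a network set
#'
#' Simulated neuron profiles are the binary membership vectors, time
#' profiles the sequence timelines (nonmembers 0), and squared trial
#' profiles are proportional to the per-trial repeat counts; profiles are
#' normalized the same way as extracted networks so the similarity
#' coefficients apply directly.
#'
#' @param truth a [GroundTruth-class]
#' @param freqs analysis frequencies the networks are compared under.
#' @return a [NetworkSet-class]
#' @export
truthAsNetworks <- function(truth, freqs = seq(50, 1000, by = 50)) {
  g <- gcdFreq(freqs)
  Fn <- ncol(truth@membership)
  K <- length(freqs); L <- nrow(truth@repeats)
  nets <- lapply(seq_len(Fn), function(f) {
    a <- truth@membership[, f]
    counts <- truth@repeats[, f]
    new("SpikeNetwork",
        neuronProfile = a / l2norm(a),
        timeProfile = wrapTime(truth@timelines[, f], g),
        freqProfile = rep(1 / sqrt(K), K),
        trialProfile = if (sum(counts) > 0) sqrt(counts / sum(counts))
                       else numeric(L),
        scale = 1, gcdFreq = g, neuronIds = character(0))
  })
  new("NetworkSet", networks = nets, explainedVariance = 1,
      freqs = freqs, gcdFreq = g, neuronIds = character(0),
      trialIds = character(0), fitMeta = list(groundTruth = TRUE))
}

#' Recovery of extracted networks against simulated ground truth
#'
#' Extracted networks are greedily paired to the simulated networks via
#' the similarity coefficients; each simulated network's row reports the
#' Pearson correlation of its matched neuron profile with the binary
#' membership, the Pearson correlation of the matched squared trial
#' profile with the per-trial repeat counts, and the circular time
#' recovery coefficient (`NA` when unmatched).
#'
#' @param nets extracted [NetworkSet-class]
#' @param truth a [GroundTruth-class]
#' @return data.frame with columns `network`, `matched`, `neuronR`,
#'   `trialR`, `timeCoef`
#' @export
recoveryReport <- function(nets, truth) {
  truthSet <- truthAsNetworks(truth, freqs = nets@freqs)
  m <- matchNetworks(truthSet, nets)
  g <- nets@gcdFreq
  out <- data.frame(network = m$a, matched = m$b, neuronR = NA_real_,
                    trialR = NA_real_, timeCoef = NA_real_)
  for (i in seq_len(nrow(out))) {
    f <- out$network[i]; e <- out$matched[i]
    if (is.na(e)) next
    net <- nets@networks[[e]]
    out$neuronR[i] <- pearsonRecovery(net@neuronProfile, truth@membership[, f])
    out$trialR[i] <- pearsonRecovery(net@trialProfile^2, truth@repeats[, f])
    out$timeCoef[i] <- timeRecovery(net@timeProfile, truth@timelines[, f],
                                    truth@membership[, f], g)
  }
  out[order(out$network), , drop = FALSE]
}

#' Coefficient of variation of a squared trial profile
#'
#' `100 * SD / mean` in percent, with the population (divide-by-n) SD.
#'
#' @param c2 squared trial profile weights (nonnegative, positive mean).
#' @return percent CoV
#' @export
trialProfileCoV <- function(c2) {
  if (!length(c2)) stop("empty profile")
  m <- mean(c2)
  if (m <= 0) stop("profile mean must be positive")
  100 * sqrt(mean((c2 - m)^2)) / m
}

#' Continuous cross-correlogram of a neuron pair
#'
#' Both spike trains are binarized at the recording's sampling rate and
#' convolved with a unit-peak Gaussian of the given full width at half
#' maximum (truncated at 4 SD); the correlogram is the summed lagged
#' product over time samples and trials, evaluated on the lag grid
#' `seq(-maxLag, maxLag, by = step)` (step rounded to whole samples). A
#' positive-lag peak means the second neuron spikes after the first.
#'
#' @param rec a [SpikeRecording-class]
#' @param pair length-2 vector of neuron identifiers or indices.
#' @param maxLag largest lag in seconds (default 0.020).
#' @param step lag step in seconds (default 5e-5).
#' @param fwhm Gaussian full width at half maximum in seconds (default 5e-4).
#' @return data.frame with columns `lag` (s) and `value`
#' @export
crossCorrelogram <- function(rec, pair, maxLag = 0.020, step = 5e-5,
                             fwhm = 5e-4) {
  fs <- rec@samplingRate
  stepS <- max(1L, as.integer(round(step * fs)))
  maxS <- as.integer(round(maxLag * fs))
  lagS <- seq(-maxS, maxS, by = stepS)
  j <- vapply(pair, function(p)
    if (is.character(p)) match(p, rec@neuronIds) else as.integer(p), 0L)
  if (anyNA(j)) stop("unknown neuron in pair")

  sdS <- (fwhm / (2 * sqrt(2 * log(2)))) * fs       # SD in samples
  half <- as.integer(ceiling(4 * sdS))
  kn <- (-half):half
  G <- exp(-kn^2 / (2 * sdS^2))                      # unit peak
  # discrete autocorrelation of the kernel: A(m) = sum_n G(n) G(n+m)
  Am <- (-2 * half):(2 * half)
  A <- vapply(Am, function(m) {
    ov <- kn[kn + m >= -half & kn + m <= half]
    sum(exp(-ov^2 / (2 * sdS^2)) * exp(-(ov + m)^2 / (2 * sdS^2)))
  }, 0)

  samp <- binarizeSamples(rec)
  counts <- integer(2 * (maxS + 2 * half) + 1)       # pair delays d = s2 - s1
  off <- maxS + 2 * half + 1L
  for (l in seq_len(nTrials(rec))) {
    s1 <- samp[[l]][[j[1]]]; s2 <- samp[[l]][[j[2]]]
    if (!length(s1) || !length(s2)) next
    d <- as.vector(outer(s2, s1, `-`))
    d <- d[abs(d) <= maxS + 2 * half]
    if (length(d)) {
      t <- tabulate(d + off, nbins = length(counts))
      counts <- counts + t
    }
  }
  val <- vapply(lagS, function(tau) {
    dd <- tau + Am                                   # delays hitting this lag
    ok <- dd >= -(maxS + 2 * half) & dd <= maxS + 2 * half
    sum(counts[dd[ok] + off] * A[ok])
  }, 0)
  data.frame(lag = lagS / fs, value = val)
}

#' Export a recovery table or correlogram as delimited text
#'
#' @param x data.frame (e.g. from [recoveryReport()] or
#'   [crossCorrelogram()]).
#' @param path output TSV path.
#' @return `path` invisibly
#' @export
writeTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
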