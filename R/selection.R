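# Network similarity coefficients, greedy matching, artefact flagging, and
# the odd/even spike-split reliability procedure for choosing the number of
# networks.

#' Similarity coefficients between networks
#'
#' `neuronSimilarity` is the absolute inner product of the L2-normalized
#' neuron profiles; `trialSimilarity` the same applied to the squared trial
#' profiles (re-normalized to unit L2 norm); `timeSimilarity` compares the
#' circular time profiles weighted by the normalized neuron profiles:
#' `|sum_j A1_j A2_j exp(i 2 pi gamma (sigma1_j - sigma2_j))|`, which is
#' invariant to a global time offset and to shifts by whole cycles 1/gamma.
#' All three lie in `[0, 1]`, 1 meaning identical.
#'
#' @param a1,a2 neuron profiles (numeric vectors of equal length).
#' @return similarity coefficient in `[0, 1]`
#' @export
neuronSimilarity <- function(a1, a2) {
  n1 <- l2norm(a1); n2 <- l2norm(a2)
  if (n1 == 0 || n2 == 0) stop("zero neuron profile")
  abs(sum(a1 * a2) / (n1 * n2))
}

#' @rdname neuronSimilarity
#' @param c1sq,c2sq squared trial profiles (nonnegative vectors).
#' @export
trialSimilarity <- function(c1sq, c2sq) {
  n1 <- l2norm(c1sq); n2 <- l2norm(c2sq)
  if (n1 == 0 || n2 == 0) stop("zero trial profile")
  abs(sum(c1sq * c2sq) / (n1 * n2))
}

#' @rdname neuronSimilarity
#' @param net1,net2 [SpikeNetwork-class] objects on the same neuron set.
#' @param g gcd of the analysis frequencies in Hz (defaults to the
#'   networks' own).
#' @export
timeSimilarity <- function(net1, net2, g = net1@gcdFreq) {
  A1 <- net1@neuronProfile; A2 <- net2@neuronProfile
  n1 <- l2norm(A1); n2 <- l2norm(A2)
  if (n1 == 0 || n2 == 0) stop("zero neuron profile")
  A1 <- A1 / n1; A2 <- A2 / n2
  Mod(sum(A1 * A2 * exp(1i * 2 * pi * g * (net1@timeProfile - net2@timeProfile))))
}

# the three coefficients between two networks
similarityTriplet <- function(net1, net2, g = net1@gcdFreq) {
  c(neuron = neuronSimilarity(net1@neuronProfile, net2@neuronProfile),
    time = timeSimilarity(net1, net2, g),
    trial = trialSimilarity(net1@trialProfile^2, net2@trialProfile^2))
}

#' Greedy matching of two network sets
#'
#' Pairs networks by repeatedly taking the most similar remaining pair,
#' scored by the mean of the three similarity coefficients (neuron, time,
#' trial); ties break to the lowest index pair. Sets may differ in size;
#' unmatched leftovers are reported with `NA` partners.
#'
#' @param setA,setB [NetworkSet-class] objects on the same neuron set.
#' @return data.frame with columns `a`, `b` (indices into the sets; `NA`
#'   for unmatched), the three coefficients, and their `mean`
#' @export
matchNetworks <- function(setA, setB) {
  nA <- length(setA@networks); nB <- length(setB@networks)
  if (nA == 0 || nB == 0)
    return(data.frame(a = seq_len(nA),
                      b = rep(NA_integer_, nA),
                      neuron = NA_real_, time = NA_real_, trial = NA_real_,
                      mean = NA_real_))
  g <- setA@gcdFreq
  S <- matrix(-Inf, nA, nB)
  trip <- array(NA_real_, c(nA, nB, 3))
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    ni <- setA@networks[[i]]; nj <- setB@networks[[j]]
    if (ni@scale == 0 || nj@scale == 0) next
    tr <- similarityTriplet(ni, nj, g)
    trip[i, j, ] <- tr
    S[i, j] <- mean(tr)
  }
  rows <- list()
  Swork <- S
  while (any(is.finite(Swork))) {
    best <- which(Swork == max(Swork, na.rm = TRUE), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]  # lowest pair
    i <- best[1]; j <- best[2]
    rows[[length(rows) + 1L]] <- data.frame(
      a = i, b = j, neuron = trip[i, j, 1], time = trip[i, j, 2],
      trial = trip[i, j, 3], mean = S[i, j])
    Swork[i, ] <- -Inf; Swork[, j] <- -Inf
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(a = integer(), b = integer(), neuron = numeric(),
                         time = numeric(), trial = numeric(), mean = numeric())
  leftoverA <- setdiff(seq_len(nA), out$a)
  if (length(leftoverA))
    out <- rbind(out, data.frame(a = leftoverA, b = NA_integer_,
                                 neuron = NA_real_, time = NA_real_,
                                 trial = NA_real_, mean = NA_real_))
  out[order(out$a), , drop = FALSE]
}

#' Strongest-to-second-strongest neuron weight ratio
#'
#' A high ratio indicates a power-driven single-neuron "network" that does
#' not reflect between-neuron spike timing; the conservative cutoff flags
#' ratios above 5.
#'
#' @param a neuron profile (length >= 2).
#' @param cutoff flag threshold (default 5).
#' @return list with `ratio` (>= 1, possibly `Inf`) and logical `flag`
#' @export
artefactRatio <- function(a, cutoff = 5) {
  if (length(a) < 2) stop("need at least two neurons")
  s <- sort(abs(a), decreasing = TRUE)
  ratio <- if (s[2] == 0) Inf else s[1] / s[2]
  list(ratio = ratio, flag = ratio > cutoff)
}

#' Choose the number of networks by odd/even spike-split reliability
#'
#' Builds cross spectra (with identical scaling and normalizations) for the
#' full recording and for its odd- and even-spike splits, then increments
#' the number of networks F starting at 1: at each step all three data sets
#' are fitted, and the full-data networks are greedily matched to each
#' split's networks. If every full-data network matches both splits with
#' all three similarity coefficients at or above `cutoff`, F is
#' incremented; otherwise the procedure stops and the previous (passing)
#' full-data networks are returned. `chosenF` 0 means F = 1 already failed.
#'
#' @param rec a [SpikeRecording-class]
#' @param cfg a [SpectralConfig-class]
#' @param cutoff similarity cutoff (default 0.7).
#' @param nInit random initializations per fit (default 50).
#' @param maxF largest F tried.
#' @param scaleByDuration,neuronRoot,trialwise normalization chain applied
#'   identically to all three data sets: duration scaling, neuron-wise
#'   Nth-root power normalization (`NULL` to skip), trial-wise power
#'   equalization.
#' @param splitFn function taking the recording and returning a list of two
#'   sub-recordings; the default is the odd/even spike split
#'   ([splitOddEven()]), with [splitOddEvenTrials()] as an alternative.
#' @param seed,tol,maxIter,gridStep passed to [fitSpace()].
#' @return a [ReliabilityResult-class]
#' @export
splitReliability <- function(rec, cfg = SpectralConfig(), cutoff = 0.7,
                             nInit = 50, maxF = nNeurons(rec),
                             scaleByDuration = FALSE, neuronRoot = NULL,
                             trialwise = FALSE, seed = 1, tol = 1e-8,
                             maxIter = 1000, gridStep = 1e-5,
                             splitFn = splitOddEven) {
  splits <- splitFn(rec)
  prep <- function(r) {
    x <- computeCrossSpectra(r, cfg, scaleByDuration = scaleByDuration)
    if (!is.null(neuronRoot) && neuronRoot > 1)
      x <- neuronwiseNormalize(x, neuronRoot)
    if (trialwise) x <- trialwiseNormalize(x, guardSeed = seed)
    x
  }
  Xfull <- prep(rec)
  Xodd <- prep(splits[[1]]); Xeven <- prep(splits[[2]])

  emptySet <- new("NetworkSet", networks = list(), explainedVariance = 0,
                  freqs = cfg@freqs, gcdFreq = gcdFreq(cfg),
                  neuronIds = rec@neuronIds, trialIds = rec@trialIds,
                  fitMeta = list())
  tab <- data.frame()
  lastPass <- NULL
  for (F in seq_len(max(1, maxF))) {
    seeds <- with_seed(seed + F, sample.int(.Machine$integer.max - 1L, 3))
    full <- fitSpace(Xfull, F, nInit = nInit, seed = seeds[1], tol = tol,
                     maxIter = maxIter, gridStep = gridStep)
    odd <- fitSpace(Xodd, F, nInit = nInit, seed = seeds[2], tol = tol,
                    maxIter = maxIter, gridStep = gridStep)
    even <- fitSpace(Xeven, F, nInit = nInit, seed = seeds[3], tol = tol,
                     maxIter = maxIter, gridStep = gridStep)
    ok <- TRUE
    for (sp in c("odd", "even")) {
      m <- matchNetworks(full, if (sp == "odd") odd else even)
      pass <- !is.na(m$b) & m$neuron >= cutoff & m$time >= cutoff &
        m$trial >= cutoff
      tab <- rbind(tab, data.frame(F = F, network = m$a, split = sp,
                                   neuron = m$neuron, time = m$time,
                                   trial = m$trial, pass = pass))
      if (!all(pass)) ok <- FALSE
    }
    if (!ok) break
    lastPass <- list(F = F, networks = full)
    if (F == maxF) break
  }
  if (is.null(lastPass))
    new("ReliabilityResult", chosenF = 0, networks = emptySet, table = tab,
        cutoff = cutoff)
  else
    new("ReliabilityResult", chosenF = lastPass$F, networks = lastPass$networks,
        table = tab, cutoff = cutoff)
}

#' Doubling schedule for the neuron-wise normalization root
#'
#' Runs the split-reliability procedure at roots 1, 2, 4, ... and stops at
#' the first root that yields at least one reliable network with no
#' artefact-flagged neuron profile (strongest-to-second-strongest weight
#' ratio at most `ratioCutoff`).
#'
#' @inheritParams splitReliability
#' @param maxRoot largest root tried.
#' @param ratioCutoff artefact flag threshold (default 5).
#' @param ... passed to [splitReliability()].
#' @return list with `rootN`, the chosen root's [ReliabilityResult-class],
#'   and a data.frame `trace` of per-root outcomes
#' @export
chooseNormalizationRoot <- function(rec, cfg = SpectralConfig(), maxRoot = 64,
                                    ratioCutoff = 5, ...) {
  rootN <- 1
  trace <- data.frame()
  res <- NULL
  repeat {
    res <- splitReliability(rec, cfg, neuronRoot = rootN, ...)
    flags <- vapply(networks(res), function(n)
      artefactRatio(n@neuronProfile, ratioCutoff)$flag, logical(1))
    trace <- rbind(trace, data.frame(rootN = rootN, chosenF = chosenF(res),
                                     nFlagged = sum(flags)))
    if (chosenF(res) > 0 && !any(flags)) break
    if (rootN >= maxRoot) break
    rootN <- rootN * 2
  }
  list(rootN = rootN, result = res, trace = trace)
}

#' Export a reliability report as a delimited table
#'
#' @param res a [ReliabilityResult-class]
#' @param path output TSV path
#' @return `path` invisibly
#' @export
writeReliabilityReport <- function(res, path) {
  write.table(res@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
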