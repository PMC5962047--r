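# Orchestration of simulation studies (noise / jitter / deletion grids,
# differential-rate conditions) and the recording-extraction pipeline.

# 31-bit polynomial rolling hash of a serialized R object; provenance
# stamp for output rows
cfgHash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

#' Run a simulation recovery study
#'
#' For every grid cell and replicate: simulate a recording, compute cross
#' spectra (by default 20 ms window, 50-1000 Hz in steps of 50 Hz), apply
#' the configured normalizations, fit `F` networks, and score recovery
#' against ground truth. Cells are lists with elements `noise` (Hz;
#' scalar, per-neuron vector or J x L matrix), `jitter` (s), `deletion`
#' (probability) and optionally `trialwise` (logical, default taken from
#' the `trialwise` argument) and `name`.
#'
#' @param cells list of grid-cell lists (see Details).
#' @param nReps replicate simulations per cell.
#' @param F networks to extract per fit.
#' @param nInit random initializations per fit.
#' @param seed master seed; every replicate gets an independent stream.
#' @param trialwise apply trial-wise power equalization before fitting.
#' @param neuronRoot neuron-wise Nth-root normalization (`NULL` to skip).
#' @param cfg a [SpectralConfig-class]
#' @param simArgs extra arguments passed to [simConfig()] for every cell.
#' @param tol,maxIter ALS stopping parameters for the study fits; the
#'   defaults are looser than [fitSpace()]'s since replicate averages move
#'   by far less than a replicate SEM beyond 1e-6.
#' @return list with `summary` (mean and SEM of each recovery measure per
#'   network per cell; SEM is `NA` at one replicate) and `detail` (per-rep
#'   rows, stamped with the cell config hash)
#' @export
runSimulationStudy <- function(cells, nReps = 10, F = 4, nInit = 10,
                               seed = 1, trialwise = FALSE, neuronRoot = NULL,
                               cfg = SpectralConfig(), simArgs = list(),
                               tol = 1e-6, maxIter = 300) {
  detail <- NULL
  repSeeds <- with_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2 * length(cells) * nReps),
           ncol = 2))
  row <- 0L
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    tw <- if (!is.null(cell$trialwise)) cell$trialwise else trialwise
    cellName <- if (!is.null(cell$name)) cell$name else paste0("cell", ci)
    hash <- cfgHash(list(cell = cell, F = F, nInit = nInit, tw = tw,
                         neuronRoot = neuronRoot, simArgs = simArgs))
    for (r in seq_len(nReps)) {
      row <- row + 1L
      res <- tryCatch({
        scfg <- do.call(simConfig, c(list(
          noiseRate = cell$noise, jitterMax = cell$jitter,
          deletionProb = cell$deletion, seed = repSeeds[row, 1]), simArgs))
        sim <- simulateRecording(scfg)
        x <- computeCrossSpectra(sim$recording, cfg)
        if (!is.null(neuronRoot) && neuronRoot > 1)
          x <- neuronwiseNormalize(x, neuronRoot)
        if (tw) x <- trialwiseNormalize(x, guardSeed = repSeeds[row, 1])
        nets <- fitSpace(x, F, nInit = nInit, seed = repSeeds[row, 2],
                         tol = tol, maxIter = maxIter)
        rep <- recoveryReport(nets, sim$truth)
        rep$cov <- vapply(rep$matched, function(e)
          if (is.na(e)) NA_real_
          else trialProfileCoV(nets@networks[[e]]@trialProfile^2), 0)
        rep
      }, error = function(e) {
        message("cell ", cellName, " rep ", r, " failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      res$cell <- cellName; res$rep <- r; res$hash <- hash
      detail <- rbind(detail, res)
    }
  }
  if (is.null(detail)) stop("all study replicates failed")
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sem = if (sum(!is.na(v)) > 1)
                         sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
                       else NA_real_)
  summ <- do.call(rbind, lapply(split(detail,
                                      list(detail$cell, detail$network),
                                      drop = TRUE), function(d) {
    data.frame(cell = d$cell[1], network = d$network[1], nReps = nrow(d),
               neuronR = agg(d$neuronR)[1], neuronR_sem = agg(d$neuronR)[2],
               trialR = agg(d$trialR)[1], trialR_sem = agg(d$trialR)[2],
               timeCoef = agg(d$timeCoef)[1], timeCoef_sem = agg(d$timeCoef)[2],
               cov = agg(d$cov)[1], cov_sem = agg(d$cov)[2],
               hash = d$hash[1])
  }))
  rownames(summ) <- NULL
  list(summary = summ, detail = detail)
}

#' Full extraction pipeline for a spike recording
#'
#' The end-to-end chain used on real recordings: rate-based neuron
#' selection, cross spectra with per-trial duration scaling, neuron-wise
#' Nth-root power normalization (default 32nd root), split-half
#' reliability selection of the number of networks, and (optionally) a
#' final re-estimation of the trial profiles on additionally trial-wise
#' normalized cross spectra with all other profiles held fixed.
#'
#' @param rec a [SpikeRecording-class]
#' @param minRate neuron selection threshold in Hz.
#' @param scaleByDuration divide each trial's cross spectra by its duration.
#' @param neuronRoot Nth-root power normalization (`NULL` to skip).
#' @param trialwiseRefit re-estimate trial profiles on trial-normalized
#'   spectra.
#' @param cutoff,nInit,maxF,seed,tol,maxIter passed to [splitReliability()].
#' @param cfg a [SpectralConfig-class]
#' @return list with `reliability` (a [ReliabilityResult-class]),
#'   `networks` (the selected [NetworkSet-class], trial-refitted when
#'   requested), `artefactFlags`, and `params`
#' @export
runExtractionPipeline <- function(rec, minRate = 1, scaleByDuration = TRUE,
                                  neuronRoot = 32, trialwiseRefit = TRUE,
                                  cutoff = 0.7, nInit = 50,
                                  maxF = nNeurons(rec), seed = 1,
                                  cfg = SpectralConfig(), tol = 1e-8,
                                  maxIter = 1000) {
  rec <- selectByRate(rec, minRate)
  rel <- splitReliability(rec, cfg, cutoff = cutoff, nInit = nInit,
                          maxF = maxF, scaleByDuration = scaleByDuration,
                          neuronRoot = neuronRoot, seed = seed, tol = tol,
                          maxIter = maxIter)
  nets <- rel@networks
  if (chosenF(rel) > 0 && trialwiseRefit) {
    x <- computeCrossSpectra(rec, cfg, scaleByDuration = scaleByDuration)
    if (!is.null(neuronRoot) && neuronRoot > 1)
      x <- neuronwiseNormalize(x, neuronRoot)
    x <- trialwiseNormalize(x, guardSeed = seed)
    nets <- refitTrialProfiles(x, nets)
  }
  flags <- vapply(nets@networks, function(n)
    if (n@scale == 0) NA else artefactRatio(n@neuronProfile)$flag, logical(1))
  params <- list(minRate = minRate, scaleByDuration = scaleByDuration,
                 neuronRoot = neuronRoot, trialwiseRefit = trialwiseRefit,
                 cutoff = cutoff, nInit = nInit, seed = seed,
                 windowLen = cfg@windowLen, freqs = cfg@freqs)
  list(reliability = rel, networks = nets, artefactFlags = flags,
       params = c(params, hash = cfgHash(params)))
}

#' Save / load a network set; export a human-readable summary
#'
#' `saveNetworkSet`/`loadNetworkSet` persist all profiles, scales,
#' explained variance and fit metadata as a named-list container in R
#' native serialization; `writeNetworkSummary` exports one per-network
#' block of neuron/time/trial tables as delimited text.
#'
#' @param nets a [NetworkSet-class]
#' @param path file path
#' @return `path` invisibly; `loadNetworkSet` returns the
#'   [NetworkSet-class]
#' @export
saveNetworkSet <- function(nets, path) {
  saveRDS(list(
    networks = lapply(nets@networks, function(n) list(
      neuron_profile = n@neuronProfile, time_profile_s = n@timeProfile,
      freq_profile = n@freqProfile, trial_profile = n@trialProfile,
      scale = n@scale)),
    explained_variance = nets@explainedVariance, freqs_hz = nets@freqs,
    gcd_hz = nets@gcdFreq, neuron_ids = nets@neuronIds,
    trial_ids = nets@trialIds, fit_meta = nets@fitMeta,
    version = as.character(utils::packageVersion("stnets"))), path)
  invisible(path)
}

#' @rdname saveNetworkSet
#' @export
loadNetworkSet <- function(path) {
  o <- readRDS(path)
  nets <- lapply(o$networks, function(n)
    new("SpikeNetwork", neuronProfile = n$neuron_profile,
        timeProfile = n$time_profile_s, freqProfile = n$freq_profile,
        trialProfile = n$trial_profile, scale = n$scale, gcdFreq = o$gcd_hz,
        neuronIds = o$neuron_ids))
  new("NetworkSet", networks = nets, explainedVariance = o$explained_variance,
      freqs = o$freqs_hz, gcdFreq = o$gcd_hz, neuronIds = o$neuron_ids,
      trialIds = o$trial_ids, fitMeta = o$fit_meta)
}

#' @rdname saveNetworkSet
#' @export
writeNetworkSummary <- function(nets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# networks: %d  explained variance: %.4f",
                     length(nets@networks), nets@explainedVariance), con)
  for (i in seq_along(nets@networks)) {
    n <- nets@networks[[i]]
    writeLines(sprintf("\n## network %d  scale %.6g", i, n@scale), con)
    ids <- if (length(nets@neuronIds)) nets@neuronIds
           else as.character(seq_along(n@neuronProfile))
    df <- data.frame(neuron = ids, weight = n@neuronProfile,
                     time_ms = 1e3 * n@timeProfile)
    write.table(format(df, digits = 4), con, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
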