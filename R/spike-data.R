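# Spike-train data model, file I/O, rate-based selection, odd/even splitting.

#' Construct a SpikeRecording
#'
#' @param spikes list over trials; each element a list over neurons of numeric
#'   spike-time vectors in seconds relative to trial start. Times are sorted
#'   internally.
#' @param durations numeric vector of trial durations in seconds.
#' @param neuronIds,trialIds optional identifiers; defaults are `n1, n2, ...`
#'   and `t1, t2, ...`.
#' @param samplingRate sampling rate in Hz used for binarization (default
#'   20000, the maximum rate of typical extracellular recordings).
#' @return a [SpikeRecording-class]
#' @examples
#' rec <- SpikeRecording(list(list(c(0.1, 0.3), 0.2)), durations = 1)
#' firingRates(rec)
#' @export
SpikeRecording <- function(spikes, durations,
                           neuronIds = NULL, trialIds = NULL,
                           samplingRate = 20000) {
  stopifnot(is.list(spikes), length(spikes) == length(durations))
  J <- if (length(spikes)) length(spikes[[1]]) else 0L
  if (is.null(neuronIds))
    neuronIds <- if (J) paste0("n", seq_len(J)) else character(0)
  if (is.null(trialIds))
    trialIds <- if (length(spikes)) paste0("t", seq_along(spikes))
                else character(0)
  spikes <- lapply(spikes, function(tr) lapply(tr, function(s) {
    s <- as.numeric(s)
    if (anyNA(s)) stop("NA spike time")
    sort(s)
  }))
  new("SpikeRecording", neuronIds = as.character(neuronIds),
      trialIds = as.character(trialIds), durations = as.numeric(durations),
      spikes = spikes, samplingRate = samplingRate)
}

#' Read a spike recording from a TSV file with metadata sidecar
#'
#' The spike file is tab-separated with header columns `trial_id`,
#' `neuron_id`, `spike_time_s`. Trial durations, the sampling rate and
#' (optionally) the full neuron set live in a YAML sidecar, by default at
#' `<path>.meta.yaml`, with fields `trial_ids`, `durations_s`,
#' `sampling_rate_hz` and optionally `neuron_ids`.
#'
#' @param path path to the spike TSV.
#' @param metaPath path to the sidecar; default `paste0(path, ".meta.yaml")`.
#' @return a [SpikeRecording-class]
#' @seealso [saveSpikes()] for the inverse; the pair round-trips spike times
#'   at full double precision.
#' @export
loadSpikes <- function(path, metaPath = paste0(path, ".meta.yaml")) {
  if (!file.exists(path)) stop("spike file not found: ", path)
  if (!file.exists(metaPath)) stop("metadata sidecar not found: ", metaPath)
  meta <- yaml::read_yaml(metaPath)
  for (field in c("trial_ids", "durations_s", "sampling_rate_hz"))
    if (is.null(meta[[field]])) stop("metadata sidecar missing field: ", field)
  df <- read.delim(path, colClasses = c("character", "character", "character"))
  need <- c("trial_id", "neuron_id", "spike_time_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("spike file missing column(s): ", paste(miss, collapse = ", "))
  times <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(is.na(times) & !is.na(df$spike_time_s))
  if (length(bad)) stop("non-numeric spike_time_s in row ", bad[1],
                        " (", df$spike_time_s[bad[1]], ")")
  if (anyNA(times) && nrow(df)) stop("missing spike_time_s in row ", which(is.na(times))[1])

  trialIds <- as.character(meta$trial_ids)
  durations <- as.numeric(meta$durations_s)
  if (length(durations) != length(trialIds))
    stop("metadata: durations_s and trial_ids differ in length")
  neuronIds <- if (!is.null(meta$neuron_ids)) as.character(meta$neuron_ids)
               else sort(unique(df$neuron_id))

  l <- match(df$trial_id, trialIds)
  if (anyNA(l)) stop("row ", which(is.na(l))[1], ": trial_id '",
                     df$trial_id[which(is.na(l))[1]], "' not declared in metadata")
  j <- match(df$neuron_id, neuronIds)
  if (anyNA(j)) stop("row ", which(is.na(j))[1], ": neuron_id '",
                     df$neuron_id[which(is.na(j))[1]], "' not declared in metadata")
  out <- which(times < 0 | times > durations[l])
  if (length(out))
    stop(sprintf("row %d: spike_time_s = %g outside trial '%s' of duration %g s",
                 out[1], times[out[1]], df$trial_id[out[1]], durations[l[out[1]]]))

  spikes <- lapply(seq_along(trialIds), function(li) {
    lapply(seq_along(neuronIds), function(ji) {
      sort(times[l == li & j == ji])
    })
  })
  SpikeRecording(spikes, durations, neuronIds = neuronIds, trialIds = trialIds,
                 samplingRate = as.numeric(meta$sampling_rate_hz))
}

#' Write a spike recording to a TSV file with metadata sidecar
#'
#' @param rec a [SpikeRecording-class]
#' @inheritParams loadSpikes
#' @return `path`, invisibly
#' @export
saveSpikes <- function(rec, path, metaPath = paste0(path, ".meta.yaml")) {
  rows <- list()
  for (l in seq_along(rec@trialIds))
    for (j in seq_along(rec@neuronIds)) {
      s <- rec@spikes[[l]][[j]]
      if (length(s))
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = rec@trialIds[l], neuron_id = rec@neuronIds[j],
          spike_time_s = sprintf("%.17g", s))
    }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(trial_id = character(), neuron_id = character(),
                        spike_time_s = character())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(trial_ids = as.list(rec@trialIds),
                        durations_s = as.list(rec@durations),
                        sampling_rate_hz = rec@samplingRate,
                        neuron_ids = as.list(rec@neuronIds)), metaPath)
  invisible(path)
}

#' Keep neurons whose average firing rate reaches a threshold
#'
#' The average rate is total spike count over total recorded duration;
#' neurons at exactly the threshold are kept.
#'
#' @param rec a [SpikeRecording-class]
#' @param minRate minimum average rate in Hz (>= 0).
#' @return a [SpikeRecording-class] with the retained neurons
#' @export
selectByRate <- function(rec, minRate = 1) {
  stopifnot(minRate >= 0)
  keep <- which(firingRates(rec) >= minRate)
  if (!length(keep))
    stop("no neuron reaches ", minRate,
         " Hz; lower the threshold (rates range ",
         paste(signif(range(firingRates(rec)), 3), collapse = "-"), " Hz)")
  spikes <- lapply(rec@spikes, function(tr) tr[keep])
  SpikeRecording(spikes, rec@durations, neuronIds = rec@neuronIds[keep],
                 trialIds = rec@trialIds, samplingRate = rec@samplingRate)
}

#' Split a recording into odd- and even-numbered spikes per neuron
#'
#' Spikes of each neuron are enumerated over the whole recording in trial
#' order, then time order within trial; the 1st, 3rd, 5th, ... go to the
#' first split, the 2nd, 4th, ... to the second. The multiset union of the
#' two splits equals the original recording, and per-neuron counts differ
#' by at most one.
#'
#' @param rec a [SpikeRecording-class]
#' @return list of two [SpikeRecording-class] objects, `odd` and `even`
#' @export
splitOddEven <- function(rec) {
  J <- nNeurons(rec); L <- nTrials(rec)
  odd <- even <- rec@spikes
  for (j in seq_len(J)) {
    idx <- 0L
    for (l in seq_len(L)) {
      s <- rec@spikes[[l]][[j]]
      n <- length(s)
      if (n) {
        pos <- idx + seq_len(n)
        odd[[l]][[j]] <- s[pos %% 2L == 1L]
        even[[l]][[j]] <- s[pos %% 2L == 0L]
        idx <- idx + n
      }
    }
  }
  list(odd = SpikeRecording(odd, rec@durations, rec@neuronIds, rec@trialIds,
                            rec@samplingRate),
       even = SpikeRecording(even, rec@durations, rec@neuronIds, rec@trialIds,
                             rec@samplingRate))
}

#' Split a recording into odd- and even-numbered trials
#'
#' Alternative splitter for the reliability procedure: trials 1, 3, 5, ...
#' versus trials 2, 4, 6, ... (all spikes kept within each trial).
#'
#' @param rec a [SpikeRecording-class]
#' @return list of two [SpikeRecording-class] objects, `odd` and `even`
#' @seealso [splitOddEven()] for the default per-neuron spike split
#' @export
splitOddEvenTrials <- function(rec) {
  pick <- function(keep) SpikeRecording(rec@spikes[keep],
                                        rec@durations[keep],
                                        rec@neuronIds, rec@trialIds[keep],
                                        rec@samplingRate)
  L <- nTrials(rec)
  list(odd = pick(seq(1, L, by = 2)),
       even = pick(seq(2, L, by = 2)))
}
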