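# Diagonal (congruence) normalizations of cross spectra. Both act through
# positive diagonal weight matrices, so Hermitian structure, positive
# semi-definiteness and coherency (off-diagonal / sqrt(power product)) are
# preserved.

#' Neuron-wise Nth-root power normalization
#'
#' Rescales the cross spectra so that each neuron's total power (its
#' diagonal summed over frequencies and trials) equals the Nth root of its
#' pre-normalization total power, damping firing-rate differences between
#' neurons. Off-diagonal elements are rescaled by the geometric mean of the
#' two neurons' scale factors. `rootN = 1` is the identity.
#'
#' @param x a [CrossSpectra-class]
#' @param rootN integer root N >= 1.
#' @return a [CrossSpectra-class]
#' @export
neuronwiseNormalize <- function(x, rootN) {
  if (rootN < 1) stop("rootN must be >= 1")
  J <- nNeurons(x)
  P <- vapply(seq_len(J), function(j) sum(Re(x@values[j, j, , ])), 0)
  if (any(P <= 0))
    stop("neuron(s) with zero total power: ",
         paste(x@neuronIds[P <= 0], collapse = ", "),
         "; remove silent neurons (selectByRate) or apply the trial-wise ",
         "zero-guard first")
  w <- P^(1 / rootN) / P
  sw <- sqrt(w)
  x@values <- x@values * as.vector(outer(sw, sw))  # recycled over (k, l)
  x@provenance <- c(x@provenance, list(neuronwise_root = rootN))
  x
}

#' Trial-wise power equalization
#'
#' Rescales the cross spectra so that, per neuron and frequency, power is
#' identical across trials and equal to the pre-normalization power summed
#' over trials. Because the normalization acts through a diagonal weight
#' matrix, off-diagonal magnitudes keep reflecting the relative amount of
#' spike timing consistency. Zero diagonal entries (a neuron silent in a
#' trial) are first replaced by seeded noise of trivial strength
#' (1e3 * machine epsilon times the mean nonzero power) so the
#' normalization is defined everywhere.
#'
#' @param x a [CrossSpectra-class]
#' @param guardSeed seed for the zero-guard noise.
#' @return a [CrossSpectra-class]
#' @export
trialwiseNormalize <- function(x, guardSeed = 1L) {
  d <- dim(x@values); J <- d[1]; K <- d[3]; L <- d[4]
  v <- x@values
  p <- array(0, c(J, K, L))
  for (l in seq_len(L)) for (k in seq_len(K))
    p[, k, l] <- Re(diag(v[, , k, l, drop = TRUE]))
  zero <- p <= 0
  if (any(zero)) {
    m <- if (any(!zero)) mean(p[!zero]) else 1
    p[zero] <- with_seed(guardSeed,
                         runif(sum(zero), 0, 1e3 * .Machine$double.eps * m))
  }
  tot <- apply(p, c(1, 2), sum)                       # J x K
  for (l in seq_len(L)) for (k in seq_len(K)) {
    if (any(zero[, k, l])) {
      jz <- which(zero[, k, l])
      v[cbind(jz, jz, k, l)] <- p[jz, k, l] + 0i
    }
    sw <- sqrt(tot[, k] / p[, k, l])
    v[, , k, l] <- outer(sw, sw) * v[, , k, l]
  }
  x@values <- v
  x@provenance <- c(x@provenance, list(trialwise = TRUE, guard_seed = guardSeed))
  x
}
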