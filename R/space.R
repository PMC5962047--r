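# Fitting the cross-spectra decomposition: each network f contributes
#   lambda_f * a[j1] a[j2] * exp(i 2 pi phi_k (sigma[j1] - sigma[j2]))
#            * b2[k] * c2[l]
# where b2 and c2 are the squared frequency and trial profiles. The fit is
# alternating least squares from multiple random initializations; profile
# indeterminacies (scale, sign, circular time offset) are resolved
# afterwards without changing the model prediction.

# spatial vectors u[j,k] = a_j exp(i 2 pi f_k sigma_j) of one network
netSpatial <- function(net, freqs) {
  outer(net@neuronProfile, rep(1, length(freqs))) *
    exp(1i * 2 * pi * outer(net@timeProfile, freqs))
}

# wrap times into (-1/(2g), +1/(2g)]
wrapTime <- function(s, g) s - ceiling(s * g - 0.5) / g

# resolve scale/sign/offset indeterminacies of raw ALS factors; exact in the
# sense that the model prediction is unchanged
resolveNetwork <- function(araw, sraw, beta, gam, g, neuronIds) {
  na <- l2norm(araw); sb <- sum(beta); sc <- sum(gam)
  J <- length(araw); K <- length(beta); L <- length(gam)
  if (na == 0 || sb == 0 || sc == 0)
    return(new("SpikeNetwork", neuronProfile = numeric(J),
               timeProfile = numeric(J), freqProfile = numeric(K),
               trialProfile = numeric(L), scale = 0, gcdFreq = g,
               neuronIds = neuronIds))
  a <- araw / na
  if (mean(a) < 0) a <- -a                 # sign enters the model pairwise
  jmax <- which.max(abs(a))
  s <- wrapTime(sraw - sraw[jmax], g)
  new("SpikeNetwork", neuronProfile = a, timeProfile = s,
      freqProfile = sqrt(beta / sb), trialProfile = sqrt(gam / sc),
      scale = na^2 * sb * sc, gcdFreq = g, neuronIds = neuronIds)
}

#' Fit spike timing networks to cross spectra
#'
#' Alternating least squares over the parameter blocks of all `F` networks
#' (per-frequency rank-one spatial update with projection onto the
#' magnitude/linear-phase structure, then nonnegative least squares for the
#' squared frequency and trial profiles), restarted from `nInit` random
#' initializations; the initialization with the lowest residual sum of
#' squares is kept. Cross-network interaction terms are structurally absent
#' from the model.
#'
#' @param x a [CrossSpectra-class]
#' @param F number of networks to extract (>= 0).
#' @param nInit number of random initializations.
#' @param seed integer seed; spawns one independent stream per
#'   initialization.
#' @param tol relative loss-change convergence tolerance.
#' @param maxIter maximum ALS iterations per initialization.
#' @param gridStep resolution in seconds of the dense time-profile search
#'   grid over one cycle of 1/gcd(freqs); each grid optimum is refined by
#'   golden-section search.
#' @return a [NetworkSet-class]; `fitMeta(x)$converged` is `FALSE` when the
#'   best initialization hit `maxIter`
#' @export
fitSpace <- function(x, F, nInit = 10, seed = 1, tol = 1e-8, maxIter = 1000,
                     gridStep = 1e-5) {
  stopifnot(F >= 0)
  J <- nNeurons(x); K <- length(x@freqs); L <- nTrials(x)
  g <- gcdFreq(x)
  normX2 <- sum(Mod(x@values)^2)
  if (normX2 == 0) stop("all-zero cross spectra")
  if (F == 0)
    return(new("NetworkSet", networks = list(), explainedVariance = 0,
               freqs = x@freqs, gcdFreq = g, neuronIds = x@neuronIds,
               trialIds = x@trialIds,
               fitMeta = list(F = 0, nInit = nInit, seed = seed)))

  half <- 1 / (2 * g)
  initSeeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, nInit))
  inits <- lapply(initSeeds, function(s) with_seed(s, list(
    A = matrix(runif(J * F, 0.1, 1), J, F),
    S = matrix(runif(J * F, -half, half), J, F),
    B = matrix(runif(K * F, 0.5, 1.5), K, F),
    C = matrix(runif(L * F, 0.5, 1.5), L, F))))

  Xm <- x@values
  dim(Xm) <- c(J * J * K, L)
  fits <- space_als_cpp(Xm, x@freqs, J, F, inits, tol, maxIter, 1 / g, gridStep)
  losses <- vapply(fits, `[[`, 0, "loss")
  best <- which.min(losses)                  # ties: lowest init index
  fit <- fits[[best]]

  nets <- lapply(seq_len(F), function(f)
    resolveNetwork(fit$A[, f], fit$S[, f], fit$B[, f], fit$C[, f], g,
                   x@neuronIds))
  new("NetworkSet", networks = nets,
      explainedVariance = 1 - fit$loss / normX2,
      freqs = x@freqs, gcdFreq = g, neuronIds = x@neuronIds,
      trialIds = x@trialIds,
      fitMeta = list(F = F, nInit = nInit, seed = seed, tol = tol,
                     maxIter = maxIter, losses = losses, bestInit = best,
                     iterations = vapply(fits, `[[`, 0L, "iterations"),
                     converged = fit$converged,
                     worstLossIncrease = fit$worst_increase))
}

#' Model prediction of a fitted network set
#'
#' Reconstructs the complex J x J x K x L tensor implied by the networks;
#' Hermitian with real nonnegative diagonal by construction.
#'
#' @param nets a [NetworkSet-class]
#' @return complex array of dimension J x J x K x L
#' @export
modelPredict <- function(nets) {
  J <- length(nets@neuronIds); K <- length(nets@freqs)
  L <- length(nets@trialIds)
  Xhat <- array(0 + 0i, c(J, J, K, L))
  for (net in nets@networks) {
    if (net@scale == 0) next
    U <- netSpatial(net, nets@freqs)
    b2 <- net@freqProfile^2; c2 <- net@trialProfile^2
    Tf <- array(0 + 0i, c(J, J, K))
    for (k in seq_len(K))
      Tf[, , k] <- (net@scale * b2[k]) * (U[, k] %o% Conj(U[, k]))
    Xhat <- Xhat + outer(Tf, c2)
  }
  Xhat
}

#' Fraction of cross-spectral variance explained by a model tensor
#'
#' `1 - sum(|x - xhat|^2) / sum(|x|^2)`, at most 1 (can be negative for a
#' model worse than the zero tensor).
#'
#' @param x observed complex tensor or [CrossSpectra-class]
#' @param xhat model tensor of the same shape
#' @return scalar fraction
#' @export
explVariance <- function(x, xhat) {
  if (is(x, "CrossSpectra")) x <- x@values
  if (is(xhat, "CrossSpectra")) xhat <- xhat@values
  stopifnot(all(dim(x) == dim(xhat)))
  n2 <- sum(Mod(x)^2)
  if (n2 == 0) stop("all-zero reference tensor")
  1 - sum(Mod(x - xhat)^2) / n2
}

#' Re-estimate trial profiles on (re-)normalized cross spectra
#'
#' One final least-squares pass in which the neuron, time and frequency
#' profiles are kept constant and only the squared trial profiles (and the
#' network scales) are re-estimated, by nonnegative least squares per trial.
#' Typically used to re-estimate trial profiles on trial-wise normalized
#' cross spectra after the networks were found without that normalization.
#'
#' @param x a [CrossSpectra-class] compatible with the fit.
#' @param nets a [NetworkSet-class]
#' @return a [NetworkSet-class]; neuron, time and frequency profiles are
#'   returned bit-identical
#' @export
refitTrialProfiles <- function(x, nets) {
  J <- nNeurons(x); K <- length(x@freqs); L <- nTrials(x)
  Fn <- length(nets@networks)
  if (Fn == 0) return(nets)
  stopifnot(J == length(nets@neuronIds), K == length(nets@freqs))
  Us <- lapply(nets@networks, netSpatial, freqs = x@freqs)
  b2 <- vapply(nets@networks, function(n) n@freqProfile^2, numeric(K))
  b2 <- matrix(b2, K, Fn)
  G <- matrix(0, Fn, Fn)
  for (f in seq_len(Fn)) for (gg in seq_len(Fn)) {
    uu <- vapply(seq_len(K), function(k)
      Mod(sum(Conj(Us[[f]][, k]) * Us[[gg]][, k]))^2, 0)
    G[f, gg] <- sum(b2[, f] * b2[, gg] * uu)
  }
  W <- matrix(0 + 0i, J * J * K, Fn)
  for (f in seq_len(Fn)) {
    wf <- vapply(seq_len(K), function(k)
      as.vector(outer(Conj(Us[[f]][, k]), Us[[f]][, k])) * b2[k, f],
      complex(J * J))
    W[, f] <- as.vector(wf)
  }
  Xm <- x@values; dim(Xm) <- c(J * J * K, L)
  rhs <- Re(t(W) %*% Xm)                       # Fn x L
  gam <- vapply(seq_len(L), function(l) nnls_gram_cpp(G, rhs[, l]), numeric(Fn))
  gam <- matrix(gam, Fn, L)
  newNets <- lapply(seq_len(Fn), function(f) {
    net <- nets@networks[[f]]
    sg <- sum(gam[f, ])
    if (sg == 0) {
      net@trialProfile <- numeric(L); net@scale <- 0
    } else {
      net@trialProfile <- sqrt(gam[f, ] / sg)
      net@scale <- sg
    }
    net
  })
  out <- nets
  out@networks <- newNets
  out@trialIds <- x@trialIds
  out@fitMeta <- c(nets@fitMeta, list(trialRefit = TRUE))
  out@explainedVariance <- explVariance(x@values, {
    tmp <- out; modelPredict(tmp)
  })
  out
}
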