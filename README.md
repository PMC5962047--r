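# stnets — spike timing networks from multineuron recordings

`stnets` extracts **spike timing networks** — groups of neurons whose
spikes keep consistent between-neuron time delays, forming spike
sequences — from multi-trial spike recordings, without searching over
neuron subsets or delay templates. It is aimed at systems neuroscientists
working with sorted multielectrode spike trains (tens of neurons, trials
of seconds) who want to know *which* neurons fire in sequence, *with what
timeline* (at sub-millisecond resolution), and *in which trials*.

## The method

A time delay `d` between two spike trains appears in the frequency domain
as a phase difference `2πf·d` growing linearly with frequency. Binarized
spike trains are convolved with untapered complex exponentials
(`exp(-i2πfT)`, 20 ms window, 50–1000 Hz in 50 Hz steps by default) and
their cross products over time give trial- and frequency-resolved cross
spectra `X[j1, j2, k, l]`. This Hermitian 4-way tensor is decomposed by
alternating least squares into rank-one networks:

    X[j1,j2,k,l] ≈ Σ_f λ_f · a[j1,f]·a[j2,f] · exp(i2πφ_k (σ[j1,f] − σ[j2,f])) · b²[k,f] · c²[l,f]

where, per network `f`, `a` is the **neuron profile** (membership
weights), `σ` the circular **time profile** (one delay coefficient per
neuron, in seconds — the spike-sequence timeline), `b²` a frequency
profile, and `c²` the **trial profile** (per-trial network strength).
The package also provides the surrounding machinery: neuron-wise
Nth-root and trial-wise power normalizations, odd/even spike-split
reliability for choosing the number of networks, a spike-sequence
simulator with Poisson noise / jitter / deletion and full ground truth,
recovery statistics, and continuous cross-correlograms for validating
extracted delays.

## Worked example

Simulate two embedded networks (a 5-neuron sequence at 0–1–2–3–4 ms and a
3-neuron sequence at 0–2.5–5 ms) in a 10 Hz Poisson background with
±0.25 ms spike jitter, then extract them:

```r
library(stnets)
cfg <- simConfig(nNeurons = 8, nTrials = 40,
  networks = list(list(members = 1:5, timeline = c(0, 1, 2, 3, 4) / 1e3),
                  list(members = 6:8, timeline = c(0, 2.5, 5) / 1e3)),
  repeats = cbind(rep(c(1L, 2L, 0L, 0L), 10), rep(c(0L, 0L, 1L, 2L), 10)),
  noiseRate = 10, jitterMax = 0.25e-3, seed = 1)
sim  <- simulateRecording(cfg)
x    <- computeCrossSpectra(sim$recording)
nets <- fitSpace(x, F = 2, nInit = 10, seed = 1)
nets
#> NetworkSet: 2 networks, explained variance 0.286
#>  [1] SpikeNetwork (scale 4.1e+06):
#>   strongest neurons: n4 (a=0.52, sigma=0.00 ms), n2 (a=0.50, sigma=-2.00 ms),
#>     n1 (a=0.45, sigma=-3.04 ms), n5 (a=0.40, sigma=1.00 ms), n3 (a=0.34, sigma=-0.99 ms)
#>  [2] SpikeNetwork (scale 3.81e+06):
#>   strongest neurons: n7 (a=0.75, sigma=0.00 ms), n6 (a=0.48, sigma=-2.48 ms),
#>     n8 (a=0.45, sigma=2.53 ms), ...
recoveryReport(nets, sim$truth)
#>   network matched   neuronR    trialR  timeCoef
#> 1       1       1 0.9675315 0.8783141 0.9999817
#> 2       2       2 0.9538869 0.7128302 0.9999940
```

Reading the output: network 1's time profile is anchored at its strongest
neuron (`n4`, 0 ms), so neurons `n1…n5` sit at −3.04, −2.00, −0.99, 0,
+1.00 ms — the simulated 1 ms-step sequence recovered to a few hundredths
of a millisecond (time profiles are offset-free and circular with period
1/gcd(freqs) = 20 ms). Network 2 reproduces the 0–2.5–5 ms timeline. In
the recovery table, `neuronR` and `trialR` are Pearson correlations of
the extracted neuron profile against true membership and of the squared
trial profile against the per-trial sequence-repeat count; `timeCoef` is
the circular time-recovery coefficient (1 = perfect). The modest
explained variance is expected — most tensor energy is Poisson power, not
phase structure. A cross-correlogram confirms the delays independently:
`crossCorrelogram(sim$recording, c("n1", "n2"))` peaks at +1.1 ms.

On real recordings, use the end-to-end pipeline (rate filter, duration
scaling, 32nd-root power normalization, split-half selection of the
number of networks, trial-profile refit):

```r
rec <- loadSpikes("spikes.tsv")          # TSV + YAML metadata sidecar
res <- runExtractionPipeline(rec)
res$networks; res$artefactFlags
```

A thin command-line wrapper over these functions is in
`inst/scripts/stn-cli.R` (subcommands `simulate`, `spectra`, `fit`,
`reliability`, `pipeline`, `xcorr`, `study`).

See the methods vignette (`vignettes/spike-timing-networks.Rmd`) for the
model, the normalizations, the ALS scheme, the simulator's scope, and
known limitations.

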