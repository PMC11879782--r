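# eegmicrostates

Resting-state EEG microstate segmentation and paired-design statistics.

Spontaneous EEG passes through brief (~20–120 ms) periods in which the
scalp electric-field topography stays quasi-stable before switching —
*microstates*. Segmenting a resting recording into K recurring template
topographies (conventionally A–G for K = 7) and measuring how long and how
often each class is active gives compact temporal fingerprints of
large-scale brain dynamics, used for example to look for changes in
patients measured before and after chemotherapy. This package is for
researchers who need that workflow as tested, scriptable R functions:

* **Segmentation** — global field power `GFP(t) = sqrt(mean_c v_c(t)^2)`,
  strict-local-maximum peak extraction, polarity-invariant modified
  k-means on the peak maps (template update = dominant eigenvector of the
  assigned maps' outer-product sum; quality = global explained variance
  `GEV = Σ (gfp_n r_n)² / Σ gfp_n²`, maximised over restarts), two-level
  individual → grand-mean template derivation, and exact shared-variance
  sorting to any reference template set (Hungarian assignment).
* **Backfitting & features** — peak labelling by squared spatial
  correlation, nearest-neighbour label interpolation, per-class mean
  duration (ms), occurrence (Hz) and coverage, with an explicit
  edge-truncation convention.
* **Paired statistics** — paired t-tests with paired Cohen's
  d = mean(diff)/sd(diff) (so |d| = |t|/√n), 95% CIs, CI inversion to
  recover t, p and d from published confidence intervals,
  Bonferroni-adjusted significance levels and large-effect (d ≥ 0.8)
  selection, plus Pearson brain–behavior correlations.
* **Synthetic data** — a generator that plants known templates, a
  semi-Markov (gamma-duration) label sequence, a rectified 10 Hz amplitude
  envelope and average-referenced white noise at a configured SNR, so every
  stage is validated by parameter recovery without confidential study data.
* **Preprocessing** — average re-referencing and zero-phase Butterworth /
  notch filtering (0.5 Hz high-pass, 50 Hz low-pass, 60 Hz notch defaults).

## Worked example

```r
library(eegmicrostates)

# simulate one subject (64 ch, 500 Hz, 60 s, K = 4 planted classes, snr 5)
cfg <- generatorConfig(nChannels = 64, nClasses = 4, samplingRate = 500,
                       durationS = 60, snr = 5, seed = 1)
sim <- simulateRecording(cfg)

cl  <- clusterIndividual(sim$recording, K = 4, seed = 2)
cl
#> ClusterResult: K = 4, GEV = 0.9808 (restart 3, 4 iterations)

srt <- sortToTemplates(cl@templates, sim$groundTruth$templates)
round(srt$sharedVariance, 4)
#> [1] 0.9998 0.9999 0.9999 1.0000

bf <- backfitRecording(sim$recording, srt$sorted)
bf$features
#> MicrostateFeatures (fs = 500 Hz):
#>  class mean_duration_ms occurrence_hz  coverage
#>      1         50.95455      1.466667 0.0753000
#>      2         72.32370      2.883333 0.2085333
#>      3        102.82759      2.900000 0.2982000
#>      4        128.81865      3.216667 0.4179667
#> overall mean duration: 88.73 ms (unweighted), 95.14 ms (segment-weighted)
```

The GEV of 0.98 says the four fitted templates explain almost all
GFP-weighted topographic variance at the peaks; the shared variances near 1
confirm the fitted maps are the planted ones. The feature table gives, per
class, the average length of its stable segments, how many segments occur
per second, and the fraction of recording time it occupies (coverage sums
to 1). Note that recovered durations run longer than the planted means:
labels can only change at midpoints between GFP peaks (~50 ms apart at a
10 Hz alpha rhythm), an intrinsic resolution limit of peak-based
backfitting discussed in the vignette.

Published paired results that print only a 95% CI of the mean difference
can be reconstructed exactly:

```r
invertCI(3.87, 16.75, n = 8)
#> Paired t-test: n = 8, mean diff = 10.31 (SD 7.703)
#>   t(7) = 3.786, p = 0.006842, Cohen's d = 1.338, 95% CI [3.87, 16.75]
```

A bundled example table of published pre/post-chemotherapy outcomes
(`pairedOutcomesExample()`) shows this reproducing nine printed effect
sizes to ≤ 0.002.

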