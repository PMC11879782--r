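---
title: "Resting-state EEG microstate analysis: model, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegmicrostates)
```

## The model

Spontaneous EEG does not wander continuously through topographies: for
periods of roughly 20–120 ms the scalp electric field keeps a quasi-stable
spatial configuration, then switches abruptly to another one. These
quasi-stable configurations — *microstates* — recur, and resting-state
recordings are well summarised by a small number K of template topographies
(conventionally labelled A–G when K = 7) plus a per-sample label saying
which template is active.

`eegmicrostates` implements the standard two-level segmentation workflow on
average-referenced, band-filtered recordings:

1. **GFP and peak extraction.** Global field power is the per-sample
   standard deviation of voltage across channels,
   `GFP(t) = sqrt(mean_c v_c(t)^2)` for a zero-mean map. Topographies are
   sampled at strict local GFP maxima, where the signal-to-noise ratio of
   the momentary map is highest; peaks closer than `minDistanceMs`
   (default 10 ms) are pruned keeping the larger one.
2. **Polarity-invariant modified k-means.** The peak maps are clustered
   into K classes. Polarity is ignored throughout — a map and its sign-flip
   are the same topography, so similarity is the squared (or absolute)
   spatial Pearson correlation. The template update is the dominant
   eigenvector of the sum of outer products of the maps assigned to a
   class, which is the polarity-blind analogue of the cluster mean. The
   quality functional is the global explained variance
   `GEV = sum_n (gfp_n r_n)^2 / sum_n gfp_n^2`, maximised over restarts.
3. **Two-level template derivation.** Individual-level clustering per
   recording, then a second clustering of the pooled individual maps (equal
   weights) yields grand-mean maps, which are used as the backfitting
   templates so that features are comparable across subjects.
4. **Sorting.** Grand-mean maps are matched one-to-one to a reference
   template set by maximising total shared variance (squared spatial
   correlation) over assignments — solved exactly with a Hungarian
   algorithm — then reordered and sign-aligned to the reference.
5. **Backfitting and features.** Each GFP-peak map takes the label of its
   best-correlated template; intervening samples take the label of the
   nearest peak (exact midpoints go to the earlier peak). From the label
   sequence we extract, per class, the mean segment duration (ms), the
   occurrence rate (segments/s) and coverage (fraction of samples).
6. **Paired statistics.** Pre/post designs are analysed with paired
   t-tests; the effect size is the paired Cohen's d = mean(diff)/sd(diff),
   so |d| = |t|/sqrt(n). Published results that report only a 95% CI of the
   mean difference can be reconstructed with `invertCI()`, which recovers
   se = (hi − lo)/(2 t crit), the mean difference as the midpoint, and from
   them t, p and d. Multiple testing uses Bonferroni-adjusted significance
   levels (alpha/m), reported at full precision and at the conventional
   3-decimal rounding.

A note on optimisation direction: clustering selects, at fixed K, the
restart with *maximal* GEV. Some method descriptions in the applied
literature phrase the criterion as a minimisation; minimising explained
variance is not meaningful, and the direction is configurable only in the
sense that the full restart trace is reproducible from the seed.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `K` | 7 | classes | number of microstate templates (A–G convention) |
| `minDistanceMs` | 10 | ms | minimum GFP-peak separation |
| `nRestarts` | 20 | – | random restarts of the modified k-means |
| `maxIter` | 100 | – | iteration cap per restart |
| `tol` | 1e-6 | – | relative GEV change declaring convergence |
| `highpass/lowpass/notch` | 0.5 / 50 / 60 | Hz | filter corners (4th-order Butterworth, zero phase; notch biquad Q = 30) |
| `includeEdgeRuns` | FALSE | – | count edge-truncated segments in duration/occurrence |

Filter family, order and phase behaviour are conventional resting-EEG
defaults, not properties of the segmentation model; all are configurable.
Edge-truncated runs (the first and last segment of a recording) are
excluded from duration and occurrence because their observed length is
censored by the recording window — including them biases durations
downward — but they still count toward coverage. Two subject-level overall
durations are computed: the unweighted mean of class means (the default
summary, appropriate when class-level means are the unit of analysis) and
the segment-weighted mean over all interior runs.

The package ships no claimed normative template maps: numerical values of
the widely used normative A–G sets are not redistributable here, so
`sortToTemplates()` accepts any user-supplied reference matrix, and the
tests sort against planted synthetic templates.

## What the synthetic generator emulates

Real resting-state study data of this kind are typically confidential, so
every stage is validated by parameter recovery on synthetic recordings with
known ground truth:

* **Templates** are electrode-space fields of a few randomly placed,
  randomly oriented current dipoles in a homogeneous head sphere,
  average-referenced and unit-normalised, rejection-sampled until all
  pairwise |spatial correlations| are below `maxAbsTemplateCorr`
  (default 0.7). This yields realistic smooth, dipolar-looking maps
  without a full BEM/FEM forward model.
* **Label dynamics** are semi-Markov: segment lengths are gamma
  (shape 4 by default, giving realistic right-skewed durations) with
  configurable per-class means defaulting to the 20–120 ms stability
  range; the successor class is uniform over the other K − 1 classes.
* **Amplitude** is a rectified sinusoid at `alphaHz` (default 10 Hz), so
  GFP peaks arrive at about 2 × 10 = 20 per second, matching the
  eyes-closed resting rhythm the GFP-peak method exploits.
* **Noise** is white Gaussian per channel, average-referenced, scaled so
  signal RMS / noise RMS equals `snr` (RMS taken over all channels and
  samples).

What it does **not** emulate: 1/f background spectra, ocular/muscle/cardiac
artifacts, volume-conduction-correlated noise, electrode drift, or
non-stationary alpha power. Recovery results on this generator therefore
demonstrate algorithmic correctness — that the pipeline finds planted
structure at realistic SNR — not robustness to every artifact class of real
recordings, which the upstream ICA-based cleaning step (out of scope here)
is responsible for.

## Numerical choices and degenerate inputs

* Assignment ties (equal squared correlation) go to the lowest class
  index; GFP-peak ties under the distance rule keep the earlier sample;
  interpolation midpoints go to the earlier peak. All deterministic.
* An empty cluster during k-means iteration is re-seeded from the
  currently worst-explained map.
* A zero-variance map has undefined spatial correlation and errors
  explicitly; an all-zero GFP series makes GEV undefined.
* A constant label sequence has no interior runs: durations are reported
  missing and occurrences 0, with coverage 1 for the observed class.
* Paired tests with zero-variance differences return t = 0, p = 1 (all
  differences zero) or infinite t with p → 0 (identical non-zero
  differences), flagged `degenerate`.
* Filtering uses 1 s reflective padding before each forward–backward
  pass; the 0.5 Hz high-pass needs several seconds to settle, so edge
  seconds of filtered output should not be over-interpreted.

## Validation and problem sizes

The test-suite checks each stage against an independent oracle at sizes
where exhaustive computation is feasible, and the whole pipeline by
parameter recovery:

* modified k-means GEV equals the exhaustive optimum over all 127
  bipartitions of 8 maps (K = 2, eigenvector template per side);
* template sorting equals the exhaustive optimum over all 7! = 5040
  permutations;
* an 8-subject cohort (64 channels, 500 Hz, 120 s each, K = 4, snr 5,
  class mean durations spread over 40–90 ms) recovers the planted
  grand-mean templates with |correlation| ≥ 0.95, and the noise-free run
  gives GEV = 1 and 100% peak-label accuracy;
* the paired t-test's empirical type-I error over 10,000 simulated null
  cohorts of n = 8 lies in [0.04, 0.06];
* effect sizes recovered by CI inversion from a bundled published
  pre/post-chemotherapy summary table (n = 8) match the printed d values
  to ≤ 0.002.

These sizes (120 s recordings, 8 subjects, 10,000 replicates) were chosen
as the smallest instances at which the law-of-large-numbers checks are
stable; longer recordings only tighten them.

## Known limitations

* **Temporal resolution of backfitting.** Labels can only change at
  midpoints between consecutive GFP peaks, which arrive every ~50 ms at a
  10 Hz alpha rhythm. Segments shorter than the inter-peak spacing are
  absorbed into their neighbours, so recovered mean durations are biased
  upward for fast-switching classes — in the recovery experiment the bias
  is ~10% for a 90 ms class but ~45% for a 40 ms class. This is a property
  of the GFP-peak + nearest-neighbour method itself, not of this
  implementation, and is worth keeping in mind when interpreting absolute
  duration values (paired contrasts of the same class are much less
  affected, since the bias is shared by both timepoints).
* No temporal smoothing or minimum-duration rejection is applied by
  default; a minimum-duration filter is deliberately not part of the
  standard chain here because the backfitting convention interpolates
  between peaks rather than smoothing labels.
* K is fixed by the user (7 by convention); no meta-criterion for
  selecting K is provided.
* ICA-based artifact removal is out of scope; recordings are expected to
  be cleaned upstream.

## A worked example

```{r example, eval = FALSE}
library(eegmicrostates)

# simulate a small subject, cluster, sort to the planted maps, backfit
cfg <- generatorConfig(nChannels = 64, nClasses = 4, samplingRate = 500,
                       durationS = 60, snr = 5, seed = 1)
sim <- simulateRecording(cfg)
cl  <- clusterIndividual(sim$recording, K = 4, seed = 2)
srt <- sortToTemplates(cl@templates, sim$groundTruth$templates)
bf  <- backfitRecording(sim$recording, srt$sorted)
featureTable(bf$features)

# reconstruct a published effect size from its printed 95% CI (n = 8)
invertCI(3.87, 16.75, n = 8)$cohens_d
```
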