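---
title: "Methods: simulating and classifying beluga and narwhal echolocation clicks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying beluga and narwhal echolocation clicks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Belugas (*Delphinapterus leucas*) and narwhals (*Monodon monoceros*) are
the only two monodontids, share Arctic habitat, and have confusably similar
vocal repertoires.  Passive acoustic monitoring (PAM) of their populations
therefore needs a classifier that can separate the two species from
echolocation clicks alone.  `echoclass` implements such an analysis end to
end: click detection, extraction of twenty spectral/temporal click
parameters, aggregation of clicks into fixed-window *acoustic events*,
multivariate differentiation tests, and two event classifiers — a single
balanced random forest and a two-stage (call + event) classifier.  Because
raw field audio of visually confirmed single-species encounters is rarely
distributable, the package also contains a first-class synthetic data
generator whose defaults are calibrated to published event-level summary
statistics for the two species, so that every downstream stage is testable
without any download.

## The click model

A synthetic click is a sum of Gaussian-enveloped cosines (Gabor
components),

$$x(t) = \sum_i g_i \exp\!\left(-\frac{t^2}{2\sigma_i^2}\right)
          \cos(2\pi f_i t + \phi_i), \qquad \phi_i \in \{0, \pi\}.$$

A single component has an exactly Gaussian magnitude spectrum, so the
$-d$ dB half-width has the closed form
$\sqrt{d\ln 10/40}\,/(\pi\sigma)$ (`gabor_halfwidth_hz()`), which the test
suite uses as an analytic oracle for the band-edge estimators.

Two deliberate modelling choices depart from the most naive reading of
"sum of Gabor atoms":

* **Amplitudes are specified on the spectral dB scale.**  A Gaussian
  envelope's spectral amplitude scales with $\sigma$, so the time-domain
  gain is $g_i = a_i\,\sigma_{\mathrm{ref}}/\sigma_i$ where $a_i$ is the
  linear spectral amplitude.  This makes the calibration targets (spectral
  peak heights) directly controllable.
* **Components carry a sign** ($\phi_i = \pi$ means $-1$).  Two same-phase
  components centred at the same instant have strictly positive spectra
  that *add*; they can never produce a deep spectral notch.  Anti-phase
  components subtract and carve an interference null between their centre
  frequencies — which is how the narwhal template gets its characteristic
  notch (trough near 48 kHz between peaks at 43.7 and 49.3 kHz) while the
  beluga template, with only same-phase components, stays smooth.

## Species templates and calibration

The beluga template is a 68.7 kHz main lobe plus a weak same-phase
high-frequency shoulder; the shoulder is required because a symmetric
Gaussian cannot reproduce the observed *asymmetric* −3 dB edges
(65.0 kHz below vs 74.2 kHz above a 68.7 kHz peak).  The narwhal template
is a 43.7 kHz main lobe, an anti-phase secondary at 49.3 kHz and a weak
third component near 55 kHz, giving the notched spectrum and −3 dB edges
near 40.5/46 kHz.

Calibration happens in two numeric passes inside `species_template()`:
first against the analytic spectrum, then a polish against the package's
*own estimator* (noise-free click rendered into a detector-length snippet
and measured by `estimate_spectrum()`/`band_metrics()`).  The polish
matters: Hann windowing and zero-padding bias the raw calibration by a few
hundred Hz, and the recovered event means are specified in the measurement
domain.

Event- and click-level variability:

* event-level frequency offset: normal, sd 10.1 kHz (beluga) / 7.8 kHz
  (narwhal) — the published standard deviations of event-mean peak
  frequency.  Click-level offsets use 20% of that sd, a modelling choice:
  the published dispersions are *across event means*, so event averaging
  must not shrink them, and the within-event share is not separately
  published.
* a small fraction of "variant" clicks per event is shifted far in
  frequency (uniform shifts, 8%/12% up/down for beluga, 5% up for
  narwhal).  These emulate off-axis and atypical clicks and are what
  populates all four middle detector bands (20–150 kHz) for both species,
  as observed in field data.  The base template is offset by the exact
  negative of the variants' mean shift, so the population mean peak stays
  on target.
* inter-click intervals are log-normal parameterised by their mode (the
  event-level summary used downstream is a mode, so the parameterisation
  is unambiguous), with log-scale dispersion 0.15 — a steady click train
  with ≈15% interval variability.  Event-level ICI modes are themselves
  log-normal across events with the published mean and standard deviation
  (143.5 ± 70.1 ms narwhal, 177.9 ± 174.6 ms beluga).
* detection SNR is drawn uniformly in [20, 40] dB, comfortably above the
  14 dB detection threshold while leaving noise-sensitivity headroom.
  SNR is defined in the *detector's* domain (peak smoothed Teager–Kaiser
  energy over the noise-floor median), so generator SNR and detector SNR
  agree by construction.

What a green test on this world does *not* establish: robustness to
propagation effects (frequency-dependent absorption, multipath), to
overlapping click trains of multiple animals, to non-Gaussian or
non-stationary noise, or to clock/gain differences between recorders.
Durations are also systematically shorter than field values (idealised
Gabor clicks have no reverberant tail), so duration acts as a weak,
SNR-linked feature here rather than the strong one seen in real data.

## Detection and parameters

The detector high-passes (4th-order Butterworth, 4 kHz corner, designed by
bilinear transform and verified against an independent reference design),
computes Teager–Kaiser energy $\psi[n] = x[n]^2 - x[n-1]x[n+1]$ smoothed
over 0.1 ms, sets the noise floor to the median smoothed energy, and emits
one detection per excursion exceeding the floor by ≥ 14 dB, with an
800-sample snippet centred on the energy maximum and a minimum separation
of one snippet between detections.  The exact trigger logic of field
software is not published; this detector matches the stated threshold and
filter, and its false-alarm rate on pure noise is validated separately
(≤ 1 per 10 s).

Spectra use a 10 kHz Butterworth high-pass, a Hann window over at most
2.5 ms of snippet, and zero-padding to a 2048-point FFT (≈244 Hz bins at
500 kHz).  The twenty parameters are the spectral peak; second and third
peaks; the troughs between them; the three peak-to-peak differences; −3
and −10 dB minimum/maximum frequencies (outermost crossings, linearly
interpolated), bandwidths, centre frequencies and Q; Teager–Kaiser
duration (samples above 100× the 40th percentile of $\psi$); and the
inter-click interval.  Numerical conventions worth noting:

* `peak2`/`peak3` are the highest *local maxima* outside a ±2 kHz
  exclusion zone around previously selected peaks; raw order statistics
  would select main-lobe shoulders and make the troughs meaningless.  When
  no further local maxima exist the code falls back to order statistics
  outside the exclusion zones, so the fields are always populated.
* Q is reported as the dimensionless ratio centre/bandwidth (the published
  table nominally lists kHz; the ratio is unitless and that is what the
  definition computes).
* the ICI histogram mode uses 10 ms bins *centred* on multiples of 10 ms,
  ties toward the smaller interval; centring makes the estimator exact for
  constant-interval trains on the bin grid.
* detector codes are half-open bins [4,20), [20,50), [50,70), [70,100),
  [100,150), [150,250) kHz — the published ranges share endpoints, so a
  deterministic tie rule is required; 50.0 kHz maps to detector 3.

## Events and statistics

Clicks are tiled into consecutive windows anchored at each recording's
start (60 s beluga, 120 s narwhal); events need ≥ 2 clicks (otherwise the
ICI mode is undefined) and are summarised by per-parameter means plus the
modal ICI.  Differentiation uses the fifteen −3 dB ("starred") parameters:
z-scores, Euclidean distances, perMANOVA (999 permutations) and PERMDISP
(distances to group centroids in principal-coordinate space, with the
standard negative-eigenvalue correction; the dispersions are permuted
across groups).  PCA is computed on the correlation matrix and components
are declared significant by the *sequential* broken-stick rule — a
component counts only while every component up to it exceeds its
broken-stick expectation, since trailing components trivially exceed their
tiny expectations.

## Classifiers

The random forest is implemented in compiled code inside the package
because the sampling scheme is not standard bootstrap bagging: every tree
draws an equal per-class subsample *without replacement* (default 9 events
per species, half the smallest class), which prevents the unbalanced event
set (19 vs 62) from biasing the classifier and avoids the variance
underestimation that resampling stereotyped clicks with replacement would
cause.  Trees are unpruned CART with Gini splits over `mtry` = ⌊√p⌋
features; OOB predictions are majority votes over the trees in which an
event was out of bag; importance is the mean decrease in per-tree OOB
accuracy under feature permutation; proximities are the fraction of trees
in which two events share a terminal node.  Exact binomial
(Clopper–Pearson) 95% intervals and one-sided exact tests against the 50%
chance rate summarise the confusion matrices; the Clopper–Pearson choice
reproduces the published worked intervals digit for digit.  Vote ties
resolve to the alphabetically first species.

The two-stage classifier fits one balanced forest per detector code
(50 clicks per species per tree, 20 000 trees; detectors with fewer than
50 clicks in either species are dropped — at the default calibration that
removes the lowest and highest bands, leaving detectors 2–5).  Stage-2
predictors are, per retained detector, the event's mean OOB assignment
probability for each species and the proportion of the event's clicks in
that detector, plus the event ICI mode.  Missing-detector events get
proportion 0 and the *neutral* probability 0.5, which injects no class
signal.  Stage-1 probabilities come from OOB votes only, so no training
information leaks into stage 2.  Both species' probabilities are emitted
per detector for readability even though they are complementary
(collinear) for two classes.

For the encounter-similarity validation, every (beluga encounter, narwhal
encounter) pair trains its own two-stage model (10 000 trees; stage-2
sampsize half the smaller class; per-detector stage-1 samples shrink
adaptively to half the smaller class) and predicts all held-out events.
The published procedure "correlates the training and validation confusion
matrices" without naming the statistic; with two classes the per-class
correct-rate vectors have length 2, making Pearson correlation degenerate
(±1).  The default therefore correlates the four row-normalised confusion
cells; `"rates"` and `"spearman"` variants are provided behind a flag.
Correlation > 0.5 flags a pair as similar.

## Numerical and design notes

* All randomness (R and C++ sides) flows from R's RNG, so a single
  `set.seed()` reproduces any fit bit for bit; the forest's feature and
  row sampling use the same stream.
* First-click ICIs (undefined backward difference) are imputed with the
  event median before forest fitting; forests cannot handle missing
  values and the imputation is label-free.
* The pipeline renders each simulated event's occupied span (clicks ±
  0.25 s margin) rather than whole encounters, so hours of silent 500 kHz
  audio are never materialised; the detector's behaviour on pure noise is
  validated by its own false-alarm test.
* `sensitivity_grid()` defaults to 500 trees per cell (306 cells); the
  grid checks rate *stability*, not absolute performance, and the reduced
  size keeps the full grid inside seconds.  The final models always use
  the published 10 000/20 000 trees.
* The acceptance script scales nothing else down: parameter-recovery
  targets average 5 full-pipeline seeds and classifier targets 10, at the
  complete 81-event, ~6 000-click design.

## Known limitations

The synthetic world is a stated model, not a fitted one: only the
event-mean peak frequency, −3 dB edges, ICI structure, event/encounter
design and detector-band occupancy are calibrated.  Other published
statistics (e.g. −10 dB bandwidths, duration means, exact per-detector
confusion rates) emerge from the model and differ from field values in
magnitude while preserving the qualitative contrasts.  Classifier
accuracies on this well-separated world sit at or near 100%, above the
published 92.6%/97.5% — the acceptance criteria treat those as floors, not
equalities, because the real recordings (with their off-axis distortion
and noise) are not available.
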