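---
title: "Decoding the multivariate mismatch in roving-oddball MEG: models, calibration, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding the multivariate mismatch in roving-oddball MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In a roving-oddball paradigm, stimuli arrive in trains of four to six
identical tokens. The first token of every train breaks the preceding
repetition — it is a *deviant* — and as it repeats it becomes the new
*standard*. The brain's response to this structure, classically measured as
the mismatch negativity/field, can instead be read out multivariately: a
classifier trained on the sensor pattern at each time point learns to
distinguish deviant from standard trials regardless of which syllable was
played. The time course of that cross-validated classification accuracy —
the *multivariate mismatch* — carries three quantities of interest: whether
it is reliably above the 50% chance level (significance), how strong it is
(accuracy), and when it arises and peaks (latency). Comparing these across
levels of repetition (2nd through 6th presentations) asks whether
"standardness" accrues with repetition; comparing them across a control and
a dyslexia group asks whether that accrual is atypical in dyslexia.

`oddwave` implements this entire chain as tested, reusable components, plus
a synthetic-data generator with known ground truth so that every stage can
be validated without access to recordings.

## Pipeline and models

### Design generation

`generateDesign()` draws the pseudo-randomized train sequence. With the
defaults (600 trains; 200 each of lengths 4, 5, 6; five stimuli A–E) the
per-trial expansion has 3,000 rows with position counts
600/600/600/600/400/200 for positions 1–6. Consecutive trains must differ
in stimulus and all 20 ordered stimulus transitions must occur "roughly
equiprobably". We implement this exactly rather than by retry sampling:
the 599 transitions are a multiset with 19 ordered pairs occurring 30
times and one occurring 29 times, and the stimulus sequence is a seeded
Eulerian path through that transition multigraph (Hierholzer's algorithm).
A side effect of the balanced multiset is that every stimulus heads
exactly 120 trains. Stimulus selection itself is psychometric:
`fitPsychometric()` fits a four-parameter logistic (asymptotes constrained
to [0, 1], least squares via `minpack.lm`) to a participant's /ba/–/da/
labeling proportions, and `selectStimulusSet()` takes the continuum step
nearest the inflection point as stimulus C with A–E spaced two steps
apart, clamping at the continuum edge with a flag.

### The epoch simulator

`simulateEpochs()` emits trials × sensors × time arrays (default −200 to
550 ms at 1,000 Hz; 306 sensors split 102 magnetometers / 204 planar
gradiometers). Each trial is a low-rank, two-component spatiotemporal
pattern plus noise:

* a **common auditory component**: a unit-norm random sensor pattern times
  a gamma-like kernel (onset 40 ms, peak 130 ms), amplitude 45 (nominal
  fT);
* a **deviance component**: an orthogonal unit-norm pattern times a kernel
  with onset 100 ms and peak 280 ms, amplitude 30, multiplied by a
  position-in-train attenuation profile and by `1 + jitter` with jitter SD
  0.2;
* **spatially correlated Gaussian noise**: covariance built from a random
  orthogonal mixing of exponentially decaying eigenvalues (condition
  number 100, mean eigenvalue 1), scale 60, independent across time points
  and trials.

The attenuation profiles *are* the study conditions. `"control"` encodes
cumulative accrual of standardness (multipliers 1, 0.6, 0.4, 0.2, 0.1,
0.05 for positions 1–6), `"dyslexia"` encodes immediate but flat
attenuation (1, then 0.6 for every repetition), and `"null"` leaves the
deviance component untouched everywhere, so no condition information
exists. The contrast between the first two profiles is the generative
analog of the headline finding: 1sts-vs-4ths decoding should exceed
1sts-vs-2nds decoding only under cumulative attenuation.

The kernels' rise shape is a free parameter (`kernelShape`, default 2,
i.e., a quadratic rise). Faster-rising kernels make the nominal onset
detectable closer to 100 ms; the latency-recovery test uses shape 1 for
this reason (see "Latency" below). Amplitudes and noise scale were
calibrated once so that a reduced-scale synthetic participant (120-train
design, 16 sensors) decodes the equal-count repetition contrasts with peak
accuracies spanning roughly 60–95% — the per-level analyses land in the
60–80% band, and parameter-recovery tests retain headroom. They are
ordinary `groundTruth()` arguments, not constants.

`injectArtifacts()` corrupts a seeded fraction of trials with a
high-amplitude pulse on one sensor (default twice the rejection
thresholds) and returns the corrupted indices, giving the rejection stage
a ground-truth oracle.

### Preprocessing

`rejectArtifacts()` removes trials with zero signal (all samples exactly
zero) or any sensor exceeding a peak-to-peak threshold over the full epoch
(10,000 fT magnetometers, 2,500 fT/cm gradiometers), logging the violated
rule per trial and passing survivors through bit-identically.
`lowpassFilter()` applies a zero-phase 15 Hz low-pass: a Hamming-windowed
linear-phase FIR (order set by a 5 Hz transition band, kernel normalized
to exact unit DC gain) applied by centered FFT convolution with reflection
padding. Zero phase matters because the latency analyses cannot tolerate
group delay; the symmetric smearing it implies is discussed under
"Limitations". `baselineZNormalize()` subtracts the prestimulus mean and
divides by the prestimulus SD per trial and sensor, and flips the
container's normalization state, which downstream stages check — running
the pipeline out of order is therefore an error, not a silent mistake.

### Decoding

`decodeTimecourse()` implements time-resolved pairwise classification with
five ingredients, repeated `nRepetitions` times and averaged:

1. **Stratified fold assignment**: trials of each condition are randomly
   spread over 5 folds, so every fold contains both conditions.
2. **Multivariate noise normalization ("epoch" method)**: per time point
   and condition, the across-trial sensor covariance of deviations from
   the condition mean; averaged over time points, then conditions;
   estimated from the training folds only and applied to both training
   and test data.
3. **Shrinkage**: the covariance is shrunk toward its diagonal with an
   analytically chosen intensity (Ledoit–Wolf-style, computed from the
   pooled centered observations; a fixed gamma override exists). The
   whitener is the symmetric inverse square root.
4. **Pseudo-trial averaging**: trials of one condition within one fold
   average into a single summary trial, boosting SNR and neutralizing
   class imbalance at the classifier level.
5. **Linear SVM (C = 1)** at each time point on the 2 × 4 training
   pseudo-trials, tested on the 2 held-out pseudo-trials.

The SVM is solved in the dual by sequential minimal optimization,
vectorized across time points (every SMO quantity is a vector over the
time axis), with the intercept recovered from the KKT conditions. The
solver is validated against libsvm (`e1071`) on random instances — 100%
label agreement, decision-value correlations above 0.999 — and exists
because per-time-point calls into an external SVM would dominate the cost
of the calibration suites by orders of magnitude.

Whitening is linear, so pseudo-trials are averaged first and whitened
afterwards; both orders are mathematically identical and the cheaper one
is used. `temporalGeneralization()` shares the entire fold/normalize/
average/train path (on a grid decimated by 4, safe after the 15 Hz
low-pass) and only adds testing at every time point, which guarantees the
matrix diagonal equals the time-resolved result exactly, not just
statistically.

### Inference

`signPermutationClusterTest()` flips each subject's whole series around
the null value (0.5 for accuracies, 0 for differences) with independent
random signs, re-averages, and builds pointwise permutation p-values;
clusters are maximal contiguous runs of pointwise p below 0.05, their mass
is the sum of the averaged map within the run, and the corrected p is the
proportion of permutation maximal cluster masses at least as large. The
observed arrangement counts as one of the 5,000 samples, so p-values are
floored at 1/5,000 = 0.0002 — the convention that pins every minimal
p-value the method can report. Cluster extraction for all 5,000
permutation maps runs as a single pass over a guard-separated flattening
of the mask matrix, which keeps the full machinery fast enough to sit
inside bootstrap loops. A 2^10 exhaustive sign enumeration (independent,
loop-based oracle in the test helpers) agrees with the Monte-Carlo
corrected p within Monte-Carlo error.

`twoSampleClusterTest()` compares group means; the permutation scheme for
two groups is ambiguous in the field's usage, so both readings exist:
group-label permutation (default) and sign-flipping of paired difference
series (`method = "signflip-differences"`). Both are exact by
exchangeability; a 400-simulation null calibration puts the empirical
size at the nominal level.

`onsetPeakLatency()` reads the onset as the first time point of the
earliest significant cluster (no extra minimum-duration rule) and the peak
as the argmax of the group-mean series in the 0–550 ms window; the peak is
always defined, the onset carries an undefined flag when nothing is
significant. The analysis window excludes the prestimulus period because
at a 575 ms stimulus onset asynchrony the baseline of one epoch is the
late response of the previous one. `bootstrapLatencyTest()` resamples
subjects with replacement (jointly for paired designs), recomputes the
cluster test and latency per draw with a shared inner permutation seed
(common random numbers — identical inputs give exactly zero differences),
drops draws with undefined onsets (flagging the count, and the whole
result if more than half drop), and reports the two-sided p as
`2 * min(P(diff <= 0), P(diff >= 0))`.

`pooledTD()` supplies the pooled-variance two-sample t and Cohen's d used
for the behavioral battery; `behavioralReferenceTable()` bundles the
printed group summaries of the 24-vs-24 reading battery as a regression
suite — every printed t and d reproduces from the printed means and SDs
within two-decimal rounding.

### The study orchestrator

`runFullStudy()` chains everything for a two-group synthetic study:
design → per-subject simulation under the group's profile → artifact
injection → preprocessing → decoding of all configured contrasts → the
trial-count control (standards subsetted to each subject's usable
6th-trial count) → group-level one-sample tests, between-group tests, the
three ordered repetition contrasts (1v3 > 1v2, 1v4 > 1v2, 1v4 > 1v3, as
one-sided one-sample tests on difference series), bootstrap latency
comparisons, and the 5 × 5 stimulus-specific grid (each stimulus's
4th-position standards vs each of its five possible successors). Every
stage draws its seed from a pool generated once from the master seed, so
two runs with the same configuration are identical object-for-object;
`writeStudyReport()` serializes accuracy matrices, cluster tests and a
JSON manifest.

## Problem sizes used by the test-suite

The shipped tests run everything at reduced scale, chosen once: unit
fixtures use 8–32 sensors, 30–120 trains and 5–25 ms grids; the
chance-calibration suite uses the full 600-train design at 16 sensors and
a 10 ms grid over 20 seeds; the repetition-accrual recovery uses 50
control plus 50 flat cohorts of 6 subjects each (120 trains, 16 sensors,
12.5 ms grid, one decoding repetition, 500 permutations); the
stimulus-specific grid runs at the full design's trial counts with 6
subjects. Accuracy levels scale with sensor and trial counts, so numbers
quoted here describe this reduced regime, not a 306-sensor recording.

## What the generator does and does not emulate

The generator reproduces the paradigm's structure (train design,
per-position attenuation, epoch geometry), realistic spatial noise
correlation, trial-amplitude jitter, and artifact trials. It deliberately
does **not** model: continuous recordings (epochs do not overlap, although
at a 575 ms SOA real epochs share samples), temporal autocorrelation of
noise, across-trial dependence (slow session states), non-Gaussian
single-trial statistics, or biophysical source geometry. Three
consequences matter when interpreting test results:

1. **Unequal trial counts are decodable by themselves.** Pseudo-trials
   average unequal numbers of trials when the conditions have unequal
   counts, so their variances differ by the count ratio, and a linear
   classifier with an intercept can exploit that difference. On iid
   Gaussian trials this puts a genuine above-chance pedestal on null
   decoding: about +5 to +10 percentage points at ratios of 8–24, uniform
   over time (it is visible in the prestimulus window of
   deviant-vs-all-standards decoding). A dedicated test characterizes
   this. It is why the latency and repetition analyses here use the
   equal-count 1vK contrasts, and why the stimulus-specific grid (120
   standards vs as few as 5 deviants per cell) shows spurious
   above-chance decoding on synthetic data where the real study showed
   none — real single-trial noise is not iid Gaussian across trials, and
   its heavy tails and session structure evidently dilute the variance
   cue.
2. **No below-chance regime.** With balanced pseudo-trials and iid
   trials, measured long-run null accuracy at 16 trials per class is 0.5
   to within half a percentage point. The below-chance classification
   reported for real low-count, low-effect data therefore does not emerge
   here; it plausibly requires the across-trial dependence (overlapping
   epochs, nonstationarity) excluded from the generator's scope. The
   corresponding grid expectation is left failing in the acceptance suite
   rather than redefined.
3. **Zero-phase filtering smears backwards.** A 15 Hz low-pass with a
   5 Hz transition band has an impulse response hundreds of milliseconds
   wide; applied to epochs it leaks post-stimulus signal symmetrically
   into the baseline. Onset estimates on filtered, high-SNR data can
   therefore precede the generative onset. Latency-recovery tests run on
   unfiltered epochs for this reason.

## Numerical choices

Tie handling at the cluster-defining threshold includes pointwise p equal
to the threshold; exactness of the corrected test is unaffected
(exchangeability) and verified empirically. Eigenvalues of the shrunk
covariance are floored at a 1e-12 relative level before inversion.
The SMO solver iterates to an alpha-change tolerance of 1e-6 with
per-time-point convergence deactivation. Degenerate inputs fail loudly:
all-trials-rejected, zero baseline SD (with the offending trial and
sensor named), non-positive-definite noise covariance, fold starvation,
and non-converged psychometric fits (flagged, and an error only when a
stimulus set is requested without a fallback midpoint).

## Known limitations

Beyond the generator gaps above: accuracy ceilings compress the latency
of peak estimates when SNR saturates (tests pick non-saturating regimes);
the 5,000-permutation floor limits how small reportable p-values can be;
and the bootstrap latency test is conservative when onsets are undefined
in many draws (it flags rather than extrapolates). Real-data ingestion
from vendor formats is out of scope; the epoch container's on-disk schema
(array plus JSON sidecar with times, layout, trial table and
normalization state) is documented so adapters can be written.
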