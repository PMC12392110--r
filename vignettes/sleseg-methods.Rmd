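---
title: "Models and methods behind sleseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sleseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleseg)
```

# The problem

Acute brain slices kept in a disinhibiting bath (elevated K^+^, zero
Mg^2+^, with or without 4-aminopyridine) generate spontaneous
epileptiform activity that is recorded as a single-channel local field
potential (LFP): trains of similar-morphology spikes, recurring almost
rhythmically at roughly 10 Hz, organized into *seizure-like events*
(SLEs). The operational definition used throughout this package is:

* an SLE lasts at least **0.2 s**, and
* is separated from its neighbors by at least **0.1 s**.

Experiments of this kind compare treatment conditions (e.g. an
anticonvulsant at one or two doses against vehicle) through four
summary metrics per analysis unit: the **SLE fraction** (proportion of
analyzed time occupied by SLEs), the **mean SLE duration**, the **SLE
rate**, and the **spike frequency within SLEs**. `sleseg` implements
the full path from raw trace to group statistics, together with a
synthetic generator so that every stage can be exercised and validated
without access to tissue recordings.

# The synthetic LFP generator

`simulateRecording()` builds a recording from four ingredients:

1. **Event skeleton.** Event onsets follow a renewal process: the gap
   after each event is `min_gap_s` plus an exponential excess whose
   mean is chosen so that the long-run event rate equals
   `sle_rate_per_min`. Durations are lognormal
   (`sle_duration_mean_s`, `sle_duration_cv`), resampled until they
   exceed the 0.2-s definitional minimum. Because gaps are forced to
   be at least `min_gap_s` and durations at least 0.2 s, every
   ground-truth event satisfies the SLE definition by construction.
   `expectedEventCount()` returns the analytic mean event count
   `duration_s / mean_cycle` of this process, which the test suite
   compares against Monte-Carlo runs.
2. **Spikes.** Inside each event, single-trough kernels
   (`waveformKernel()`: a Gaussian trough, zero-based at its edges,
   with a unique strict minimum) are stamped at the intra-event
   frequency `intra_sle_spike_hz` (default 10 Hz) with mild
   inter-spike-interval jitter (lognormal, cv 0.05) and amplitude
   jitter (lognormal, cv 0.2). The jitters keep events "almost
   rhythmic" rather than metronomic, which matters for exercising the
   strict-minimum spike detector realistically.
3. **Interictal spikes.** Isolated kernels stamped outside events (at
   least 0.3 s away), at `interictal_rate_per_min` (default 2/min).
   They provide the false-positive class that the 0.1-s drop rule of
   the post-processing stage is designed to remove.
4. **Noise and band-limiting.** White Gaussian noise is added, and the
   assembled trace is passed through a zero-phase FFT low-pass with a
   raised-cosine rolloff at `lowpass_cutoff_hz` (default 30 Hz),
   emulating the acquisition chain's hardware filter. The FFT filter
   was chosen over a forward-backward IIR filter because it is exactly
   zero-phase, unconditionally stable at very low relative cutoffs
   (30 Hz against a 1,000-Hz Nyquist), and leaves provably negligible
   out-of-band power (< 1% is asserted by the tests). Optional 50-Hz
   hum is added *after* the low-pass, since real mains contamination
   enters downstream of the filter.

Amplitude scale: the trough depth default (8 noise SDs before
filtering) is a deliberate choice in the absence of published
amplitude/SNR figures for such recordings; it makes detection
non-trivial (filtering smears troughs, noise creates spurious local
minima) without making the segmentation task hopeless at desk scale.

Treatment effects are expressed as multipliers on mean duration,
intra-SLE spike frequency, and rate (`treatmentEffect()`), applied to
the base configuration per cohort group. Cohort seeds are derived from
a single seed by a counter-based scheme keyed only on the
(animal, slice) position, so groups differing only in treatment share
noise realizations and the identity effect `(1, 1, 1)` reproduces
control recordings bit for bit.

**What the generator does not emulate:** electrode drift, bath
temperature artifacts, slice-to-slice morphology differences, seizure
build-up dynamics over the session, multi-channel structure, or the
chemistry difference between the two disinhibition solutions. Passing
tests on synthetic cohorts therefore demonstrate that the *pipeline*
is correct and sensitive under the stated generative assumptions, not
that any particular biological effect size would be recovered from
real tissue.

# Data path to the segmenter

Recordings are analyzed in a 40-min window (minutes 100-140 of a
session; `selectAnalysisWindow()`), downsampled from 2,000 Hz to the
125-Hz label rate (`downsampleRecording()`; anti-alias low-pass at
0.4 x the target rate, a conventional guard band below the new
Nyquist), cut into non-overlapping 30-s segments (3,750 samples;
trailing remainders are dropped), and standardized per segment by
subtracting the mean and dividing by the *population* (divide-by-n)
standard deviation. The population convention is immaterial at
n = 3,750 but is fixed for bit-reproducibility; constant segments map
to all-zeros with a warning rather than erroring, so dead stretches
cannot abort batch preparation.

Sample-index intervals are half-open `[onset, offset)` and 0-based
everywhere, which makes duration arithmetic and concatenation exact;
the `EventList` class stores them on an `IRanges` backbone.

# The segmenter

`buildDetector()` constructs a stack of gated residual dilated 1-D
convolutions: each block computes tanh- and sigmoid-gated features
from a kernel-2 dilated convolution, projects them back onto a
residual path, and adds a skip contribution; a two-layer relu head
with a sigmoid output produces one probability per sample. The default
configuration (10 blocks, dilations 1-512, 32 channels) has a
receptive field of 1,024 samples (~8.2 s at 125 Hz) and on the order
of 10^4^-10^5^ parameters — small enough for rapid CPU retraining,
which is the point of the architecture. Padding is symmetric by
default because segmentation is offline and future context is
legitimate; a causal mode is kept as a configuration flag.

Training (`trainDetector()`) minimizes per-sample binary cross-entropy
with Adam (default initial learning rate 10^-3^; the optimizer choice
is a default, not a constraint). After each epoch the **corrected
validation accuracy** is computed: predictions are post-processed by
the full rule chain (below) and compared per sample against the truth
labels, with validation recordings reassembled from their segments.
When this quantity fails to improve for more than 2 epochs the
learning rate is divided by 10, and the weights of the best epoch are
retained. "Improvement" means any increase over the best value so far.

Augmentation (`augmentSegments()`) splits the training set into exact
quarters: unchanged; a weak ~50-Hz component plus Gaussian noise; one
contiguous 5-s portion per 30-s segment replaced by a Gaussian noise
burst; and random sample points replaced by Gaussian draws (10% of
points by default). The 50-Hz component is representable at the 125-Hz
label rate (Nyquist 62.5 Hz) and is therefore added there; noise
scales are in standardized units because the batch is standardized
first. Sign-inversion duplication (`duplicateWithInversion()`) doubles
the data with negated copies, teaching the model that deflection
polarity is arbitrary. The train/validation split
(`splitTrainVal()`) is recording-exclusive — SLE morphology within a
recording is too self-similar for a within-recording split to measure
generalization — and balances both the SLE-time share and the
treated-recording share between sides, by exhaustive enumeration when
feasible and a seeded random search otherwise.

The backward pass is verified against numeric gradients in the test
suite, and identical seeds reproduce initialization, training history,
and weights exactly.

# Rule-based label correction

`correctEvents()` applies, in order:

1. binarize at 0.5 (a probability equal to the threshold maps to 1);
2. maximal runs of 1s become events;
3. **drop** events strictly shorter than 0.1 s (mostly interictal
   events or noise misclassified as SLEs);
4. **merge** events separated by strictly less than 0.2 s,
   transitively;
5. **snap** each event's endpoint to one past its last strict interior
   extremum (comparison against immediate neighbors); onsets never
   move, and events without an interior extremum are unchanged.

Drop-before-merge is deliberate and consequential: a sub-0.1-s
fragment near a long event is removed before it can bridge a gap.
The strict inequalities at 0.1 s and 0.2 s, and the >= tie rule at the
binarization threshold, are fixed conventions of this implementation.
Note the deliberate asymmetry with the generator: the *manual* SLE
definition (>= 0.2 s duration, >= 0.1 s gap) governs ground truth,
while these *algorithmic* rules (drop < 0.1 s, merge < 0.2 s) govern
prediction correction. The whole chain is validated against an
independent brute-force reference on a thousand random instances.

# Spike detection and metrics

`detectSpikes()` marks a sample as a spike trough iff it is strictly
smaller than every other sample within 0.165 s before and after, and
keeps troughs inside events. Detection runs at the acquisition rate
(2,000 Hz), where trough timing is most precise. One documented
interaction: with intra-SLE spikes recurring at ~10 Hz (0.1-s
spacing), the 0.165-s window spans neighboring troughs, so shallower
neighbors are suppressed and the detected count undershoots the
stamping frequency. This is the stated behavior of the rule, is
reproduced faithfully, and cancels in between-group comparisons under
equal morphology.

`spikeFrequency()` pools spikes over pooled event time rather than
averaging per-event frequencies; pooling is robust to very short
events (a 0.2-s event with two spikes would otherwise contribute an
extreme per-event rate). Pause detection counts maximal event-free
intervals strictly longer than 120 s, including leading and trailing
gaps of the analyzed window.

`aggregateMetrics(level = "animal")` merges all slices of one animal
within an experimental group by pooling events and analyzed time and
recomputing the metrics (time-weighted fraction, count-weighted mean
duration, pooled rate, event-time-weighted spike frequency), which is
invariant to slice order and equals the slice metrics when slices are
identical. Slice-within-animal nesting is addressed only through this
merged re-analysis; no mixed-effects modelling is attempted.

# Spectral analysis

`computePsd()` is a one-sided periodogram with a periodic Hann taper
and density scaling (mean removed; `|X(f)|^2 * 2 / (fs * sum(w^2))`,
factor 1 at DC and Nyquist), numerically identical to the standard
scientific-Python implementation, against which frozen reference
values are asserted in the tests. The band is restricted to
0 < f <= 30 Hz (DC excluded, 30 Hz included), normalized to unit
total, and binned into 150 right-closed 0.2-Hz bins, a bin's value
being the **sum** of its member ordinates — summing rather than
averaging keeps normalized bins summing to exactly 1; only the scale
of raw-unit bins depends on this choice.

`bootstrapBand()` resamples recordings (not samples) with replacement,
takes the across-recording mean per bin, and reports percentile
intervals — the plain percentile bootstrap, matching the
mean-plus-interval presentation such analyses use; 10^4^ resamples by
default. `findPsdPeaks()` reports strict local maxima over bins; the
first and last bin may qualify through a one-sided comparison because
the band is artificially truncated at 0 and 30 Hz (the SLE-recurrence
peak of a 12/min process lies at 0.2 Hz, at the very edge of the first
bin). On simulated control cohorts the two characteristic peaks
emerge: one below 1 Hz from SLE recurrence and one at the intra-SLE
spike frequency (~10 Hz).

# Group statistics

Group differences are tested with the Kruskal-Wallis omnibus test
(tie-corrected H, chi-squared approximation; an exact
permutation-enumeration option is provided for small samples and is
checked against an independent oracle), followed by Dunn's post hoc
z-tests on pooled ranks with tie correction, two-sided p-values, and
Holm-Bonferroni step-down adjustment over an **explicitly passed**
family of pairs — figures in this literature bracket specific
comparisons, so the family is never guessed. Stars follow the
0.05/0.01/0.001 convention. The Fisher exact test (two-sided, by
summing hypergeometric probabilities of tables at most as probable as
the observed one) serves the pause-count comparison between the two
disinhibition solutions; the reported odds ratio is the sample
`ad/bc` (infinite when `bc = 0`).

# Pipeline and reproducibility

`runPipeline()` chains simulate, prepare, train, predict, correct,
metrics, PSD, and stats, writing a self-describing bundle (manifest,
detector archive as plain JSON, per-recording event interval files,
slice- and animal-level metric CSVs, per-group PSD tables with
bootstrap bands, statistics CSVs, and a JSON-lines run log with stage
names, seeds, and wall times). Every stage failure aborts with the
stage name. `validateConfig()` fills all defaults — every analysis
constant appears exactly once there — and rejects unknown keys before
any computation. Re-running with the same configuration and seed
reproduces all tables.

The manual-review loop that real deployments need is served by plain
interval text files (`writeEvents()` / `readEvents()`, one
`onset_s<TAB>offset_s` pair per line): export, edit, re-import,
retrain (`inst/scripts/sleseg-cli.R retrain`).

# Problem sizes used for validation

The shipped test suite chooses desk-scale sizes: spectral properties
use twelve 40-min control recordings at the full 2,000 Hz; the
segmenter check trains a 6-block, 8-channel model on 60 min of
synthetic data (with inversion duplication and full augmentation) and
evaluates on 20 held-out minutes, reaching corrected validation
accuracy >= 0.95 within 15 epochs; generator-recovery and type-I-error
checks run on 10-min recordings at reduced sampling rates, which
leaves the event process untouched. These sizes are the package's own
validation choices; the defaults users see remain the full-scale
values.

# Known limitations

* The generator's spike morphology is a single fixed kernel family;
  real SLE morphology drifts within and across events.
* The 0.165-s strict-minimum spike rule undercounts rhythmic ~10-Hz
  trains by design (see above); absolute spike frequencies are
  comparable only under equal morphology.
* The percentile bootstrap can undercover slightly for small numbers
  of recordings; with ~12 recordings per group, per-bin coverage in
  simulation sits a little below the nominal 95%.
* EDF export quantizes to 16 bits over the signal range and truncates
  metadata to the 80-character header fields; the CSV and binary
  containers are lossless.
* Training is CPU-bound, single-threaded linear algebra; the defaults
  are sized for small models, not GPU-scale experiments.
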