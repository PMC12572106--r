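---
title: "Methods: detection evaluation, call acoustics and dive discrimination for acoustic biologgers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection evaluation, call acoustics and dive discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagflight)
library(tibble)
```

This vignette describes what `tagflight` computes and why its defaults are
what they are. The package addresses the three analysis stages that follow
a sound-and-movement tag deployment on a wild bird: evaluating vocalization
detections against human annotations, characterizing the amplitude and
signal-to-noise ratio of detected calls, and discriminating anti-predatory
dives from ordinary flight in tri-axial acceleration.

## 1. Detection evaluation

### Data model

A vocalization event is a half-open time interval `[start_s, stop_s)` with
a label from four scored caller classes — *Focal* (the tagged bird),
*Non-focal* (another adult), *Crow chick* and *Cuckoo* (nestling begging
calls) — or *Unknown* when attribution was not possible. Annotations carry
no frequency bounds, so intervals, not time-frequency boxes, are the unit
of evaluation. Tables of events are plain tibbles, read and written in the
Raven Pro selection-table dialect (`Begin Time (s)` / `End Time (s)`
required; the label column name is configurable because Raven exports
vary).

### Matching

A predicted box may match an annotated box only if their interval IoU
strictly exceeds the threshold (default 0.5). Matching is one-to-one and
class-agnostic. Because greedy matching depends on input order, the
package computes an exact optimum instead: the pairing that maximizes the
number of pairs and, among those, total IoU. This is solved as a
maximum-weight bipartite matching with edge weights `iou + (n+1)`, where
the constant guarantees cardinality dominates. The result is deterministic
and invariant under row permutations. An independent exhaustive matcher
(`match_boxes_exhaustive()`, depth-first search per connected component of
the candidate graph) serves as reference in the tests and as the
ground-truth matcher inside the scenario generator; the two agree on every
random instance the test suite throws at them.

Touching intervals have IoU 0 under the half-open convention, and an IoU
of exactly 0.5 does not match (strict inequality).

### Scoring and the Unknown rules

After matching, labels are compared. Matched pair with equal scored
labels: TP for that class. Matched pair with different scored labels: FN
for the annotated class and FP for the predicted class — detection
succeeded, classification failed, and both sides of the error are counted.
Unmatched scored annotations are FN; unmatched scored predictions are FP.
*Unknown* is neutral everywhere: an undetected Unknown annotation is not a
miss, a pair involving an Unknown annotation contributes nothing, and an
Unknown-labelled prediction never generates an FP (an annotation matched
only by an Unknown prediction still counts as FN for its own class, since
the class was not recovered). How cross-class pairs and predicted-Unknown
boxes enter a published score table is rarely stated explicitly in the
literature; the convention above is this package's documented choice, and
a class-blind detection-level P/R (`detection_metrics()`) is available
separately so the detection and classification questions can be kept
apart.

Per-class precision, recall and F1 follow the standard definitions with
the 0-when-undefined convention (flagged in a `zero_denominator` column);
macro scores are unweighted means over the four classes. Feeding the
published per-class confusion counts of a trained crow-call detector
through `compute_metrics()` reproduces all of that table's six-decimal
metric values to 1e-5, which pins the arithmetic (counts like TP = 1433,
FP = 293, FN = 378 for Focal give P = 0.830243, R = 0.791275,
F1 = 0.810291; macro F1 = 0.780108).

## 2. Call acoustics

**Level.** Call level is RMS amplitude over the box span in dBFS with full
scale fixed at amplitude 1.0 (integer WAV samples are scaled by
`1/2^(bits-1)` on read). Under this reference a full-scale sine measures
−3.01 dBFS; sine- vs square-referenced dBFS is a genuine ambiguity in the
field, and the full-scale-amplitude convention is fixed here once.

**Confidence filter.** Only detections with detection probability > 0.5
*and* target-class probability > 0.5 enter acoustic analyses; both
comparisons are strict, so a call at exactly 0.5 is dropped.

**SNR.** The noise reference for a call is the nearest contiguous 4-s
window that intersects no focal call; everything that is not a focal call
— other callers, wind, wingbeats — deliberately counts as noise. The
search slides candidate windows outward from the call at 0.1-s steps and
also anchors candidates at every focal-box edge (so a snug 4-s hole
between calls is always found); the feasible window with the smallest gap
wins, ties toward earlier time, and abutting the call is allowed. If no
clean window exists in the file the call is skipped with a warning rather
than given a biased estimate. `SNR = 20·log10(RMS_call/RMS_window)`;
values above 60 dB are flagged as clipping artifacts and excluded, with
the 60.0 boundary kept. No denoising is applied at any point.

**Subsampling and summaries.** Chick-call analyses sample exactly 100
calls per individual per calendar day, only from days with at least 100
detections, without replacement under a caller-supplied seed ("day" is the
calendar day of the file's start time). Distribution summaries use
type-7 (linear interpolation) quartiles and Tukey whiskers at 1.5 IQR;
amplitude comparisons use Gaussian-kernel densities on a shared dBFS grid,
each normalized to unit area so groups of different sizes are comparable.

## 3. Motion analysis

**Normalization and decimation.** Calibration is reduced to a single
scaling so the mean acceleration-vector magnitude equals 1 g; tag-specific
per-axis offset/gain calibration depends on proprietary toolkit internals
and is out of scope — the synthetic generator produces pre-calibrated
traces. Decimation from the 200-Hz native rate to the 50-Hz working rate
low-pass filters at 0.8× the target Nyquist (zero-phase 67-tap Hamming
FIR, DC gain renormalized to exactly 1) before keeping every fourth
sample.

**Static/dynamic split.** The dynamic component is a delay-free high-pass:
a linear-phase symmetric FIR with a Hamming window, cutoff 3 Hz, with the
group delay `(taps−1)/2` removed exactly and reflect-padded edges so
output length equals input length. The static component is defined as
`raw − dynamic`, making `static + dynamic = raw` a sample-exact identity
rather than an approximation — tested to 1e-9 on random traces. The tap
count (67 at 50 Hz, ≈ 4·fs/cutoff, odd) and the reflect edge policy are
this package's choices; the filter's DC gain is forced to exactly zero by
subtracting the tap mean, so constant input yields a zero dynamic
component identically. At 10 Hz (wingbeat territory) ≥ 95% of signal power
lands in the dynamic component; at 0.2 Hz (posture/banking) ≥ 95% stays
static.

**Clips, segments, peaks.** Dive clips span ±60 s around annotated dive
timepoints, clamped to the trace, with overlapping clips merged.
Segmentation separators are runs of at least 5 s during which the
*dynamic* vector magnitude stays below 0.2 g — the dynamic component is
used because gravity keeps the raw magnitude near 1 g, which would make a
0.2-g criterion on raw data unsatisfiable; segments longer than 20 s are
kept. Banking peaks are static-z local maxima ≥ 1.8 g (normalized units,
per-clip normalization) with ≥ 50 samples (1 s at 50 Hz) separation; among
closer maxima the higher wins, ties to the earlier. Only the z axis is
tested — slow excursions also appear in y, but z is where the
discriminative signal was established. Non-dive flight segments are
supplied as labelled intervals, mirroring the manual identification of
post-nest-visit flights from audio cues; each is treated as one segment.

**Fisher test.** The 2×2 table of segment category × peak presence is
tested exactly: conditional on both margins, the two-sided p-value sums
the hypergeometric probabilities of all tables at most as probable as the
observed one (1e-12 relative slack for floating-point ties), computed in
log space via `lchoose` and clamped at 1. For the table
`[[11, 9], [3, 17]]` this gives p = 0.0187011, verified in the tests
against both a direct enumeration oracle and `stats::fisher.test`.

**Spectrogram.** For visual inspection, `accel_spectrogram()` computes a
centered STFT (periodic Hann, 128-sample window and FFT, hop 12) with
reflect padding; frames satisfy Parseval's identity to numerical
accuracy.

## 4. What the synthetic generator emulates — and what it does not

The generators produce the study conditions the analysis chain must
handle, with exact ground truth:

* **Soundscapes**: Gaussian background noise plus harmonic call bursts
  (three harmonics of a 1.2-kHz fundamental — crow-like band placement,
  safely above the front end's corner — under a Tukey envelope), passed
  through a single-pole 500-Hz high-pass emulating the tag's analogue
  front end. All levels are quoted as peak-equivalent dBFS (the level of
  the equally loud sine), so a call at −10 dBFS over −60 dBFS noise has a
  constructed SNR of 50 dB; burst and noise amplitudes are pre-compensated
  for the front-end response so measured levels land on the quoted values
  (call RMS within 1 dB of `peak − 3`). The default generation rate is
  8 kHz to keep desk-scale runs fast; the tag-native 46.875 kHz is
  supported.
* **Detection scenarios**: per-class events of mean duration 0.33 s (the
  median call duration in the annotated tag data), perturbed by boundary
  jitter, misses, spurious insertions and label flips at configurable
  rates, with expected confusion counts computed by the independent
  exhaustive matcher. Closure — `match_boxes()` + `confusion_counts()`
  recovering those counts exactly — is asserted over 100 seeds.
* **Acceleration traces**: gravity along a unit axis, a wingbeat sinusoid
  (default 5 Hz, 0.4 g — the frequency is a free parameter with no claim
  of species accuracy), sub-3-Hz Gaussian banking bumps reaching a
  specified static-z peak during dives, 60-ms landing impulses, quiescent
  gaps with the wingbeat suppressed, and white sensor noise of σ = 0.02 g
  per axis (small enough to keep quiet gaps unambiguously below the 0.2-g
  threshold).

What passing these closures shows is that the analysis chain is
self-consistent and implements its stated definitions; it does **not**
show field performance. Real tag audio has non-Gaussian, non-stationary
noise, overlapping calls, reverberation and self-noise; real flight
acceleration has variable wingbeat frequency and amplitude, posture
changes that leak into static z, and calibration drift. The published
field-scale results (1.2×10^5-scale detection counts, per-individual SNR
medians, mixed-model tag-impact analyses) depend on external raw
deployments and a trained neural detector, both outside this package's
scope; the energy detector included here is plumbing for end-to-end runs,
not a stand-in for model performance.

## 5. Numerical and design choices

* Half-open intervals and 0-based time (seconds from file start) make
  duration exactly `stop − start` and give touching boxes IoU 0.
* The matching tie-break (max pairs, then max total IoU) is chosen for
  reproducibility; distinct optimal pairings can exist only at exact IoU
  ties, which have measure zero under continuous jitter.
* Zero-denominator metrics are 0 *and flagged*, never NA, so macro
  averages stay defined on degenerate scenarios.
* The Fisher implementation enumerates the full support; with segment
  counts in the tens this is microseconds, and exactness removes any
  dependence on asymptotic approximations that small tables violate.
* Noise-window search granularity is 0.1 s plus edge-anchored candidates;
  pure sliding could miss a snug feasible hole between calls.
* Per-stage seeds derive from the pipeline seed as `seed + stage index`,
  recorded in the manifest, so stages can be rerun independently.
* Problem sizes in the test suite (1000 random matching instances ≤ 8
  boxes/side, 100 scenario seeds, 100 SNR scenes at 8 kHz, 50 dive
  cohorts, 500 Fisher tables) are the package's desk-scale choices: large
  enough to exercise tie-breaking, edge and closure behaviour, small
  enough to run as a routine check.

## 6. Known limitations

* Only mono (or first-channel) WAV is read; the tag's on-board flash
  format is undocumented and unsupported — acceleration is exchanged as
  CSV.
* 2-D (time × frequency) IoU is out of scope, as annotations carry no
  frequency bounds.
* The dive/flight comparison inherits the study design's caveat: non-dive
  flights are identified manually, and the helper heuristics here cannot
  replace that judgment.
* `sample_chick_calls()` resolves "day" as the calendar day of the file
  start without timezone arithmetic.
* The exhaustive matcher is exponential in the worst case and intended
  for reference and generator use, not production-size tables.
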