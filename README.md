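# tagflight

Analysis toolkit for animal-borne sound-and-movement tags ("biologgers")
deployed on birds, built around three questions that arise when a tag
records both audio and tri-axial acceleration from a wild corvid:

1. **How good are the vocalization detections?** Predicted call bounding
   boxes (time intervals with a caller-class label) are evaluated against
   human annotations by one-to-one interval intersection-over-union
   matching, yielding per-class and macro-averaged precision, recall and
   F1.
2. **How loud and how clean are the detected calls?** Per-call RMS level in
   dBFS and a per-call signal-to-noise ratio estimated against the nearest
   4-s noise window that contains no focal call.
3. **Can accelerometry distinguish anti-predatory dives from ordinary
   flight?** Tri-axial acceleration is split into static and dynamic
   components with a zero-delay FIR high-pass; flight bouts are segmented,
   banking peaks in static z-acceleration are detected, and the association
   between segment type and peak presence is tested with an exact
   two-sided Fisher test.

A seeded synthetic-data generator produces soundscapes, detection
scenarios and acceleration traces with known ground truth, so the whole
pipeline is testable end-to-end without field recordings.

## The core quantities

**Box matching.** Two time intervals are matched only if their IoU —
`|a ∩ b| / |a ∪ b|` on the time axis — strictly exceeds 0.5. Among all
one-to-one pairings of annotated and predicted boxes the matcher returns
the exact optimum: maximum number of pairs, ties broken by maximum total
IoU (solved as a maximum-weight bipartite matching). For each scored class
c: `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; macro scores are
unweighted means across the four caller classes (Focal, Non-focal, Crow
chick, Cuckoo). Calls labelled *Unknown* are never penalized or rewarded.

**Levels and SNR.** Levels are RMS amplitude re digital full scale 1.0, in
dB (a full-scale sine measures −3.01 dBFS).
`SNR = 20·log10(RMS_call / RMS_noise)` with the noise RMS taken from the
nearest clean 4-s window; calls with SNR > 60 dB are flagged as clipping
artifacts.

**Dive discrimination.** After normalizing so the mean acceleration-vector
magnitude is 1 g, the dynamic component is a 3-Hz linear-phase FIR
high-pass (Hamming window, group delay corrected); static = raw − dynamic
exactly. Segments separated by ≥ 5 s of dynamic magnitude < 0.2 g and
longer than 20 s are kept; a banking peak is a static-z local maximum
≥ 1.8 g with ≥ 1 s separation. The 2×2 table of segment category ×
peak presence is tested with Fisher's exact test (two-sided, exact
hypergeometric enumeration in log space).

## Worked example

```r
library(tagflight)

# a synthetic evaluation scenario: 20 events per class, 10% boundary
# jitter, 20% misses, 20% spurious detections, 10% label flips
scen <- generate_detection_scenario(detection_scenario_spec(
  n_events = 20, jitter_frac = 0.1, miss_rate = 0.2,
  spurious_rate = 0.2, label_flip_rate = 0.1, seed = 7))
ev <- evaluate_detections(scen$annotations, scen$predictions)
ev
#> Detection evaluation (IoU > 0.5, one-to-one matching)
#>   80 annotations, 84 predictions, 63 matched pairs
#> # A tibble: 5 × 8
#>   class         tp    fp    fn precision recall    f1 zero_denominator
#>   <chr>      <int> <int> <int>     <dbl>  <dbl> <dbl> <lgl>
#> 1 Focal         18     8     2     0.692  0.9   0.783 FALSE
#> 2 Non-focal     12     6     8     0.667  0.6   0.632 FALSE
#> 3 Crow chick    13     5     7     0.722  0.65  0.684 FALSE
#> 4 Cuckoo        14     8     6     0.636  0.7   0.667 FALSE
#> 5 macro         NA    NA    NA     0.679  0.712 0.691 FALSE
```

Each row gives that class's confusion counts and metrics; the `macro` row
is the unweighted mean over the four classes. `scen$expected_counts`
carries the generator's own ground-truth confusion, computed by an
independent exhaustive matcher — here it equals `ev$counts` exactly.

```r
# dive discrimination on a synthetic 10-minute trace with two banked dives
tr <- generate_accel_trace(accel_scenario_spec(600,
  dive_events = tibble::tibble(time_s = c(150, 420),
                               bank_peak_g = c(2.2, 2.0),
                               bank_width_s = c(0.8, 0.6)),
  seed = 27))
res <- analyze_dives(tr$accel, tr$dive_peak_times_s,
  flight_spans = tibble::tibble(start_s = c(10, 550), stop_s = c(50, 590)))
res
#> Dive vs non-dive flight comparison (static-z banking peaks)
#>          peak no_peak
#> dive        2       0
#> non_dive    0       2
#> Fisher exact two-sided p = 0.3333

fisher_exact_two_sided(rbind(c(11, 9), c(3, 17)))
#> [1] 0.01870113
```

Both dive clips contain a banking peak, neither control flight does; with
only four segments the exact test is far from significance (p = 1/3),
which is the honest answer at this sample size. The second call shows the
test on a field-scale table: 11 of 20 dive segments with a peak against
3 of 20 non-dive segments gives p ≈ 0.0187.

`tidy()` and `glance()` methods return per-unit and one-row summaries of
evaluation and dive-test objects; `plot_metrics()`,
`plot_snr_distribution()`, `plot_amplitude_density()`,
`plot_accel_decomposition()` and `plot_accel_spectrogram()` give ggplot2
views. `run_pipeline(pipeline_config(seed = 42), out_dir)` executes every
stage on synthetic data and writes all artifacts plus a manifest with the
configuration hash.

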