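---
title: "Models and methods behind pivotshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pivotshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pivotshift)
```

This vignette documents the scientific model the package implements, the
tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the design decisions taken where the
underlying method left choices open.

## 1. The signal model

A pivot-shift exam capture is a tri-axial angular-velocity recording
(rad/s) at 100 Hz over 5 s — 500 samples. Only the X axis is analysed:
with the phone strapped to the anteromedial tibia it aligns with the
rotation of the leg. Time is measured in **centiseconds** throughout; at
100 Hz a sample index *is* a centisecond, which removes an entire family
of unit-conversion bugs. All sample intervals are half-open `[start, end)`
and 0-based.

Each of the three consecutive maneuvers produces, in order:

1. a positive **flexion** peak (PI-III across the recording),
2. an **extension** trough (the dominant negative excursion),
3. the **pivot** region: the signature of the joint reduction.

### Peak detection

No detection algorithm is prescribed by the source method, so the package
uses a transparent one (`detect_peaks()`): candidate local maxima must
have topographic prominence of at least 20% of the global maximum
(`min_prominence_frac`), and the final selection is the admissible subset
of at most `expected_peaks` candidates with pairwise separation of at
least 50 cs (`min_separation_cs`) that maximizes summed amplitude. The
selection is an exact dynamic program, and the test suite proves it
equivalent to exhaustive subset enumeration on randomized signals. Ties in
summed amplitude break toward earlier times. Amplitudes are the raw rad/s
values at the peak samples — no interpolation and no smoothing, because
the source pipeline applies none.

The defaults suit the documented cadence (three maneuvers in five
seconds, so peaks sit > 100 cs apart); a capture with slower or faster
cadence only needs a different `peak_config()`.

### Segmentation

For each peak (`segment_maneuvers()`):

* **flexion** = `[rise start, peak)`, where the rise start is the last
  sample at or below 10% of the peak height — a noise-robust onset;
* **extension** = `[peak, trough)`, with the trough the global minimum
  between consecutive peaks (or within a 100-cs horizon after the last
  peak);
* **pivot** = `[trough, next rise start)` (window end for the last
  maneuver). A pivot shorter than 2 samples is a truncated maneuver and
  produces a warning.

The three phases tile the maneuver contiguously by construction.

### Normalization and features

Signals are min-max normalized to `[0, 1]` (`normalize_unit_interval()`).
Whether normalization should be per recording or per maneuver is not
decidable from the source material; **per recording** is the default so
that normalized pivot values are comparable across the three maneuvers of
one capture. Per-maneuver normalization can be emulated by slicing first.

From a pivot segment, `compute_features()` returns:

| feature | definition | units |
|---|---|---|
| `sd_nv` | population (divide-by-N) SD of the normalized values | — |
| `max_ov` | maximum of the original values | rad/s |
| `range_plus_mean_ov` | `(max - min) + mean` of the original values | rad/s |
| `mean_square_ov` | `sum(x^2)/N` over the segment's own N | (rad/s)² |

Three readings were fixed once and used everywhere: the population SD (it
shares its N-division with the mean-square feature), "range plus mean"
read as `(range of OV) + (mean of OV)`, and all four features computed on
the pivot slice (the maximum is *not* taken over the whole maneuver).
`sd_nv` is invariant under any affine transform of the raw signal and is
bounded by 0.5; the other three are homogeneous of degree 1, 1 and 2 in
the signal amplitude. Clinically, a large `sd_nv` means pronounced
residual oscillation after joint reduction — hypermobility.

## 2. Reliability (ICC)

Ratings are arranged as an n-targets × k-raters matrix and summarized by
classical single-rating intraclass correlations computed from ANOVA mean
squares (`icc()`), with the mean squares exposed for audit:

* `ICC(1)` — one-way random; used for **intraobserver** analysis, where
  the "raters" are an evaluator's interchangeable repeats;
* `ICC(2,1)` — two-way random, absolute agreement; used for
  **interobserver** analysis, where evaluators are a random sample of
  orthopedists and "repeatability" means agreement in value, not merely
  in ranking;
* `ICC(3,1)` — two-way mixed consistency, provided for completeness.

The source material never names a form; the defaults above are the
package's choice and every entry point accepts `form = `. Two further
open choices: the timing measure is the mean of the two **inter-peak
intervals** rather than absolute peak times (absolute times depend on
when the recording started, cadence is the evaluator-reproducible
quantity; configurable via `use_intervals`), and the interobserver matrix
uses each evaluator's **first repeat** (configurable via `aggregate`).
The amplitude measure is the mean of the three peak amplitudes.

Estimates are reported clipped to `[0, 1]` — the scale is described as
running from 0 to 1 — with the unclipped value retained in the result.
Interpretation uses Landis-Koch bands with the lowest bands merged:
below 0.2 "poor", then "fair", "moderate", "substantial", and
"almost perfect" at 0.8 and above. Confidence intervals are deliberately
out of scope (none are reported by the source method).

## 3. Grading and classes

`cdp_grade()` maps the KT-1000 side-to-side difference to grades 0-3.
The published table leaves non-integer differences between 5 and 6 mm
unmapped ("4-5" then ">6"); the package rounds the difference to the
nearest integer millimetre first and maps every rounded value of 6 mm or
more to grade 3. This makes the map total and monotone — verified
exhaustively over differences 0-20 mm in the test suite — at the cost of
reading the published ">6" as ">=6", which is recorded here as a
deliberate deviation.

`assign_class()` bins the maximum detected peak speed into classes 0-4.
The true boundaries are unpublished; the defaults `(50, 100, 150, 200)`
rad/s were chosen once to spread the synthetic generator's class
amplitudes and are overridable everywhere (`class_bins()`). Bins are
half-open upward: a speed exactly on an edge falls in the upper class.

## 4. The synthetic-data generator

`simulate_recording()` renders each maneuver as a raised-cosine flexion
lobe (half-width 25 cs, exact height at the requested sample), a
raised-cosine extension trough (half-width 20 cs, depth 60% of the peak),
and a 50-cs pivot region: a **damped sinusoid** (2 cycles, exponential
decay, relative amplitude 0.35 of the peak) for classes 1-4, or a **low
flat-topped plateau** (relative amplitude 0.06 — a hysteresis shelf) for
class 0. Additive i.i.d. Gaussian noise goes on all three axes; Y and Z
carry noise only. All randomness flows from explicit seeds, and identical
parameters give bit-identical recordings.

Two generator constants deserve explanation because their first guesses
were wrong and were corrected during development:

* *Plateau vs sinusoid amplitudes.* The pivot window opens at the
  extension trough, so every pivot segment contains the recovery limb
  from the trough back to baseline. A tall sustained plateau raises the
  segment's variance *more* than a zero-mean oscillation of comparable
  size, which would have inverted the intended ordering of `sd_nv`
  between class 0 and classes >= 1. The defaults (0.06 vs 0.35) encode
  the clinical reading — a flat, low pivot region means little residual
  joint movement — and satisfy the documented ordering for every seed in
  a 100-seed sweep.
* *Detection gain.* The detected peak speed of a simulated subject runs
  about 10.7% above the subject's characteristic amplitude: the three
  maneuvers jitter multiplicatively (max-of-three) and the unfiltered
  detector picks the largest noisy sample near the lobe top. Cohort
  amplitude bands are therefore centered at the class-bin centers
  *divided by* this measured gain (defaults 68/113/158/203 rad/s for
  grades 0-3), so that detected speeds land mid-bin and a subject's
  speed class is unambiguous.

`simulate_cohort()` builds a full study: per subject it draws KT-1000
values whose difference reproduces the requested grade, a characteristic
amplitude (uniform, ±15 rad/s band) and a characteristic maneuver cadence
(gap uniform in 130-150 cs); per recording it adds within-rater execution
noise (3% amplitude, 2 cs timing) and the rater's own gain and timing
jitter (`rater_profile()`). Per-recording RNG streams are derived by
stable hashing of (subject, evaluator, repeat) from one root seed, so
cohorts are reproducible regardless of generation order. The returned
truth table carries grade and subject-level speed class for
parameter-recovery tests.

**What the generator does not emulate:** biomechanics (no forward model
of the knee), accelerometer channels, sensor drift or clipping,
evaluator learning effects across repeats, and any correlation between
demographics and signal shape. A green test on synthetic data therefore
establishes that the *pipeline* recovers what the generator encoded — not
that the classifier would reach the same accuracy on clinical data.

## 5. Two-stage classification

The pipeline mirrors the two-stage design: stage 1 predicts the speed
class from the four pivot features; stage 2 holds one model per class,
trained only on that class's training cases, and predicts the grade.
Stage-1 truth labels come from the speed bins applied to the detected
peak speed (one of the open questions; manual labels do not exist at desk
scale). A test case routed to a class never seen in training is returned
as `"unclassifiable"` rather than forced into a grade, and the
classifiability ratio is reported alongside the metrics — mirroring the
behaviour of the original study, where several class-0/1 cases could not
be determined.

The train/test split (`split_train_test()`) draws exactly 3 test cases
per grade, but only from grades with at least 3 cases — with the study's
grade mix (10/9/9/2) this yields the 9-case test group, with the 2-case
grade-3 stratum kept entirely in training. The published sample
arithmetic for the training group is internally inconsistent, so the
package implements the stated rule, not the stated counts.

Four back ends are provided behind one interface (`fit_classifier()`):

* `"lr"` — multinomial logistic regression with a small fixed ridge
  penalty (`lambda = 1e-3`, via glmnet);
* `"svm"` — linear soft-margin SVM, one-vs-one, each binary dual solved
  exactly as a quadratic program. The default cost is `C = 1`, the
  customary libsvm default: with only a handful of training cases per
  class, harder margins latch onto spurious low-variance feature
  directions;
* `"dt"` — CART with Gini impurity, grown to purity (no pruning: the
  training sets are tiny and the published method states no
  hyperparameters);
* `"rf"` — 100 bagged CART trees on bootstrap samples and random feature
  subspaces of size ~sqrt(p).

All fits are deterministic given the seed; every tie (votes, leaf
majorities, equal-impurity splits) breaks toward the lexicographically
smallest label or earliest feature/threshold. Evaluation is
micro-averaged, under which accuracy, recall and precision coincide for
complete single-label predictions — the reason the published per-method
tables show identical columns; per-class confusion matrices are emitted
for inspection. The raw-signal baseline (`train_baseline_raw()`) feeds
the 500 X-axis samples directly to the same back ends; on simulated
cohorts it underperforms the two-stage pipeline across seeds because the
peak positions are not aligned across recordings — the desk-scale
re-statement of the finding that preprocessing is necessary.

## 6. Numerical and I/O choices

* Recording CSVs print doubles with `%.17g`, which round-trips IEEE
  doubles bit-exactly; manifests are schema-versioned JSON with unknown
  top-level keys preserved (forward compatibility).
* A capture within 2% of the nominal sample count loads with a warning
  (real phones drop samples); a larger deviation is an error.
* Min-max normalization rejects constant signals (`max == min`) rather
  than guessing; peak detection rejects constant signals likewise.
* ICC computation errors on zero total variance and on incomplete
  matrices; degenerate ANOVA (non-finite estimate) is an error, not NaN.
* Negative ICC estimates are clipped to 0 for reporting only.
* All writers are deterministic (stable orderings, fixed formats); the
  full simulate-write-read-analyze chain is byte-reproducible, which the
  test suite asserts.

## 7. Known limitations

* The published headline numbers (ICC values, per-method accuracy
  tables, classifiability ratios on patients) are not reproducible
  without the 52-subject clinical dataset, which was never deposited;
  the package's acceptance checks anchor on in-method worked values,
  analytic constants, and property-based suites instead.
* The speed-class boundaries and the mapping between published class
  labels and the 0-4 scale are unpublished; defaults are explicit and
  overridable but not validated against the original device.
* Time jitter in `apply_rater_effect()` requires simulation provenance;
  it re-renders the waveform and cannot be applied to externally loaded
  recordings (gain effects can).
* With the stated 5% amplitude noise, recordings whose speed sits close
  to a bin edge can still flip class occasionally; roughly one seed in
  six produces a single misgraded test case (88.9% instead of 100%) in
  the acceptance-style cohort. This is inherent to binning noisy maxima
  and is left as-is.
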