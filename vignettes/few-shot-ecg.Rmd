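---
title: "Few-shot metric learning for 12-lead ECG: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot metric learning for 12-lead ECG: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgfsl)
```

## The problem

A clinical 12-lead ECG is a 10-second, 500 Hz recording of cardiac
electrical activity. Diagnostic labels attach to whole records, but the
information lives in the individual heartbeats — a variable-length set of
QRS complexes whose shape, not count or order, carries the diagnosis. This
package implements a full pipeline for classifying such records with very
few labeled examples per class:

1. **Consensus R-peak labeling.** Six classical single-lead detectors
   (Hamilton, two-moving-average, stationary-wavelet, Christov,
   Pan–Tompkins, Engzee) run on all 12 leads; the 72 candidate streams are
   reconciled by a deterministic one-dimensional k-means.
2. **Beat segmentation.** The record is cut at midpoints between
   consecutive consensus peaks, the two edge segments are dropped, and each
   retained segment is linearly resampled to 100 samples per lead, with
   per-beat BPM and resampling-ratio metadata.
3. **A set encoder.** A compact 1-D convolutional network maps each
   12×100 beat to a 24-dimensional feature vector; max and average pooling
   over the beat set produce a 48-dimensional record summary; a fully
   connected layer yields the final 20-dimensional record embedding.
4. **Metric learning.** The encoder is trained with the triplet margin
   loss \(L(a,p,n) = \max(d(a,p) - d(a,n) + m,\ 0)\), margin \(m = 1\),
   Euclidean \(d\), so that same-class records cluster in embedding space.
   A softmax head trained with cross-entropy provides the conventional
   baseline.
5. **Prototype evaluation.** Held-out records are split into a "database"
   and a "query" half; per-class database means ("class centers") label
   each query by nearest Euclidean distance. Classifier heads (SVMs,
   random forest, k-NN, gradient boosting, a decision tree) can be fitted
   on the embeddings instead.

## The encoder in detail

The per-beat network is, in order: conv(12→24, k3, pad 1), pool(2,2),
conv(24→48, k3, pad 0), pool(2,2), conv(48→96, k3, pad 1), pool(2,2),
conv(96→2, k1). Every convolution is followed by a leaky rectifier with
slope 0.01. Sample-axis lengths run 100 → 50 → 48 → 24 → 24 → 12, so the
final two-channel map flattens (channel-major) into 24 features. The last
layer is a GoogLeNet-style 1×1 channel reduction carrying only
96 × 2 × 1 = 192 multiplicative weights.

One padding choice deserves a note. With paddings (1, 0, 0, 0) the final
map would hold 2 × 11 = 22 values, which contradicts the 24-dimensional
per-beat feature contract that the rest of the architecture (and the
48-dimensional pooled vector) requires. Padding 1 on the *third*
convolution is the unique single-padding adjustment that reconciles the
published channel plan with the 24-dimensional feature vector, so that is
what `encoder_config()` instantiates.

Set pooling is exact max/mean over the per-beat feature vectors — the set
cardinality is the adapted axis — which makes the record embedding
invariant to beat order and (for the max half) to beat duplication.
`embed_record()` returns all intermediates for inspection.

## Consensus clustering choices

The reconciliation step is deliberately deterministic and order-free:

* k is the rounded median of candidate counts over non-empty streams —
  robust to individual detectors that over- or under-detect;
* centers initialize at the k evenly spaced quantiles of the pooled,
  sorted candidate positions (no random restarts);
* within each cluster, members farther than half the refractory period
  from the cluster median are stray candidates (for example an isolated
  T-wave hit absorbed into a true beat's cluster) and contribute neither
  to the center nor to its support — without this trim a handful of
  outliers from one over-detecting stream can drag a center tens of
  milliseconds off the beat;
* clusters supported by fewer than `support_frac` (default 0.5) of the
  non-empty streams are discarded;
* surviving centers are rounded to the nearest sample and centers closer
  than the refractory period (default 0.2 s) merge, keeping the
  higher-support one.

Consensus positions are cluster means, not snapped to any lead's local
extremum: with 12 leads there is no privileged reference lead. The Lloyd
iteration is written in-package because duplicate initial centers and
singleton pools — routine with integer sample positions — must reduce
gracefully rather than error.

## BPM and resampling metadata

Each beat's segment is its midpoint-to-midpoint span, about one RR
interval, so the only segment-local rate definition available is
`bpm = 60 * fs / L` with `L` the pre-resampling segment length;
`resample_ratio = L / 100` preserves the information the fixed-length
resampling discards. Midpoints use integer floor division and all segments
are half-open `[start, end)` on a 0-based sample grid, so the retained
segments plus the two dropped edges reconstruct the record exactly.
Linear interpolation is used for resampling: deterministic, cheap, exact
on constants, and shape-preserving at the 100-sample grid.

## Training protocol

Records are split 70/15/15 into training, validation and test sets by a
seeded unstratified shuffle (stratification is not promised; the split
seed is recorded in the fit). Optimization is Adam (defaults: learning
rate 1e-3, standard moments), batch size 32, an epoch being
⌈n_train / batch⌉ sampled batches. Because pooled batches must share a
beat count, the sampler first draws the batch's QRS count from the
frequency-weighted distribution of beat counts, restricts to records with
that count, then draws triplets — anchor class from the class-frequency
distribution (a uniform option exists), positive from the anchor's class,
negative from another — redrawing the count (up to 1,000 attempts) when
the restriction cannot host a triplet. After each epoch the validation
proximity accuracy is computed with class centers from the training split
— the only accuracy available to a metric-learned model — and weights are
checkpointed on every new best. Training stops after `patience` epochs
(default 50) without improvement, or at 10,000 epochs. The softmax
baseline shares the protocol, with homogeneous-count batches of labeled
records, the class-sized head, and cross-entropy.

No semi-hard or hard triplet mining is performed; triplets are sampled
uniformly within the weighting scheme above.

## Evaluation protocol

`fsl_evaluate()` implements the database/query protocol: per class,
half the held-out records (floor) form the database and the rest the
query set; database classes are truncated to the smallest class size so
every prototype is estimated from the same number of records, while the
query half keeps its natural imbalance. "Same cardinality" is read at the
record level because class centers are record-level means. Ties in the
nearest-center rule break to the earlier catalog class; ROC scores for the
proximity classifier are negated center distances, which are monotone in
the decision rule. With two classes the metric panel reports the
designated positive class; with more, everything except overall accuracy
is macro-averaged one-vs-rest, and AUC comes from an in-package
trapezoidal sweep over score thresholds (cross-checked against an
independent ROC implementation in the tests). `crossvalidate()` repeats
the whole train/evaluate cycle five times from scratch on freshly drawn
splits and aggregates average, minimum, maximum and standard deviation
per metric; the database/query split is redrawn per repetition with that
repetition's seed. The test-subset ablation draws independent seeded
subsets (1%, 5%, 10%, 50%, 100% of the test set by default) and records a
fixed classifier's accuracy on each; subsets are independent draws, not
nested.

## The synthetic generator

`generate_record()` emulates what the downstream stages consume: 12-lead
quasi-periodic PQRST morphology with known R-peak positions,
class-dependent shape parameters, additive white noise, and variable beat
counts per 10-second record. Each beat is a sum of five Gaussian bumps
(P, Q, R, S, T: amplitude in mV, center offset in seconds relative to R,
width in seconds) on a common time base, scaled per lead by a 12-vector;
beat-to-beat intervals are drawn uniformly from the class's BPM range on
the integer sample grid. Defaults are the pipeline's study conditions:
500 Hz, 10 s records, and for the ready-made classes a 0.05 mV noise
standard deviation — a moderate noise floor relative to ~1 mV R waves.
Beats are emitted only while the full QRS support (about 0.1 s around R)
fits inside the record, so every labeled peak is a detectable beat rather
than a truncated edge artifact. Per-record seeds derive deterministically
from a root seed and the record index, so datasets reproduce
element-wise. The ready-made class specifications differ in morphology
(deep Q, inverted T, wide QRS, high voltage) while their heart-rate
ranges deliberately overlap: class identity is carried by waveform shape,
as with clinical superclasses, and overlapping rates keep beat counts
shared across classes, which the homogeneous-count samplers require.

What the generator does *not* emulate: baseline wander, powerline
interference, muscle artifact, ectopic or irregular rhythms, inter-lead
timing differences, or any physiologic correlation structure in the
noise. Passing tests on this data therefore demonstrate the pipeline's
correctness — detector localization, consensus reconciliation, exact
segmentation arithmetic, encoder/pooling algebra, optimization and
protocol bookkeeping — not clinical performance on real ECG.

## Numerical choices and degenerate inputs

* Weight initialization is uniform fan-in scaled,
  \(U(-1/\sqrt{f}, 1/\sqrt{f})\), from an explicit seed; no scheme is
  canonical for a network this small.
* The triplet gradient at zero distance (coincident embeddings) uses the
  zero subgradient.
* Pool ties take the earlier sample; nearest-center ties take the earlier
  catalog class; both keep every path deterministic.
* Detectors return empty candidate lists on all-zero leads; the consensus
  errors only when *every* stream is empty.
* All randomness flows through explicit integer seeds; derived seeds stay
  below 2^31.

## Problem sizes in the tests

The test suite exercises the full pipeline at desk scale: two to five
synthetic classes, 6–24 records per experiment, ~10 beats per record,
training runs capped at a few dozen epochs with small batches, and the
end-to-end recovery check (two disjoint morphologies, noiseless) trained
to ≥95% held-out proximity accuracy within 200 epochs. These sizes were
chosen so the whole suite runs in minutes on one CPU while still covering
every stage; the same functions scale unchanged to corpus-sized inputs.

## Known limitations

* The WFDB adapter reads and writes only signal format 16 with a shared
  `.dat`, which covers the 500 Hz clinical corpus layout this pipeline
  targets, not the full WFDB specification.
* The softmax baseline's homogeneous-count batching samples records with
  replacement within the drawn count, so very rare counts are visited
  less often than a strict epoch-partition would visit them.
* Detector implementations follow the published algorithms' transforms
  and adaptive-threshold structure but are not line-by-line ports; they
  are pluggable behind `ecg_detectors()` so alternative implementations
  can be swapped in for comparison.
* Training is plain R matrix code: fast enough for few-shot regimes
  (seconds per epoch at test sizes), not tuned for corpus-scale epochs.
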