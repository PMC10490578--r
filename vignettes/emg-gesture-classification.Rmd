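---
title: "Distance-based sEMG gesture classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-based sEMG gesture classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgdtw)
```

This vignette explains the model behind `emgdtw`, the parameters that
matter, the numerical conventions the package fixes, and what its
synthetic data can and cannot show about real recordings.

## The comparison model

A gesture recording is a `C × L` matrix of sensor intensities — `C`
channels from a ring of surface-EMG electrodes around the forearm,
sampled at a fixed rate (200 Hz is carried as metadata; the mathematics is
sample-index based). Recordings of the same gesture differ in duration and
internal pacing, so frame-by-frame comparison is meaningless. Dynamic time
warping aligns two recordings along a warping path of index pairs that
starts at the first frames, ends at the last frames, and advances by
`(1,0)`, `(0,1)` or `(1,1)` only: both endpoints are matched, time never
runs backwards, and one frame can never be skipped entirely, which keeps
the deformation physically plausible for muscle signals.

The frame cost defaults to the Euclidean norm across channels. Nothing in
the method depends on that specific choice — a per-channel
absolute-difference sum is built in, and any symmetric non-negative
function of two frames can be supplied (it then runs through an R-level
dynamic program rather than the compiled core).

Accumulated path cost is biased: against a fixed query, a short reference
accumulates fewer terms than a long one. The package therefore divides
every DTW cost by `sqrt(N² + M²)`, the diagonal of the `N × M` cost
matrix, rescaling each comparison as if it were computed on a unit-square
grid. All classification, condensing and distribution machinery operates
on this normalized distance.

The normalized distance is symmetric and zero for identical series, but it
satisfies no triangle inequality — the space is non-metric, which is why
cluster structure is described by distance *distributions* rather than by
geometric embeddings.

## Classification and rejection

Classification is nearest-neighbor: a query takes the label of its closest
reference. `k = 1` is the package-wide default — with condensed references
there is only one entry per gesture, and using the same `k` for all three
reference modes keeps them comparable. For uncondensed references a
general `k` is supported; vote ties are resolved by the smaller summed
distance, then by label order.

Open-set rejection folds naturally into the distance framework: the query
must be closer than a cutoff `d_k` to the cluster it would join, otherwise
it is rejected rather than classified. Cutoffs are taken as percentiles of
the per-gesture intracluster distance distribution `δ_k` of the reference
samples, so "the 100th percentile" includes the furthest outlier of the
cluster and tightening the percentile tightens acceptance. Three metrics
summarize a batch evaluation: total accuracy `α` (correct / all),
classification accuracy `β` (correct / accepted, undefined and reported
as `NA` when nothing is accepted), and rejection rate `γ` (rejected /
all), with `α = β(1 − γ)` whenever `β` is defined. Because percentiles
are monotone in `p` and acceptance sets are nested, `γ` is non-increasing
along a percentile sweep — a structural fact, not an empirical one, and
the test suite asserts it as such.

For condensed reference sets the cutoff distributions are still the
pairwise `δ_k` of the reference samples *before* condensation: the sweep
is thereby defined uniformly across modes, and the asymmetry — the same
percentile is a tighter bound when distances are measured from a
center-like reference than from the nearest of many stored samples — is a
property of the modes, visible in the sweep output rather than hidden in
the cutoff definition. The alternative reading (cutoffs from
member-to-reference distances) is available via
`cutoff_source = "to_reference"`.

## Condensing

Both condensing methods compress a gesture cluster to one series. The
one-step method selects the *representative*: the member whose median
distance to all other members is smallest. Median ties go to the earliest
member in input order, and the median of an even count is the mean of the
two central values — both fixed so the choice is reproducible.

The two-step method refines the representative by DTW barycenter
averaging: every member is aligned to the current barycenter, each
barycenter frame is replaced by the mean of all member frames associated
with it along the optimal paths, and the process repeats. The alignment
inside this loop uses the squared-Euclidean frame cost: the frame mean is
exactly the minimizer of the summed squared deviations under fixed
associations, so each averaging step, and each re-alignment, can only
lower the within-cluster sum of squares. That descent is exposed as the
`objective_trace` attribute and asserted per-iteration in the tests. With
the plain Euclidean cost, the mean update would not minimize the aligned
cost and the objective could oscillate. Classification distances are
unaffected — condensed references are compared to queries with the same
normalized Euclidean-cost DTW as everything else.

The barycenter keeps the representative's length throughout, the
iteration cap is 30 and the stopping tolerance `1e-6` on the maximum
absolute frame change; on the synthetic clusters used in the tests the
loop converges in a handful of iterations, and a cluster of identical
series is returned unchanged after one.

Deterministic warping paths matter here: when predecessors of a dynamic
programming cell tie, the implementation prefers the diagonal step, then
advancing in the first series, then the second, making barycenter
associations (and therefore condensed references) reproducible.

## Cluster distributions and separability

For clusters `G_k` and `G_l`, `δ_k` holds the distance of every unordered
pair within `G_k` (`n(n−1)/2` values) and `Δ_{k,l}` the distance of every
cross pair (`n·m` values). Upper percentiles of `δ_k` read as cluster
diameter, lower percentiles of `Δ_{k,l}` as border-to-border distance.
The separability report tabulates the margin
`p10(Δ_{k,l}) − p90(δ_k)` for every ordered pair — both directions,
because `δ_k ≠ δ_l` — and flags non-positive margins as weakly separated.

Percentiles are computed by linear interpolation between order statistics
(`stats::quantile` type 7), so `p = 0` is the minimum, `p = 100` the
maximum. Any fixed convention would do; fixing one keeps cutoff sweeps
reproducible.

Gesture-subset selection searches all size-`n` subsets exhaustively
(pools are small) for the one maximizing the minimum pairwise margin. The
objective is deliberately *maximin*: the underlying idea — prefer subsets
whose worst-separated pair is as well separated as possible — can also be
written as minimizing the largest violation `90th(δ) − 10th(Δ)`, and the
two readings coincide; the package implements the maximin form and breaks
ties toward the lexicographically first subset.

## Inter-participant normalization

Per-sensor maximum signal strengths are estimated from powergrip
(maximum-voluntary-contraction) recordings: each recording is split into
three equal thirds and only the center third — frames with 0-based
indices in `[floor(L/3), floor(2L/3))` — is kept, excluding the ramp-up
and the tiring-out phases; the kept frames are averaged over time and
recordings per channel. Factors are computed per subject from that
subject's own powergrips, and non-positive factors are rejected rather
than clamped, since they indicate a degenerate recording. Batch
normalization divides by the mean factor (a pure gain correction; for the
Euclidean frame cost it scales all DTW distances by exactly the inverse
factor), sensor normalization divides each channel by its own factor;
the two coincide when all factors are equal.

The package takes no position on whether this suffices to transfer
reference data between real participants — the comparison machinery
(within-subject `δ` vs. cross-subject `Δ` per gesture) is provided, and
the tests verify the recovery case that *must* work: twin subjects
differing only by a known global gain are brought into overlap by batch
normalization with estimated factors.

## The synthetic generator

Real sEMG study recordings are typically private, so the generator stands
in for them, emulating structure rather than electrophysiology:

* **Templates** — per gesture, each channel's activation envelope is a sum
  of 1–3 Gaussian bumps with randomized center, width and height.
  Templates derive deterministically from a dedicated template seed, so
  different "subjects" can share a gesture vocabulary.
* **Sample variation** — each sample rescales the template duration
  uniformly within a time-jitter fraction (default 0.15, so lengths vary
  sample to sample), scales amplitude within a jitter fraction (default
  0.1), and adds i.i.d. zero-mean Gaussian sensor noise per channel and
  frame (default σ = 0.05 against envelope peaks of order 1).
* **Seatings** — each re-seating applies a persistent fractional rotation
  of the channel ring (up to 0.5 sensor positions by default),
  interpolating between adjacent sensors — a documented stand-in for
  physical electrode displacement.
* **Subjects** — a global gain on the complete recording (signal plus
  noise), so two subjects generated from the same template seed differ
  only by that amplitude factor; the per-channel MVC profile belongs to
  the subject's physiology and follows the template seed as well.
* **Powergrips** — near-saturation plateaus (ramp-up third, plateau,
  ramp-down third) at per-channel MVC levels drawn once per subject,
  defaults: 3 recordings of 300 frames at twice the envelope amplitude.

Defaults mirror the study layout the package targets: 7 gestures,
8 channels at 200 Hz, 100 samples per gesture in a single-seating dataset
or 5 seatings × 20 samples in the multi-seating one, gesture lengths of
80–120 frames (0.4–0.6 s hand gestures).

What passing tests on this data do show: the implementation's structural
guarantees (oracle-exact DTW, metric identities, monotone rejection,
barycenter descent, normalization recovery) and the *mechanism* linking
positive pairwise margins to perfect 1-NN accuracy. What they do not
show: that real gestures of real participants are separable — real sEMG
has non-Gaussian, activity-dependent noise, correlated channels,
within-subject drift and execution variability that no smooth-bump model
captures, and the published accuracy of the approach on real data cannot
be reproduced without the (private) recordings.

The noise-vs-distance experiment follows the same logic at the smallest
scale: two independent noise patterns on the same base curve are compared
1000 times per noise level. The base curve is a unit-height Gaussian bump
(center 5, width 2, on a 0–10 grid of 128 frames); its exact functional
family is immaterial — any smooth curve yields the two tested properties,
exactly zero distance at zero noise and near-linear growth of the mean
distance in σ. This experiment uses raw (unnormalized) single-channel DTW
by default, as a property of the distance itself rather than of the
classification pipeline.

## Numerical and engineering choices

* The accumulated-cost matrix is computed in full, in C++, with no band
  constraint or pruning — at a few hundred frames per recording this is
  milliseconds per pair, and exactness keeps the oracle comparison sharp.
  The test oracle enumerates every admissible warping path in R and is
  completely independent of the dynamic program.
* Indexing is 1-based at the R surface; returned warping paths are
  `L × 2` matrices of 1-based index pairs validated against the step and
  endpoint rules.
* Splits: the random strategy is stratified per gesture (reference count
  `round(fraction · n)` per label) and driven by one explicit seed; the
  leave-days-out strategy holds complete seatings out. Sweeps compute the
  test-to-reference distances once per split and mode and reuse them
  across the whole percentile grid.
* Aggregation across split repeats reports the mean and the standard
  error (sample standard deviation / √repeats).
* Degenerate inputs fail loudly: empty clusters, non-finite values,
  channel mismatches, cutoffs missing a label, out-of-range percentiles
  and undersized powergrip recordings are all errors, not warnings.
* Test and acceptance runs use deliberately moderate problem sizes —
  e.g. 700-sample multi-seating datasets for the sweep checks, 500 series
  pairs for the oracle comparison, 200 repetitions per noise level —
  chosen to exercise the study-shaped code paths while keeping the full
  suite around a minute.

## Known limitations

* DTW with the restricted step set is exact but quadratic per pair; no
  FastDTW-style approximation or pruning is provided.
* One prototype per cluster: the condensing methods do not produce
  multi-prototype or weighted representations.
* The subset selector is exhaustive and intended for pools up to ~15
  gestures.
* No streaming segmentation: queries are assumed to be pre-segmented
  recordings, not a live data stream.
* The generator's seating model (channel-ring rotation) and noise model
  (i.i.d. Gaussian) are deliberate simplifications; conclusions about
  real electrode shift or real sensor noise require real data.
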