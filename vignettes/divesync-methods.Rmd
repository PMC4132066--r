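---
title: "Methods: detecting at-sea associations and synchronous diving"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting at-sea associations and synchronous diving}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divesync)
```

## The problem

Central-place foraging seabirds such as little penguins (*Eudyptula
minor*) depart from and return to a colony on each foraging trip.  When
several individuals carry GPS loggers (nominally one fix per 2 min) and
time-depth recorders (TDR, one depth sample per 4 s) on the same day,
their joint records let us ask whether birds travel, dive, and even
time individual dives together at sea.  `divesync` turns raw fix and
depth tables into per-trip association categories and group-level
statistics.

The pipeline runs: speed filtering, trip segmentation, regular-grid
interpolation, zero-offset correction, dive detection, bout analysis,
dyadic episode detection with rafting exclusion, synchronous-dive
matching, classification, and statistics.

## Track processing

**Speed filter.** A forward pass drops any fix whose straight-line
(haversine, sphere radius 6,371 km) speed from the last retained fix is
strictly greater than `vmax` (default 2 m s^-1^; penguins do not sustain
faster travel, so faster apparent movement is GPS error).  A
single-ended pass is used rather than the two-ended root-mean-square
variant; only the threshold is essential and both are idempotent.

**Trips.** "At the colony" means within `colony_radius_m` (default
150 m — above GPS error, below the rafting buffer; the operational
departure/return rule is this package's choice, as the field definition
is only "the time between departure from and return to the colony").  A
trip runs from the last inside fix before an excursion to the first
inside fix after it; excursions that never return are flagged
incomplete and excluded.

**Interpolation.** Latitude and longitude are interpolated linearly
onto a regular grid (default 60 s, finer than the 2-min sampling so
dyadic-distance discretisation error is far below the 500-m association
radius).  The default grid is anchored at departure; the pipeline uses
epoch-anchored grids (times divisible by the step) so that two birds'
tracks share grid instants.  Interpolating raw coordinates rather than
projected ones is acceptable at trip scales of tens of km at 38°S and
is a documented approximation.

## Dive and bout analysis

**Zero-offset correction.** Pressure sensors drift.  The record is cut
into 300-s windows; each window's 2% depth quantile is its surface
baseline; baselines are interpolated between window centres, subtracted,
and negatives clamped to zero.  This rolling-quantile scheme is the
package's choice of ZOC filter.

**Dives.** A dive is a maximal run of samples at or below the 1-m
threshold (positive down); an n-sample run lasts n × interval seconds.
The threshold applies both to dive boundaries and to the maximum depth,
so sub-metre excursions never count.

**Bout-ending criterion.** Surface behaviour mixes a fast within-bout
process and a slow between-bout process.  Absolute sequential
differences of successive post-dive intervals are modelled as a
two-process exponential mixture

$$f(t) = p\,\lambda_f e^{-\lambda_f t} + (1-p)\,\lambda_s e^{-\lambda_s t},
\qquad \lambda_f > \lambda_s > 0,$$

fitted by maximum likelihood (box-constrained quasi-Newton from a
median-split moment start plus five deterministic jittered restarts; the
likelihood is multimodal at small n).  The bout-ending criterion is the
crossing point of the two weighted densities,

$$\mathrm{BEC} = \frac{\log\!\big(p\lambda_f / ((1-p)\lambda_s)\big)}
{\lambda_f - \lambda_s}.$$

Two numerical choices matter:

* **Interval censoring.** On a 4-s sampling grid a third of the
  differences can tie at exactly zero, and the continuous-density MLE
  then diverges (λ~f~ → ∞, BEC → 0).  With `resolution > 0` the fit
  scores $P(T \in [x - w/2,\, x + w/2])$ instead of the density; the
  pipeline passes the TDR interval automatically.  For continuous data
  the two forms agree.
* **Ascent-only assignment.** Differencing a sequence turns each long
  between-bout interval into *two* large differences (the jump up and
  the drop back), so thresholding absolute differences isolates every
  bout's last dive.  Assignment therefore attaches to each dive its
  pre-dive surface interval and starts a new bout only when that value
  *rises* by at least the BEC.  One BEC is fitted per trip by default
  (`pooled_bec = TRUE` pools all trips).

Bout horizontal distance is the interpolated-track path length between
the bout's first dive start and last dive end; a single-dive bout gets
its bracketing grid segment.

## Association analysis

Parameters (all in `assoc_params()`): radius 500 m (half the ~1-km mean
bout horizontal distance, so partners working the same patch stay
inside it), minimum episode duration 744 s (one mean bout duration,
12.4 min — the "minimum unit period"), synchrony window 4 s (one TDR
sample), rafting buffer 1,000 m, merge gap 120 s (one GPS interval).
`min_duration` and the radius can also be re-derived from the current
data set (mean bout duration; half the mean bout distance).

* **Episodes** are maximal runs of shared grid instants with dyadic
  distance ≤ radius (boundary inclusive, matching "within"); runs
  separated by gaps ≤ merge gap merge; runs shorter than the minimum
  unit are discarded.
* **Rafting** — surface aggregation near the colony before landfall —
  is not at-sea association.  Episode portions where *both* birds are
  within the buffer are trimmed automatically (the field practice was
  visual inspection) and survivors are re-checked against the minimum
  duration.  Trimmed time is reported for audit.
* **Synchronous dives** are matched greedily in time order, one-to-one,
  |Δstart| ≤ 4 s inclusive, both starts inside a shared episode,
  nearest partner dive first with ties to the earlier dive.  Greedy
  matching prevents one dive from joining several pairs; in contrived
  lattices it can be smaller than the maximum matching, which is
  accepted for determinism.
* **Classification.** Commuting windows are the trip segments before
  the first and after the last bout (trips without bouts are
  all-commute).  The exclusive label is the highest degree attained:
  1 no episodes; 2 episodes only while commuting, no dives in them;
  3a at-sea episodes without focal dives; 3b focal dives during
  episodes; 3c at least one synchronous pair.  Membership flags are
  reported alongside because published category counts can overlap.
  Total association time uses the *union* of episode intervals so that
  simultaneous partners are not double-counted and percentages stay in
  [0, 100].

## Group statistics

The Mantel statistic is the Pearson correlation of the lower triangles
of the nest-distance and pairwise association-time matrices; the null
distribution permutes rows and columns of one matrix jointly, p
two-sided with the +1 correction.  Dyads never simultaneously at sea
are masked (NA) by default; masking is configurable.  The sex effect on
total association time uses a Mann–Whitney U with midrank ties — exact
by rank-sum enumeration (dynamic programming, valid under ties) when
n₁n₂ ≤ 400, else a tie-corrected normal approximation with continuity
correction.  All tests are two-sided; the permutation count (default
9,999; 999 in the pipeline) and seed are recorded in the output.

## The synthetic world

`simulate_deployment()` generates a deployment day with ground truth:

* **Trips**: duration N(14.8, 4.1²) h truncated to 6–24 h; out-and-back
  correlated random walk (AR(1) heading, SD 0.08 rad per 2-min step)
  that retraces its outbound path, ends with a ~25-min rafting segment
  400 m off the colony, and lands at the nest through a speed-safe ramp.
* **Dives**: lognormal durations (median 28 s), lognormal depths
  clipped to 1.1–26.5 m, triangular depth profiles; within-bout surface
  intervals Exp(mean 20 s) truncated to [16, 80] s; between-bout gaps
  600 s + Exp(mean 300 s); bouts sized so realised mean duration is the
  744-s target; during-bout ground speed 1.37 m s^-1^ calibrated so a
  mean bout covers 0.99 km through the measurement chain (edge grid
  cells travel at commute speed, so the naive 744 s × 1.33 m s^-1^
  undershoots).
* **Pairs**: both members share the base path; the partner is offset by
  a fixed-direction vector whose magnitude ramps (over 70 min, keeping
  speeds under the filter) between 2.2 km and the planned episode
  distance (300 m).  Partner dives inside planned episodes copy the
  focal dives at a constant stagger — 0/4 s for synchronous plans,
  12 s for asynchronous — and the partner never dives independently
  while inside the association radius: independent dives on a shared
  4-s grid would create *coincidental* synchrony and corrupt the labels.
  The 16-s post-dive floor guarantees the 12-s stagger can never land
  within 4 s of the focal's next dive.
* **Noise**: 7% of fixes displaced 500–800 m (forcing > 2 m s^-1^),
  7-m GPS jitter, 0.1–1 m depth-sensor drift plus measurement noise.

Ground truth is derived from the *clean* series: episode intervals by
running the radius/merge/duration/rafting rules on the noise-free
tracks, synchrony from the planned staggers, classification from those
components.  Truth is therefore independent of the estimation stages
(filtering, ZOC, dive detection, BEC fitting, noisy interpolation) that
the pipeline must get right.

What the generator does **not** emulate: prey fields and area-restricted
search, tidal drift, heteroscedastic GPS error, sexual dimorphism in
diving, day/night dive structure beyond the rafting segment, and
groups larger than coupled dyads.  A green end-to-end test therefore
establishes that the detection chain recovers a *known* spatiotemporal
association structure under realistic sampling and noise — not that the
biological world is this simple.

## Degenerate inputs and tie-breaks

Duplicated timestamps keep the first row; single-fix tracks pass the
filter with a warning; trips that never leave or never return yield
zero trips with a warning/flag; an all-equal difference vector or a fit
with $p\lambda_f \le (1-p)\lambda_s$ (BEC ≤ 0) is an error; distance
exactly at the radius is inside; |Δ| exactly 4 s is synchronous; speed
exactly 2 m s^-1^ is retained.

## Known limitations

Interpolation in unprojected coordinates; one BEC per trip can be
unstable below ~30 differences (warned, with the pooled fit as
fallback); the greedy synchrony matching is deterministic but not
guaranteed maximum; classification of trips without depth records is
capped at group 3a; the Mantel masking rule for never-overlapping dyads
is a modelling choice.
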