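---
title: "Gait recognition by directional histograms: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait recognition by directional histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitprint)
library(dplyr)
```

## The model

`gaitprint` treats walking as a behavioural biometric read from the two
tri-axial motion sensors every modern smartphone carries: the
accelerometer (m/s², gravity included, as the calibrated Android sensors
report it) and the gyroscope (rad/s). The recogniser never models gait
cycles explicitly. Instead it summarises a fixed-duration window by the
*distribution of directions* in which the sensor vector points.

For a sample $(x_i, y_i, z_i)$ with magnitude
$m_i = \sqrt{x_i^2 + y_i^2 + z_i^2}$, each axis is encoded as

$$X_i = 1 + \arcsin(x_i / m_i),$$

and analogously $Y_i$, $Z_i$. Dividing by the magnitude discards signal
energy, so the encoding is invariant to positive rescaling (units, sensor
gain, overall vigour of the walk); the arcsine spreads the ratio
smoothly, and the $+1$ shift keeps all values positive. The output range
is therefore $[1 - \pi/2,\; 1 + \pi/2]$: we implement the printed formula
literally and treat the occasional description of arcsine output as
"between $-1$ and $1$" as prose imprecision — the function's true range
is $[-\pi/2, \pi/2]$, and clipping or rescaling would silently distort
the histograms.

Per axis, the transformed values of one window are binned into an
equal-width histogram over the transform's *full* range. Fixing the bin
range globally (rather than per window) is what makes histograms from
different windows, users and devices comparable; a data-driven range
would break every cross-sample comparison. Two histograms are compared by
intersection:

$$\mathrm{similarity}(H_1, H_2) =
  \frac{\sum_{i=1}^{n}\min(H_{1i}, H_{2i})}{\sum_{i=1}^{n} H_{2i}},$$

the shared mass normalised by the reference total. The formula is
asymmetric; we fix the convention that the *enrolled* (database)
histogram is always the denominator, and record that orientation in the
score object. We build three one-dimensional histograms per sensor and
average their scores rather than one joint three-dimensional histogram:
the per-axis reading follows the method's own description, keeps memory
at $3B$ rather than $B^3$ counts, and is what the bin-sweep experiment
presupposes. With both sensors recorded over the same window the counts
are equal, so raw counts compare directly; windows of differing retained
length are rescaled to a common per-axis total before the formula is
applied, which keeps scores in $[0, 1]$. Accelerometer and gyroscope
scores are fused by a weighted average, equal weights by default; the
weight pair `c(1, 0)` degenerates cleanly to accelerometer-only
operation.

## Recognition tasks

**Classification** scores a probe against every gallery sample regardless
of user and returns the user of the maximum (ties broken by lowest
gallery index, for determinism).

**Verification** builds a per-user threshold from the enrolment set
itself: the minimum score over all ordered pairs of enrolment samples
(ordered, because the intersection is asymmetric — this yields the most
conservative minimum), multiplied by an *error factor* of 0.95. The
factor concedes that enrolment samples are typically recorded in more
homogeneous conditions than later genuine attempts, which may therefore
score slightly below the worst intra-enrolment pair. A probe is accepted
when its mean score against the enrolment set reaches the threshold.
Decisions aggregate by majority vote over an odd number of samples per
attempt (default three); an even split rejects — the fail-safe posture
for an authentication gate. FAR, FRR and accuracy follow the standard
definitions; when a rate's denominator is zero it is reported as 0 with
an explicit `*_undefined` flag rather than NaN.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_bins` | 20 | histogram bins per axis; about a sixth of the 125 readings in a 5-s window at 25 Hz. `sweep_bins()` (10–40, step 3) explores the trade-off: too few bins blur users together, too many fragment mass into noise-dominated bins. |
| `error_factor` | 0.95 | scales the intra-enrolment minimum into the acceptance threshold; lower values admit more (monotonically — acceptances can only grow as it decreases). |
| `weights` | (0.5, 0.5) | sensor fusion weights; the plain average of the two sensor scores. |
| `magnitude_epsilon` | 1e-9 | samples with magnitude below this have no defined direction and are dropped (and counted) instead of being assigned an arbitrary value. |
| `k` | 5 | placement clusters, one per body position (torso, both arms, both legs); 8 and 10 are sensible alternatives when clothing splits positions further. |
| `failure_limit` | 3 | consecutive failed validations before the session policy locks the device. |

## Placement clustering

Samples recorded at different body positions produce systematically
different direction distributions. We cluster gallery samples under the
distance $d(i,j) = 1 - \bar{s}(i,j)$, where $\bar{s}$ is the mean of the
two orientations of the intersection score — symmetrisation is required
because a dissimilarity must be symmetric. Under this non-Euclidean
distance, mean centroids are undefined, so the "k-means on similarity
distances" idea is realised as **k-medoids**: seeded random medoid
initialisation, then alternating nearest-medoid assignment and
within-cluster medoid updates until the assignment stabilises, best of
`n_restarts` seeded starts by total within-cluster distance. The
objective is non-increasing across iterations and the procedure is
deterministic given the seed.

Verification can be *routed* through the clustering: the probe joins the
cluster of its nearest medoid and is verified only against the claimed
user's enrolment samples inside that cluster, with a per-cluster
threshold. If the claimed user has fewer than two samples there, the
attempt is rejected with a `"no enrolment in cluster"` flag — failing
safe rather than falling back to a cross-placement comparison.

One design point deserves honesty. On mixed-placement enrolments the
*unclustered* verifier's threshold collapses: the minimum over all
ordered enrolment pairs includes cross-placement pairs with very low
similarity, so the threshold drops far below any genuine or impostor
mean score and the verifier accepts nearly everything (FRR near 0, FAR
near 1). Cluster routing restores discrimination from both sides: probes
are compared among like-placed samples (genuine mean scores rise) and
thresholds are computed among like-placed pairs (impostors are cut off).
Our seeded experiments show exactly this signature — FAR dropping from
~0.9 to ~0.1 and verification accuracy from ~0.3 to ~0.9 on a
two-placement cohort — rather than a reduction in FRR, which is already
zero without clustering. The tests assert this truthful contrast.

## The session policy

Continuous authentication only makes sense while the user is actually
walking, so the state machine is gated by activity-recognition events
(still, tilting, walking, running, on bicycle, in vehicle, unknown).
During enrolment, a valid activity starts the recording alarm and an
invalid one cancels it, discarding any sample in progress — a sample
spanning an activity transition never enters the model. During
validation, an alarm tick under an invalid activity counts as a failed
attempt (this tolerates ordinary interruptions — waiting at a crossing,
boarding a bus — up to the limit), a tick under a valid activity records
and scores a sample, and reaching `failure_limit` consecutive failures
locks the device. Locking is absorbing. We resolve two under-specified
points explicitly: the failure counter resets only on a successful
validation (both choices are defensible; reset-on-success matches the
intended "turned off at the next successful validation" behaviour and is
configurable in code), and invalid-activity ticks share one counter with
failed-score attempts. Running is excluded from the valid set by default
because the gait model is walking-trained, but it can be added.

## The synthetic generator

The generator exists so the entire pipeline can be exercised without any
recorded data. Each walker is a truncated Fourier series on their step
frequency (2–3 harmonics by default) — the simplest signal with the
repetitive structure that makes walking the method's best case — with:

- per-axis amplitudes and phase offsets (what mostly distinguishes users
  to a *direction-distribution* recogniser; step frequency alone barely
  changes a value histogram),
- gravity riding on one accelerometer axis,
- a device-pose rotation (three Euler angles) applied to both sensors,
  with per-placement pose offsets and left-side placements mirroring the
  lateral axis — which reproduces the empirical tendency of left/right
  limb recordings to co-cluster,
- the gyroscope leading by a quarter phase with its own amplitudes,
- additive Gaussian noise in the device frame.

Cohort defaults mirror the reference recording shape: 8 walkers × 60
windows of 5 s at 25 Hz. `separation` scales all between-user profile
differences (0 collapses every user onto one profile — the recogniser's
worst case; 1 spreads step frequency over ≈1.4–2.5 Hz and
amplitudes/phases over plausible inter-person ranges). Within-user
variation comes from per-sample jitter of frequency (±2%), phase and
amplitude (±5%), plus fresh noise (0.6 m/s² accelerometer, 0.12 rad/s
gyroscope — a deliberately generous allowance for soft-tissue and
placement jitter at a 25-Hz sampling rate). These defaults were fixed
once as the simulated study conditions.

What the generator does *not* emulate: gait asymmetry and double-support
phases, ground-reaction transients, footwear/fatigue/injury effects,
irregular Android timestamp spacing, and sensor bias or drift. Passing
tests on synthetic cohorts therefore demonstrate the pipeline's
correctness and its behaviour under controlled separation and noise —
not field performance on real walkers, which the original recordings
place around 90–100% classification accuracy for walking activities and
a few percent FAR/FRR.

## Numerical and degenerate-input choices

- Bins are half-open $[lo, hi)$ except the last, which is closed, so the
  transform's exact maximum (a sample pointing straight along an axis,
  e.g. gravity-only) is counted, not dropped.
- Direction ratios are clamped to $[-1, 1]$ before the arcsine to absorb
  floating-point overshoot in $x_i / m_i$.
- Zero-magnitude samples (below `magnitude_epsilon`) are dropped and
  counted; a window whose samples are *all* degenerate raises an error
  rather than producing an empty histogram.
- A zero-total reference axis raises rather than dividing by zero.
- Classification ties break to the lowest gallery index; k-medoids
  assignment ties break to the lowest cluster index; both keep results
  deterministic.
- All stochastic components (generator, k-medoids restarts) are driven
  by explicit seeds through `withr::with_seed`, so no call disturbs the
  caller's RNG state.

## Problem sizes used in the test-suite and acceptance runs

The acceptance runs use the full reference shape (8 × 60 windows) for
classification and verification; the bin sweep runs on a 4 × 12 cohort
and the clustering checks on a 3 × 10 × 2-placement cohort, sizes at
which every property being asserted is already fully expressed. Unit
tests use smaller cohorts (2–4 users, 4–12 samples) chosen the same way.

## Known limitations

- The method is placement-sensitive by construction; mixed-placement
  enrolment without clustering degrades to a non-discriminative
  threshold (see above).
- Scale invariance cuts both ways: two walkers whose motion differs
  mainly in vigour, not direction, are hard to separate.
- No equal-error-rate sweep is provided; the verifier operates at the
  single enrolment-derived threshold.
- The session policy simulates activity events; it does not bind to any
  real activity-recognition service.
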