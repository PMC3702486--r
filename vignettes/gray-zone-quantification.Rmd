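---
title: "Quantifying infarct heterogeneity from late-enhancement cardiac MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infarct heterogeneity from late-enhancement cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mclegz)
```

## The model

Late-gadolinium-enhancement (LGE) imaging distinguishes infarcted from
viable myocardium because gadolinium accumulates in scar, shortening the
apparent longitudinal relaxation time. After an inversion pulse with a
continuous SSFP readout, the voxel signal recovers as

$$S(t) = A - B\,e^{-t/T_1^*},$$

with steady-state amplitude $A$, inversion amplitude $B$ ($B = 2A$ for an
ideal inversion), and apparent relaxation time $T_1^*$. A conventional
IR-FGRE acquisition samples this curve once, at the TI that nulls healthy
myocardium; a multi-contrast (MCLE) acquisition samples it at every
cardiac phase, so $A$ and $T_1^*$ can be estimated per voxel.

Two segmentation routes are implemented.

**FWHM route.** From a remote healthy-myocardium ROI we take
`Peak_remote`; the candidate infarct is every myocardial voxel brighter
than it, `Peak_infarct` its maximum. Core is
$SI > 0.5\,\mathrm{Peak}_{infarct}$, gray zone is
$\mathrm{Peak}_{remote} < SI \le 0.5\,\mathrm{Peak}_{infarct}$. Two
boundary conventions are deliberate and switchable: signal exactly at the
half-maximum goes to the gray zone (the core inequality is strict), and
signal exactly at `Peak_remote` stays healthy. `SD_remote` is computed
(sample SD, ddof = 1) and reported but enters no threshold.

**MCLE route.** $(T_1^*, A)$ pairs of valid-fit voxels are z-scored and
clustered by fuzzy C-means with $k = 3$, fuzzifier $m = 2$, Euclidean
distance, minimizing
$J = \sum_i \sum_k u_{ik}^m \lVert x_i - c_k \rVert^2$. Clusters are
named by physics: blood has the largest steady-state amplitude; of the
remaining two, infarct has the shorter $T_1^*$. Within the myocardium,
core is infarct membership $> 0.75$, the gray zone is membership in
$[0.25, 0.75]$ (both bounds inclusive), healthy below. The banded
membership is the *infarct* one; when blood membership is negligible
inside the wall this is equivalent to banding the healthy membership. A
blood-membership override ($u_{blood} > 0.5 \Rightarrow$ blood) guards
against cavity partial-volume voxels inflating the core. Isolated
infarct-classified components smaller than 2 voxels whose entire
face-neighborhood is healthy are relabeled healthy — an automated
surrogate for the manual cleanup used in practice.

Masses use a myocardial density of 1.05 g/cm³ (standard CMR convention);
percentages are normalized to LV myocardial mass. Papillary muscles are
excluded from the wall for the percentages and scored separately: a PM is
involved when at least half its voxels classify as core or gray zone
(classification route) or when its mean signal reaches the core cutoff
$0.5\,\mathrm{Peak}_{infarct}$ (intensity route, operationalizing
"enhancement the same or similar to the adjacent infarct", which has no
printed quantitative definition). The PM-MI score is the count of
involved muscles (0, 1, 2).

## Relaxometry fitting

The three-parameter fit exploits that $S(t)$ is linear in $(A, B)$ for
fixed $T_1^*$: a 40-point log-spaced $T_1^*$ grid with exact profiled
linear solves locates the basin, Brent refinement polishes the profiled
objective, and a bounded Levenberg–Marquardt step over all three
parameters finishes. The best objective of the stages is kept, so
refinement can never worsen the grid start. Voxels with numerically
constant signal ($B$ unidentifiable), non-finite results, negative $A$,
or $T_1^*$ outside [10, 5000] ms are flagged invalid. We fit
$(A, B, T_1^*)$ rather than fixing $B = 2A$ because acquisition cannot
guarantee ideal inversion; for magnitude input an optional polarity
restoration tries each possible sign flip of the earliest frames and
keeps the lowest-residual fit.

Frame selection: `select_frames()` defaults to the last $k = 8$ frames —
in a real phase-resolved acquisition the late-diastolic frames are the
ones with minimal cardiac motion. The *pipeline* default, however, fits
all 20 frames: phantom frames are co-registered by construction, so the
motion rationale does not apply, and restricting to the last 8 TIs of a
75–1025 ms cycle leaves a narrow late-TI window on which the
three-parameter fit is badly conditioned (at 2% noise the fitted $T_1^*$
interquartile range spans hundreds of milliseconds, versus about ±3%
with all frames). Users analyzing real series should set `frames_k` to
the motion-free frame count.

## The phantom and what it does (not) emulate

`phantom_spec()` describes a short-axis LV: a 64×64×3 grid at 1.5 mm
in-plane and 8 mm slices (typical LGE resolution), an annular myocardium
(endocardial radius 20 mm, epicardial 30 mm), a 90° transmural infarct
wedge, a 3 mm gray-zone rim (every non-core myocardial voxel within 3 mm
of a core voxel center), and two 3.5 mm papillary muscles inside the
cavity, one infarcted by default. Voxels are classified by their
1-based-index centers at $((i-0.5)\,dx, (j-0.5)\,dy)$.

The tissue table is a free parameter set ordered by post-gadolinium
physics — blood (A = 120, $T_1^*$ = 250 ms), core (100, 320 ms), healthy
(80, 600 ms) — chosen so infarct and blood recover fast while nulled
healthy myocardium recovers slowest; no published tissue-level values
exist for these quantities, so they are conventions, not measurements.
Gray-zone ground truth is a 50/50 linear mix of core and healthy
parameters (configurable), reflecting that the gray zone is defined
operationally, not biophysically. Noise is additive Gaussian (default
sd 2.4 a.u., i.e. 2% of the blood amplitude), applied per voxel per
frame; magnitude reconstruction is off by default so signed signals
reach the fitter. The default TI grid is 20 frames at 75–1025 ms in
50 ms steps, one cardiac cycle of a phase-resolved acquisition.

The phantom deliberately omits cardiac motion, partial-volume
point-spread, Rician noise statistics, surface-coil shading, and
k-space/pulse-sequence effects. Passing tests therefore demonstrate the
*analysis* — fitting, clustering, thresholding, bookkeeping — not
robustness to acquisition physics; on real data the fit window, polarity
handling, and despeckling matter more than they do here.

The cohort simulator draws per-group continuous measures from truncated
normals at the group means/SDs of a two-group ICD cohort and PM scores
from categorical distributions whose frequencies ((0, 4, 8)/12 and
(5, 3, 5)/13) reproduce the group score summaries 1.67 ± 0.49 and
1.00 ± 0.93 exactly as sample statistics. Stroke volume and EDV/ESV are
drawn independently per the table rows rather than derived, so the
SV = EDV − ESV identity holds only in expectation; totals, by contrast,
are recomputed as core + gray zone so that identity is exact.

## Statistics

Group comparisons use the pooled-variance two-sided Student *t*
(`t_test_summary()` from printed mean/SD/n, `t_test_subjects()` from raw
values — algebraically identical), with sample SDs (ddof = 1) matching
the mean ± SD convention of clinical tables. Degenerate zero-variance
inputs are handled explicitly. Categorical comparisons use the Fisher
exact test under the probability-mass two-sided convention (sum of
hypergeometric probabilities no larger than the observed table's);
`stats::fisher.test` implements exactly this rule and is verified in the
test suite against exhaustive enumeration for every 2×2 table with total
≤ 25. Recomputing published p-values from rounded one-decimal summaries
carries an input-rounding uncertainty of roughly ±0.005, which is the
tolerance used throughout; one published gray-zone p-value (0.046)
recomputes to ≈ 0.050 from the rounded summaries and is documented as
such rather than forced.

## Numerical choices and tie-breaks

* FCM: seeded k-means++-style initialization, 5 restarts, best objective
  kept; convergence at relative objective change ≤ 1e-5 or 300
  iterations; a point coinciding with a centroid takes membership 1
  there (split among ties). Cluster-naming ties (equal amplitudes, equal
  $T_1^*$) break toward shorter $T_1^*$, then lower amplitude, with a
  warning.
* Fit bounds $T_1^* \in [10, 5000]$ ms, $A, B \ge 0$; LM tolerances
  `ftol = 1e-12`, `ptol = 1e-10`, ≤ 200 iterations.
* A rim width so large that the gray zone would swallow the remaining
  myocardium is clipped to the wall with a warning; a zero-extent
  infarct is valid and yields empty core and gray zone.
* All randomness flows from one seed; per-stage seeds are derived
  deterministically, so a run is bit-reproducible.

## Problem sizes

The shipped tests and the acceptance script run the default 64×64×3
phantom (about 3,700 fitted voxels), 1,000-voxel relaxometry sweeps with
32 TIs, 10–20 noisy phantom replicates, and full Fisher enumeration to
total 25 — sizes chosen so the whole suite completes in a few minutes on
a laptop core while still exercising every code path at realistic
dimensions.

## Known limitations

* The gray zone of the default phantom is a thin rim (≈ 2.8% of LV
  mass), below the 11–15% typical of patients; larger rims can be
  configured but change the difficulty of the clustering problem.
* FCM memberships depend on the z-scoring population: restricting the
  analysis mask changes features' means/SDs and thus the membership
  bands. The pipeline always clusters wall + cavity + PMs together.
* The intensity-route PM criterion and the 50% infarct-fraction
  threshold are documented surrogates for a qualitative published
  criterion.
* `lv_function()` implements plain summation of disks with no basal
  slice-inclusion rules or papillary handling options beyond the masks
  it is given.
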