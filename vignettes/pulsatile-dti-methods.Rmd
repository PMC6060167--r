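---
title: "Methods: simulating and measuring pulsatile-motion effects in DTI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring pulsatile-motion effects in DTI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pulsedti)
```

## The problem

Brain tissue moves with the cardiac cycle. During systole the brainstem and
cerebellum are displaced at peak velocities around 1.5 mm/s, predominantly in
an anterio-caudal direction. A diffusion-weighted acquisition encodes
microscopic water displacement along one gradient direction per volume, so
bulk tissue motion during the encoding period dephases the signal and appears
as a localized signal drop — strongest when the encoding gradient is aligned
with the motion. Cardiac gating avoids this by triggering acquisition into
diastole, at the price of longer, heart-rate-dependent scan times.

`pulsedti` provides a complete, reproducible test bed for the downstream
consequences of this artefact on corticospinal-tract (CST) analyses: diffusion
tensor parameters (FA, MD, eigenvalues), the principal eigenvector's
orientation, deterministic tractography, tract volume, and run-to-run tract
variability. Everything operates on a digital phantom with known ground
truth, so estimator error is measurable exactly.

## Signal model and artefact model

Clean signal follows the monoexponential tensor model per voxel:

$$ S(\mathbf{g}, b) = S_0 \, e^{-b\, \mathbf{g}^\mathsf{T} D\, \mathbf{g}} $$

with $b = 1000\ \mathrm{s/mm^2}$ for 30 encoding directions plus one $b=0$
volume, on a 2 mm isotropic grid — a standard clinical high-angular-resolution
single-shell protocol. Each of the 5 repetitions per gating mode draws an
independent cardiac phase uniform on $[0,1)$ for every volume; if the phase
falls inside the systolic window (fraction 0.3 of the cycle), every voxel of
each pulsatile zone is attenuated by

$$ a(\mathbf{g}) = \exp(-\kappa\, v\, |\mathbf{g}\cdot\mathbf{m}|) $$

where $v$ is the zone's peak velocity (1.5 mm/s brainstem, 1.0 mm/s
cerebellar analogue), $\mathbf{m}$ the unit motion direction (anterio-caudal,
$\approx(0, -0.45, -0.89)$ normalised) and $\kappa$ a dimensionless
calibration. The default $\kappa = 0.3$ makes systolic brainstem signal drop
by roughly 20–40% for near-axial encoding directions, the visually-obvious
regime; $\kappa$ is a free parameter of the artefact model, not fitted to any
in vivo measurement. Gated acquisitions draw the same phases (keeping RNG
streams aligned across gating modes, so a zero-strength artefact reproduces
the gated data bit for bit) but never attenuate. Rician noise
$\sqrt{(S+n_1)^2+n_2^2}$ is applied last; the default
$\sigma = S_0/30$ corresponds to SNR 30 on the $b=0$ brain signal.

Cardiac phase is drawn per *volume*, not per slice: real echo-planar
acquisitions interleave slices across the cycle, but a per-volume phase keeps
the data model 4D and reproduces the defining phenomenology — artefacts that
strike random subsets of the repetitions, strongest for encoding directions
aligned with the motion.

## The phantom

A $40\times40\times60$ voxel grid (2 mm isotropic) contains:

* a **CST analogue**: a 5 mm-radius tube running inferior → superior with a
  gentle sinusoidal bow (amplitude 4 mm) in the x–z plane, ground-truth
  eigenvalues $(1.7, 0.3, 0.2)\times10^{-3}\ \mathrm{mm^2/s}$ along the local
  tangent (FA $\approx 0.836$);
* isotropic tissue background ($0.8\times10^{-3}$) and a CSF compartment
  ($3.0\times10^{-3}$);
* two **pulsatile zones**: a brainstem analogue (a box around the inferior
  40 mm of the tract) and a cerebellar analogue posterior to it.

Region *labels* partition the grid, but the pulsatile *zones* are stored as
separate masks that deliberately include the tract voxels they engulf:
pulsatile motion displaces the tract tissue running through the brainstem
just as much as its surroundings, and this overlap is what propagates the
artefact into tract tensor parameters. Subject-level variation jitters the
tube's bow amplitude (SD 1 mm) and centre (SD 2 mm) — enough to decorrelate
voxel-level noise across subjects while keeping every phantom's tract
comparable slab by slab. The default study uses 22 subjects × 5 repetitions
× 2 gating modes.

What the generator does **not** emulate: head bulk motion, eddy currents,
susceptibility distortion, slice-interleave timing, spatially smooth velocity
fields (zones have sharp edges), anatomical variability beyond the tract
jitter, and scanner-specific gradient tables (a fixed electrostatic-repulsion
30-direction scheme ships with the package). Consequently, passing tests
demonstrate correctness of the estimators and the internal consistency of the
artefact → bias chain, not quantitative agreement with any in vivo cohort;
in-vivo quantities that depend on anatomy (absolute tract volumes,
between-subject spreads, per-subject gradient-to-head orientation) are out of
reach by design.

## Estimation stages

**Tensor fit.** Unweighted log-linear least squares, the classic first-pass
estimator (`dtifit`-style): exact on noiseless monoexponential data (the
acceptance suite verifies recovery of $10^4$ random SPD tensors to
$10^{-10}$ relative error). Signals are floored at $10^{-6} S_0$ before the
log so artefact-driven near-zero values cannot produce infinities. Negative
eigenvalues (possible under noise) are kept raw but clamped at zero for FA
and MD so FA stays in $[0,1]$; clamp counts are reported.

**Angles.** The gradient-facing subspace angle is the literal
$\arccos(\mathbf{g}\cdot\mathbf{a}/|\mathbf{g}||\mathbf{a}|) \in [0°,180°]$:
encoding directions carry a physical sign, and the direction farthest from
the z-axis can exceed 90°. The eigenvector-facing variant folds to
$[0°,90°]$ because eigenvectors are sign-ambiguous. Ties in the
extreme-volume selection break to the lowest volume index.

**Artefact flagging.** Visual inspection is replaced by a reproducible rule:
a repetition is flagged when its ROI-mean signal falls below
$(1-k)\times$ the median ROI-mean across repetitions, default $k = 0.15$.
The median is the natural reference because a minority of systolic
repetitions leaves it anchored at the clean level. The occurrence ratio is
flagged data sets over total data sets (subjects × repetitions), as a
percentage with two decimals.

**Tractography.** Deterministic FACT-style tracking: bidirectional fixed-step
Euler integration (1 mm) along the principal eigenvector, trilinear
interpolation of the tensor followed by local extraction of its dominant
eigenvector, termination at FA < 0.15, turns > 35° per step, or the grid
edge. The dominant eigenvector of the interpolated tensor is obtained by
power iteration warm-started from the incoming direction (12 iterations;
convergence is far inside the needs of 1 mm stepping because the start is
nearly converged, and the warm start doubles as sign continuity). FA at
interpolated tensors is computed directly from tensor invariants,
$\mathrm{FA}^2 = \tfrac32(\|D\|_F^2 - 3\,\mathrm{MD}^2)/\|D\|_F^2$, avoiding
a per-step eigendecomposition. Seeds sit at the centre of every tract-mask
voxel with fitted FA ≥ 0.25 plus the inferior include ROI. Retained
streamlines must intersect both include ROIs (cerebral-peduncle and
motor-cortex analogues) and no exclude ROI. Tracking parameters are
conventional values — the clinical tool the procedure emulates does not
publish its defaults — and are fully configurable.

**Tract metrics.** Tract masks are rasterized (a voxel is in the tract iff a
streamline point falls in it; volume = voxel count × voxel volume). Run-to-run
variability uses the five-sample generalized Jaccard distance
$JD = 1 - |\cap_i M_i| / |\cup_i M_i|$ on the rasterized masks. Along-tract
profiles cut the tract into 21 five-millimetre slabs from its inferior end
(105 mm total) with the conventional section labels: brainstem 1–5, posterior
limb of the internal capsule 6–10, corpus-callosum level 11–13, cingulum
level 14–18, motor cortex 19–21. Group comparisons are paired two-sided
t-tests at $\alpha = 0.05$ per slab, with no multiple-testing correction —
matching the per-slab convention of the analysis this reproduces; users
wanting family-wise control can correct the returned p-values. Empty slabs
are excluded, not imputed. Parameter maps are averaged across the five
repetitions per subject before group testing; repetitions are never averaged
before the tensor fit.

## Numerical and degenerate-input choices

* Tensor fit refuses rank-deficient designs (< 6 non-collinear directions).
* Eigen-decomposition drops non-finite voxels from the mask and counts them.
* FA of an all-zero tensor is defined as 0; empty ROI, empty seed mask,
  empty mask union (Jaccard) and zero-variance paired differences are
  explicit errors or degenerate results, never silent NaNs.
* Streamline points outside the grid are ignored and counted.
* World coordinates are voxel-centre based: centre of voxel $i$ (1-based) is
  $(i-\tfrac12)h$; interpolation is defined between voxel centres, so
  tracking stops half a voxel inside the grid boundary.
* Per-subject seeds follow a counter scheme (`master_seed + 1000 i`, + 1 for
  the non-gated and + 2 for the gated acquisition), so enlarging the cohort
  never changes existing subjects' data.

## What the simulation shows — and one documented divergence

The test suite and acceptance script compute, from a default 22-subject run:
repetition-SD excess confined to the pulsatile zones and scaling with
gradient–motion alignment; artefact occurrence ratios far higher for the
near-axial encoding direction than the near-orthogonal one; slab-wise FA
differences confined to brainstem/internal-capsule slabs; and exact
ground-truth recovery from gated data.

Two properties of the attenuation-only artefact model deserve emphasis
because they are *model outcomes*, not assertions:

1. **Sign of the tensor bias.** Attenuating the signal of systolic volumes
   inflates the apparent diffusivity along the affected directions, so in
   this model non-gated MD is over-estimated and tract FA slightly
   under-estimated. In vivo reports find the opposite FA sign; which sign a
   pure attenuation artefact produces depends on the geometry of affected
   directions relative to the tract, and the package reports whatever its
   model yields.
2. **Tract volume.** The same mechanism gives the nominally isotropic
   pulsatile-zone tissue a coherent apparent anisotropy; some streamlines
   leak out of the tube inside the zone, terminate at its sharp superior
   edge, and are then discarded whole by the two-include-ROI AND filter. At
   the phantom's small between-subject variability the paired test detects
   the resulting systematic volume deficit — whereas in vivo, anatomy-driven
   between-subject spread is several times larger and masks effects of this
   size. This is a known, documented limitation of combining a box-shaped
   artefact zone with all-or-nothing ROI retention.

## Problem sizes

Unit tests run on a $16\times16\times24$ phantom (seconds); the full study
property checks and the acceptance script use the default
$40\times40\times60$, 22-subject design, which completes in a few minutes on
one core. The tensor-fit oracle uses $10^4$ random SPD tensors.
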