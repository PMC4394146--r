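---
title: "Identifying anatomical boundary curves on 3D surface point clouds"
author: "ancurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying anatomical boundary curves on 3D surface point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancurve)
```

## The problem

Stereo-photogrammetry and laser scanning deliver anatomical surfaces as
large unstructured 3D point sets — tens of thousands of points for a torso,
on the order of 150,000 for a face — with no anatomical labels attached.
Classical morphometrics summarises such a surface by a handful of manually
placed landmarks, which discards almost all of the shape information.
Anatomically defined *curves* — the boundary of a breast on the chest wall,
the boundary ridges and midline valley of closed lips — are far richer
descriptors, and once a bounded region is delimited by curves it can be
resampled into corresponded *semi-landmarks* for standard statistical shape
analysis.

`ancurve` implements this programme end to end:

1. **Navigation.** Local coordinate frames from neighbourhood PCA, planar
   transect strips through the cloud, and principal curves that summarise
   each strip as a smooth 1D curve parameterised by arc length.
2. **Boundary evidence.** Ridges and valleys appear along a transect as
   extremes of the signed curvature
   $\kappa(s) = (x'y'' - x''y')/(x'^2+y'^2)^{3/2}$ of its principal curve,
   and as sharp changes in the first derivative of depth, assessed by a
   standardized two-sided comparison statistic.
3. **Boundary curves.** Candidate points are filtered by landmark-based
   plausibility rules, collated across transects, and smoothed into final
   curves — closed curves for breast boundaries, corner-constrained and
   shape-penalized P-splines for lips.
4. **Regularisation and shape analysis.** Bounded surfaces become
   corresponded semi-landmark grids; generalized Procrustes superimposition
   and principal component analysis describe shape variation, with paired
   and two-group score comparisons.

Because no study data can be redistributed, the package ships synthetic
torso and lip *phantoms* with analytically known boundaries, sampled at the
resolution and noise levels of real captures. Every claim the test suite
makes is made against these phantoms.

## Principal curves with P-spline smoothing

A principal curve $f(s)$ is self-consistent: its location at arc length $s$
is the mean of the data points that project there. `fitPrincipalCurve()`
implements the classical alternation — project all points onto the current
curve, then smooth each coordinate against the projection arc lengths —
initialised from first principal component scores. The smoother throughout
the package is a penalized B-spline (P-spline): cubic B-splines with a
second-difference penalty $\lambda\,\beta^T D_2^T D_2\beta$ on the
coefficients. The amount of smoothing is stated in effective degrees of
freedom (the trace of the hat matrix); $\lambda$ is solved by root finding
to match the requested df within $\pm 0.05$. The df values used by the
pipelines are fixed conventions of the method: 6 for breast transects, 8
for lip strips (two ridge peaks plus a valley), 12 for the closed breast
boundary, 25 for the corner-constrained lip boundary fits.

Numerical choices worth knowing:

* Arc length is cumulative chord length along a 512-point evaluation grid,
  with the coordinate smooths refit against the converged projections.
* Convergence is a relative change below `tol = 1e-4` in total squared
  projection distance, capped at `maxIter` iterations (the best iterate is
  returned with a flag when the cap binds). The alternation contracts
  slowly near its fixed point, so validation work uses a higher cap
  (40–60) than the default 20.
* Projection uses nearest-vertex search on the dense grid plus exact
  projection onto adjacent segments, optionally refined by 1D
  optimisation; ties resolve to the smallest arc length.
* Initialisation from the first principal component means the method
  handles arcs that are roughly monotone along their principal axis (as
  all transect strips are); closed or strongly folded point sets are out
  of scope for the fitter itself.
* Spline derivatives are boundary-biased, so curvature maxima are never
  taken from the outer 2\% of arc length, and curvature oracles are
  checked on interior (middle 60\%) stretches.

## The change-point statistic

On a lip strip the depth $z$ against arc length $s$ shows two smooth ridges
and, where the lips meet, a sharp valley: a discontinuity in $z'(s)$. At
each grid point two one-sided P-spline fits (df 8) are made — one to the
data below, one to the data above — and their derivative estimates at that
point are compared:

$$T(s) = \frac{\hat z_a'(s) - \hat z_b'(s)}
  {\sqrt{(w_a - w_b)^T(w_a - w_b)}\,\hat\sigma},$$

where $w_a, w_b$ are the weight vectors of the two linear derivative
estimators and $\hat\sigma$ comes from local differencing (each interior
observation against the linear interpolation of its neighbours, normalised
so iid noise of sd $\sigma$ gives expectation $\sigma$). A midline point is
declared only when the statistic exceeds 5 — strong evidence on an
interpretable standard-error scale. With arc length running up the face and
depth outward, a valley gives a *positive* derivative jump and a ridge a
negative one, so the midline search uses the signed maximum of $T$.

The evaluation grid is the observed arc lengths thinned to at most 200
points, with 10\% of the range masked at each end where one-sided fits are
unstable. The weight matrices depend only on the design, so simulation
replicates reuse them; under a smooth null with iid noise the pointwise sd
of $T$ is within a few percent of 1, and a planted slope jump of 1.0 at
noise sd 0.05 is localised within 5\% of the range essentially always.

## Breast pipeline

Radial transects sweep a frame anchored at the most prominent point
(*prom*, neighbourhood radius 12 mm) through 51 equal angular steps; each
half-strip has slab tolerance 1 mm, stops at the midline plane through
*ssn* and *xipho* (never crossing to the other breast), and is capped at
1.5 times the largest retained candidate arc length of the two previous
candidate-bearing transects. Per transect, the positive curvature maxima of
the df-6 principal curve are boundary candidates; a candidate $c$ is
retained iff

* (a) $\|c - \mathit{prom}\| > 0.7\,\min(\|\mathit{med}-\mathit{prom}\|,
  \|\mathit{lat}-\mathit{prom}\|)$,
* (b) its protrusion along the average surface normal at *ssn*/*xipho*
  lies within 10 mm of the range spanned by *med* and *lat*,
* (c) its elevation along the *xipho*→*ssn* axis lies above
  *inf* − 10 mm and below *ssn*;

projections are taken relative to the cloud centroid, identically for
candidates and landmarks, so the rules are origin-invariant. The constants
(0.7, 10 mm) are configuration-exposed: adjusting them is the intended
manual-intervention mechanism when an estimate needs correction. Transects
with exactly one retained candidate contribute a boundary point; the rest
are interpolated from flanking side curves with weights
$((l+1-i)\,\hat b_{Li} + i\,\hat b_{Ri})/(l+1)$. The closed boundary is a
df-12 smooth of each coordinate against angle, with 15\% of the
angle-ordered points duplicated beyond each end (shifted by $2\pi$) as a
periodic continuation device, then trimmed; start and end coincide to well
under 1 mm.

## Lip pipeline

A global mouth frame comes from PCA of the mouth-region cloud (n1 along the
elongated mouth axis, n2 vertical, n3 normal; signs fixed against coarse
orientation hints). Fifty vertical strips of tolerance 1.2 mm are scanned
for the midline valley; where it is detected, ridge candidates are the
convex local curvature maxima of the vertical principal curve above and
below the midline. Multi-candidate strips are resolved against a
preliminary 3D principal curve through the unambiguous strips, keeping the
candidate closest (in arc length along the strip's own curve) to the
preliminary crossing; when no unambiguous strips exist the preliminary
curve is seeded with the strongest candidate per strip.

Corners are the first and last local maxima of the 3D curvature of a
principal curve through the detected midline points (df 15) — the bends
where the crease rises toward the cheek. Maxima must exceed the 75th
percentile of the profile, and 5\% of the arc length is masked at each end
(the fitted curve's extreme ends carry leverage wiggles). The corner is
taken on the midline curve rather than on the lower-boundary curve — the
midline points are by far the best localised — and the alternative is one
argument away (`findCorners()` accepts any point set).

The three final curves share the midline arc-length parameterisation on
$[s_L, s_R]$; candidates beyond the corners are discarded. Each coordinate
is fitted at df 25 (30 basis functions) and forced through both corners via
the closed-form constrained-coefficient update applied with the penalised
Gram matrix. The vertical coordinate of the upper (lower) boundary
additionally carries monotonicity penalties — increasing (decreasing) over
the first 40\% of arc length, the reverse over the final 40\% — and
second-derivative-pattern penalties, both as iterated violation-mask
penalties with $\kappa = 100\lambda$. Masks depend on the coefficients, so
the fit iterates mask construction and solving to a fixed point; on the
rare mask cycle the union of the cycling violation sets is penalised once
and the iteration stops. The penalties are soft by design: corners are met
to machine precision (they are equality constraints), the shape conditions
in large measure.

## Semi-landmarks

Breast surfaces are resampled as the apex plus $r = 20$ points on each of
the $k = 51$ transects — 1021 points — at proportional arc lengths built
from equally spaced exponential quantiles capped at probability 0.99 (the
quantile function is unbounded, so a cap is required; it is configurable).
The spacing sequence is applied so that the gap adjacent to the apex is the
largest and gaps decrease strictly toward the boundary: the transects
converge at the apex, so selecting radial points more sparsely there gives
a more regular spacing across the surface. The last point of every transect
lies on the fitted boundary curve. Holding the descriptor (counts,
orientation, spacing rule) fixed across specimens yields point-to-point
correspondence by construction; no sliding is performed.

For lips, 50 points equally spaced in arc length on a boundary curve are
paired with the corresponding midline points, and each pair is joined by a
cross-lip principal curve (df 4) through the strip of surface points
between them, carrying interior semi-landmarks that ramp with lip width
from 3 at the corners to 24 at the widest point (piecewise-linear profile,
scaled so the widest pair gets exactly 24, rounded). Grids triangulate
into an apex fan plus split quads (breast: $k + 2k(r-1)$ faces) or by
monotone sewing between transects of unequal counts (lips).

## Shape analysis

Generalized Procrustes superimposition iterates optimal translation and
rotation (Kabsch) of every configuration onto the evolving mean.  Scale is
retained by default — with raw-coordinate covariance PCA this lets overall
size express itself in the first component (size-and-shape analysis); a
flag switches to full similarity superimposition. Loadings have their
largest-magnitude element made positive for reproducibility.
`shapeAtScore()` reconstructs the configuration at a given multiple of a
component's standard deviation (±2 sd is the conventional display);
`pairedScoreTest()` and `groupScoreTest()` run the paired and two-group
t-tests on component scores used for reconstructed-vs-unreconstructed and
male-vs-female comparisons.

## What the phantoms emulate — and what they do not

The torso phantom is a cylindrical chest wall (radius 200 mm) carrying two
spherical-cap mounds joined to the chest by a C² quintic fillet whose
curvature crest is the analytic ground-truth boundary; landmarks sit at the
cap apex, on the boundary (medial/lateral/inferior) and on the midline
(*ssn*, *xipho*). Defaults give a 500 × 400 mm window at 0.15 points/mm² —
about 30,000 jittered-lattice points, i.e. roughly 65 points within 12 mm
of *prom*, matching study-scale captures. The junction geometry (cap base
at 0.75 of a 60 mm radius, 10 mm fillet) was chosen as a realistic, shallow
inframammary fold that a 1 mm-slab transect of such a cloud can resolve.

The lip phantom is a gently curved skin patch with two Gaussian-profile
ridges (heights 3 and 2.5 mm — the lower boundary deliberately the less
marked one, as on real faces), a sharp triangular valley 1.5 mm deep where
the lips meet, and corners where all three curves meet: the valley floor
rises there over a quintic ramp and the crease path turns upward with
in-plane slope 0.6, continuing as a fading commissure crease (depth 0.8 mm,
Gaussian fade 12 mm) past the corners — the in-plane direction change is
the dominant corner-curvature signal, as on real faces, and the commissure
tail keeps the corner bends interior to the detected midline. The
ground-truth corners are the outermost curvature maxima of the analytic
midline curve. Default sampling is full-face stereo resolution
(150,000 points per 180 × 200 mm patch) over a 90 × 40 mm mouth crop, with
0.05 mm iid capture noise — the change-point statistic standardises by
noise, so a strictly noiseless surface is not its natural regime.

Both generators add displacement noise along analytic surface normals: iid
Gaussian plus an "orange peel" field (randomly weighted Gaussian kernels,
standardised to the requested sd, correlation falling to $e^{-1/2}$ at the
stated correlation length) emulating reconstruction artefacts. What the
phantoms do *not* emulate: pose deformation, missing data and occlusion,
anisotropic reconstruction error, texture, and genuinely asymmetric
anatomy. Passing tests therefore demonstrate the machinery under idealised
but realistically sampled conditions, not clinical performance.

## Known limitations

* On noiseless torso phantoms at study-scale sampling the estimated
  boundary is typically within 1–1.5 mm rms of the true junction but the
  pointwise worst case runs 2–3 mm: a df-6 smoothing spline cannot reach
  fully into the junction crease (a ~1 mm outward bias) and the sparse
  strips (30–60 points) leave ~1 mm of argmax jitter that df-12 boundary
  smoothing reduces but does not remove. The original assessment of breast
  boundaries was visual; these numbers quantify the same regime.
* Lip corner recovery is typically within 1–1.5 mm but fluctuates with the
  sampling draw (occasionally ~2.5 mm): the corner bend spans only a few
  strip spacings. Upper and midline curve errors sit comfortably under
  1 mm rms; the (weaker) lower boundary hovers around 1 mm.
* The principal-curve fitter requires strips that are roughly monotone
  along their first principal component; it is not a general space-curve
  reconstructor.
* Mouth-region cropping is assumed done (or a bounding box supplied);
  automatic face-wide mouth localisation is out of scope, as are
  open-mouth configurations and colour-based segmentation.

## Problem sizes used in validation

The test-suite and acceptance computations run the default study-scale
phantoms (one ~30,000-point torso per geometry, a ~15,000-point mouth
crop), 500 replicates for null calibration of the change-point statistic
and 200 for localisation power, 20 random instances for the
constrained-fit oracle, and 25 specimens for the planted-mode PCA check.
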