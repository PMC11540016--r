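---
title: "Lattice radiotherapy planning and polymer-gel CBCT verification: methods"
author: "latticeqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice radiotherapy planning and polymer-gel CBCT verification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeqa)
```

## Scope

Lattice radiotherapy (LRT) is a spatially fractionated technique that
delivers a 3D array of small high-dose spheres ("vertices") inside a tumor
volume, separating dose *peaks* at the vertices from much lower *valleys*
between them. `latticeqa` covers the two computational halves of an LRT
quality-assurance workflow:

1. **planning aid** — placing sphere vertices on a hexagonal close-packed
   (HCP) or rectangular lattice fully contained in a target structure; and
2. **dosimetric verification** — reading out a polymer-gel dosimeter imaged
   with cone-beam CT (CBCT) and comparing the measured 3D dose with the
   planned dose (profiles, isodose volumetrics, gamma analysis).

A synthetic-data module generates a cylindrical gel phantom, a multi-sphere
plan dose, and noisy CBCT scan pairs, so the whole chain is testable
without any clinical data.

## Vertex placement

### Lattice model

The HCP lattice with centre-to-centre spacing $s$ is built from triangular
"A" layers with basis $a_1 = (s, 0, 0)$ and
$a_2 = (s/2, s\sqrt{3}/2, 0)$; layer $k$ sits at $z = k\,s\sqrt{2/3}$ and
odd ("B") layers are offset in-plane by $(s/2,\, s/(2\sqrt 3))$. Every
interior site then has exactly 12 nearest neighbours at distance $s$ — the
close-packing coordination number — and adjacent layers are
$s\sqrt{2/3} \approx 0.8165\,s$ apart. The rectangular alternative is a
cubic grid with period $s$ (coordination number 6). A user shift
$(\Delta x, \Delta y)$ translates the whole lattice in-plane; there is no
$z$ shift.

Anchoring is genuinely underdetermined by the printed description of the
reference workflow, so the package fixes one convention and documents it:
an A-layer passes through the anchor, the anchor itself is a lattice site,
$a_1$ points along $+x$, and the default anchor is the target-mask
centroid. On the canonical cylindrical target (radius 45 mm, height
90.5 mm, i.e. 575.7 cm^3) with 15 mm spheres at 30 mm spacing this yields
the 7 + 6 + 6 = 19-sphere arrangement; the alternative convention of
running a B layer through the centre yields 20 and was rejected because it
does not reproduce the published count.

### Containment

A candidate site is kept when a sphere of radius $d/2$ around it lies
entirely inside the target. Because targets arrive as voxel masks, this is
evaluated on the mask's exact Euclidean distance transform (computed with a
separable parabolic-envelope algorithm, correct for anisotropic voxels):
the candidate's voxel must have distance $\ge d/2$ to the nearest outside
voxel centre. The sub-voxel error of this criterion is bounded by half a
voxel diagonal; on the 1 mm grids used for placement this is well below
the 7.5 mm sphere radius. Overlapping lattices ($s < d$) are rejected at
specification time, so every vertex set satisfies a minimum pairwise
distance of $s$ by construction.

## Gel readout chain

The measurable quantity is the CBCT-number change between averaged
post-irradiation and pre-irradiation scans,
$\Delta N = \bar N_\text{post} - \bar N_\text{pre}$ (six scans per
condition by default, suppressing white noise by $1/\sqrt 6$ per mean).

### Filtering

*Adaptive mean filter.* Per axial slice, a local-statistics (Wiener-type)
filter with a 3 x 3 pixel window: with window mean $\mu_w$, window
variance $\sigma_w^2$, and noise power $\nu^2$ estimated as the slice-wide
mean of $\sigma_w^2$,
$$\hat x = \mu_w + \frac{\max(\sigma_w^2 - \nu^2,\, 0)}{\max(\sigma_w^2,\,
\nu^2)}\,(x - \mu_w).$$
Flat regions collapse to the local mean; structure with variance far above
the noise floor passes through. Box sums are computed with integral
images, with windows clipped at slice borders.

*Remnant ring removal.* Ring and cupping residuals that survive background
subtraction are azimuthally symmetric about the scanner axis and narrow in
radius. Per slice the volume is resampled on polar rings (radial step =
in-plane voxel size; angular step giving half-voxel arc length) and a
radial profile is formed from a low angular quantile (35th percentile) of
each ring. For an azimuthally symmetric remnant every angular quantile is
an unbiased estimate; a low quantile is preferred over the median because
lattice sphere rings can cover almost half of a circle — exactly the
median's breakdown point — while remaining below the 65% coverage a 35th
percentile tolerates. The remnant is the rapidly varying component of this
profile: its residual above a running-median baseline over `artefact_span`
(default 7) radial samples, iterated four times because a single median
pass leaks ~25% of a sinusoidal ring into the baseline. The baseline
follows monotone ramps and steps — genuine dose falloff and the container
wall — exactly. Two boundary rules matter: the profile is mirrored about
$r = 0$ so an on-axis dose cap reads as a broad symmetric bump rather than
a narrow removable feature, and the remnant is interpolated with a spline
clamped to the knot range so it is never extrapolated at the axis pixel or
beyond the outermost ring. The subtracted remnant has its slice mean
removed, so slice means are preserved. The exact artefact-removal
algorithm used with the physical protocol is not public; this
implementation is a documented surrogate with the same interface
(`span` in radial samples), and alternates can be swapped in upstream of
calibration.

### Dose-response calibration

The gel's dose response is modelled as
$$\Delta N(D) = \alpha + \beta \tanh(\gamma D - \varphi),$$
with offset $\alpha$ and amplitude $\beta$ in CBCT numbers, rate $\gamma$
in 1/Gy, and dimensionless shift $\varphi$; $\beta, \gamma > 0$ make the
curve strictly increasing. *Self-calibration* fits these four parameters
by nonlinear least squares over all (planned dose, measured $\Delta N$)
pixel pairs of one axial slice — by default the slice whose planned-dose
range is maximal, mirroring the practice of calibrating on the slice that
contains the entire dose range. A mask (typically the gel container)
restricts the fit to pixels where gel actually responds.

Numerical care is needed because lattice slices have bimodal dose
histograms (valley floor and peak plateaus): an unconstrained fit reliably
falls into the degenerate $\beta \to \infty$, $\gamma \to 0$ quasi-linear
manifold. The fit therefore runs Levenberg-Marquardt from a 3 x 3
deterministic grid of starting values ($\gamma_0 \in \{1, 2, 4\}/\text{span}$,
tanh midpoint at the 25/50/75% dose quantiles, $\alpha_0$ at the response
mid-range, $\beta_0 = 0.8 \times$ response range) with bounds
$\beta \le 5 \times$ observed response range and
$\gamma \le 50/\text{span}$, and keeps the lowest-SSE solution. A dose
span below half the maximum dose triggers a conditioning warning; a
constant dose or response slice is an error.

Inversion applies
$D = (\operatorname{atanh}(u) + \varphi)/\gamma$ with
$u = (\Delta N - \alpha)/\beta$ clamped to $[-1 + 10^{-6},\, 1 - 10^{-6}]$
(saturation safety) and negative doses clamped to zero; both clamp
fractions are reported as attributes of the returned volume.

## Comparison suite

*Profiles* are trilinear samples of both volumes at uniform arc length
(exact on fields linear in the coordinates). *Valley metrics* detect peaks
as local maxima above 50% of the trace maximum separated by at least
10 mm (half the default lattice spacing, excluding noise peaks), report
each inter-peak minimum as a percent of a normalization dose, and measure
peak widths at the prescription level by linear interpolation of the
crossings. The default valley normalization is the volume maximum; the
prescription dose is available as an option because published valley
percentages do not always state their base.

*Equivalent diameters.* The isodose mask at the prescription level is
decomposed into 26-connected components; each component is matched to the
nearest planned vertex centre (within one sphere diameter), and its
equivalent spherical diameter is $d = (6V/\pi)^{1/3}$. Merged components
matching two vertices raise an error — impossible by construction while
spacing >= diameter holds.

*Gamma analysis.* The 3D global gamma index of reference (plan) versus
evaluated (gel) dose is
$$\gamma(r) = \min_p \sqrt{\frac{\lVert p - r\rVert^2}{\delta_\text{DTA}^2} +
\frac{(D_e(p) - D_r(r))^2}{(\delta_D\,D_\text{norm}/100)^2}},$$
with $D_\text{norm}$ the reference maximum (global normalization;
prescription normalization is an option), a 10% low-dose threshold, and
the evaluated dose trilinearly interpolated on a sub-voxel search grid
(refinement 3 by default) within a ball of radius 3 x DTA. Search points
are visited in order of increasing distance, so the scan stops as soon as
the spatial term alone exceeds the running minimum — an exact, not
heuristic, cut. A voxel passes at $\gamma \le 1 + 10^{-9}$; the slack
keeps mathematically exact boundary cases (dose difference exactly equal
to the criterion) from failing by one floating-point ulp. The refinement-3
default overestimates $\gamma$ by the sub-voxel quantization of the search
grid (order 0.1 at 2 mm DTA on steep fields); tests therefore validate the
search against an independent exhaustive oracle at matched refinement 8,
and separately bound the refinement-3 quantization. The 12-criteria sweep
crosses 1/2/3/5% dose difference with 1/2/3 mm DTA; pass rates are
monotone in both criteria by construction. Whether evaluation counts all
above-threshold voxels or only those inside the gel container is exposed
as an option (`mask`), since published pass rates rarely state the choice.

## Synthetic phantom and study conditions

The generator fixes the canonical fixture at the study's printed geometry:
a cylinder of radius 45 mm and height 90.5 mm (analytic volume
575.7 cm^3), 15 mm spheres at 30 mm spacing (19 vertices), prescription
20 Gy, peak 24.9 Gy, valley floor 30% of peak — inside the 10-40% valley
band the protocol targets. The plan dose is
$$D(p) = f P\,\sigma\!\left(\frac{R_\text{env} - d_\text{min}}{w_\text{env}}\right)
+ (1 - f) P \max_c \sigma\!\left(\frac{r_0 - \lVert p - c\rVert}{w}\right),$$
a logistic peak per vertex over a valley floor, with $r_0$ chosen in
closed form so the prescription isodose around an isolated vertex has
exactly the nominal 15 mm diameter — giving analytic oracles for isodose
and valley tests. The floor decays with distance to the nearest vertex
(logistic envelope, half-height 30 mm, width 4 mm) because delivered
plans fall toward the phantom periphery; without that decay no axial slice
would span low doses and the four-parameter calibration would be
unidentifiable on its own calibration slice. The penumbra width default of
1.8 mm keeps the vertex-centre dose within 0.5% of the nominal peak at
30 mm spacing.

CBCT scans are simulated as a constant gel base number plus the forward
tanh response inside the phantom, i.i.d. Gaussian noise per scan (default
SD 0.6 CBCT numbers = 1% of $\beta$), and an optional azimuthal ring
artefact added to the post-irradiation scans (it must survive background
subtraction to exercise the remnant-removal stage). One RNG seeded per
simulation drives all scans, so every stochastic test is reproducible.

What the generator does *not* emulate: CBCT physics (scatter, beam
hardening, projection reconstruction), gel temporal drift and dose-rate
effects, container walls with their own CT number, spatially correlated
noise, and plan-vs-readout grid mismatch (the pipeline assumes the plan
dose is already on the CBCT grid, as when both share DICOM coordinates).
Passing end-to-end tests therefore demonstrate the correctness and noise
behaviour of the *analysis chain*, not the physical fidelity of a gel
system.

## Problem sizes and tolerances

Placement and the acceptance count run on the 1 mm canonical grid
(96^3 voxels). The end-to-end closure fixture (simulate, read out,
calibrate, invert, 12-criteria sweep) runs at 2 mm voxels (52^3), which
keeps the full suite fast while leaving ~1,600 calibration pixels per
slice; the calibration-recovery property runs at 1 mm (~6,400 pixels on
the calibration slice), where the parameter estimators are tight enough
for a 2% bias bound over seeded replicates. Gamma-oracle equivalence uses
21^3 smooth random fields. Geometry comparisons use 1e-6 mm; interpolation
identities 1e-9; statistical assertions state their seed and replicate
count in the tests themselves.

## Known limitations

- The remnant-removal surrogate is near-idempotent (second application
  changes the volume by under 10% of the first correction), not an exact
  projection.
- Calibration parameters are only as identifiable as the dose support of
  the calibration slice; with valley-floor-only support the dose inversion
  remains accurate but individual parameters drift along the tanh model's
  flat manifold.
- DICOM RT Dose import is not provided; NRRD (raw or ascii encoding,
  axis-aligned) and NIfTI-1 are the supported interchange formats.
- No registration or resampling: all volumes must share one grid, checked
  to 1e-6 mm.
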