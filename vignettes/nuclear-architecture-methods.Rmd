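---
title: "Methods: simulating and measuring nuclear architecture remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring nuclear architecture remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmorph)
```

`nucmorph` quantifies how oncogene variants remodel nuclear architecture:
nuclear size and shape, nucleolar sub-compartments (nucleolin, fibrillarin),
and spliceosomal speckles (SC-35), in 2D widefield planes and 3D confocal
stacks, together with a transcriptomic remodeling score and an antibody
phospho-array classification chain. Because the real study system (inducible
KRAS-variant epithelial lines) is not reproducible at a desk, every
measurement stage is validated against seeded synthetic data whose ground
truth is known analytically. This vignette records the models, the tunable
parameters, the numerical choices, and what the synthetic validation does
and does not demonstrate about real data.

## The synthetic nucleus model

**2D.** A nucleus is a star-shaped domain with radial boundary
$r(\theta) = R\,(1 + a f(\theta))$, where $f$ is a truncated Fourier series
over harmonics $k = 2 \dots 1{+}H$ with random coefficients normalized to
unit RMS and random phases. The amplitude $a$ (fraction of the radius,
capped at 0.5) and harmonic count $H$ (default 4) control boundary
irregularity. Harmonic $k = 1$ is excluded: it mostly translates the shape
rather than deforming it.

**3D.** Nuclei of adherent epithelial cells are flattened along the optical
axis, and that flattening — not surface roughness — is the dominant
determinant of sphericity in the 0.6–0.8 range reported for such cells. The
3D model is therefore an oblate spheroid (in-plane semi-axis $R$, axial
semi-axis $qR$) modulated by a band-limited perturbation built from real
spherical harmonics of degrees $2 \dots 1{+}H$, again normalized to unit
RMS. A purely radial perturbation of a sphere cannot reach sphericity 0.68
without the radius going negative, which is why the flattening axis exists
in the model.

**Calibration to shape targets.** When a cohort specifies a target
circularity (2D) or sphericity (3D), each nucleus is calibrated
individually: the analytic circularity is monotone decreasing in $a$, and
the analytic sphericity is monotone increasing in $q$, so a bisection on the
analytic geometry (not the raster) hits the target to ~10⁻³. Shape metrics
of the generated objects are computed by quadrature on the analytic radial
function — trapezoid in the angular coordinate(s) and Gauss–Legendre in
$\cos\theta$, which is spectrally accurate for these band-limited
boundaries — and recorded as per-object ground truth. Sizes are drawn from a
lognormal with the configured mean (µm² or µm³) and CV; the shape is then
scaled so its analytic area/volume equals the drawn size exactly.

**Placement and nesting.** Nuclei are placed by rejection sampling with a
minimum center distance of the two bounding radii plus one mean radius
(i.e. an inter-nucleus margin of one object radius); a blocked configuration
restarts from scratch a bounded number of times before raising a
"field too crowded" error. Compartments are discs/spheres with lognormal
sizes, placed with strict containment: a candidate position is accepted only
if a dense deterministic sample of its boundary lies radially inside the
parent with a one-voxel margin (the parent boundary is band-limited, so a
96-point ring / 256-point Fibonacci sphere cannot miss a violating sector).
Fibrillarin foci nest inside nucleolin domains; nucleolin and SC-35 nest in
the nucleus. Same-channel siblings may not overlap; a compartment that finds
no admissible position after bounded retries is skipped, so realized counts
can fall slightly below the Poisson draw in crowded nuclei.

**Rendering.** analytic shape → binary raster (a voxel belongs to an object
iff its center lies inside the analytic boundary) → Gaussian PSF blur →
optional Poisson shot noise → additive Gaussian noise → 16-bit
quantization. Defaults: background 0.05, PSF σ 0.1 µm, Gaussian noise 0.01
of full scale, no shot noise; the acquisition noise of the emulated
instruments is not published, so these are free parameters chosen to look
like clean widefield data. All randomness flows from one master seed through
named stage substreams (`stage_seed`), so identical (spec, seed) pairs are
bit-identical.

## Segmentation and morphometry

Segmentation is deliberately simple and uniform — Gaussian smoothing, one
global threshold (Otsu per channel, or a fixed value), optional hole
filling, connected components (8-connectivity in 2D, 26 in 3D), minimum
size in physical units, border exclusion. `estimate_threshold()` freezes an
Otsu threshold on pooled baseline (0-h) images so that a single parameter
set can be applied uniformly across all cohorts and time points; the
pipeline does this per channel when `freeze_baseline` is set. 3D objects
touching the first or last z-plane are excluded by default because their
volumes are incomplete.

**Perimeter (2D).** Circularity $4\pi A/P^2$ is extremely sensitive to the
perimeter estimator. Boundary-pixel counting overestimates $P$ on discs by
up to 5% (circularity ≈ 0.9 for a perfect disc); the 4-direction Crofton
approximation is nearly unbiased on smooth convex shapes but *under*states
the perimeter of axis-aligned rectangles by ≈ 5.5%, which would report a
square at circularity 0.88 instead of π/4 ≈ 0.785. We instead measure the
length of the 0.5-level marching-squares contour of the object mask smoothed
with a fixed Gaussian (σ = 1.5 px). On digitized discs of radius ≥ 20 px
this is accurate to < 0.5% and on squares to < 1%, satisfying both closed
forms simultaneously; it is also the 2D analog of the 3D surface estimator,
so both dimensionalities share one numerical philosophy. The σ is a fixed
property of the estimator (in pixels), which keeps circularity
scale-invariant.

**Surface area (3D).** Voxel-face counting overestimates a sphere's surface
by ~50%, destroying the sphericity → 1 limit, and meshing the *binary* mask
directly still overestimates by ~27%. We mesh with marching tetrahedra
(6 tetrahedra per cell, linear edge interpolation, physical spacing applied)
at the 0.5 level of the mask smoothed with an isotropic *physical* Gaussian
of 0.8 × the coarsest voxel pitch (so on a grid with 0.1 µm lateral and
0.3 µm axial spacing the kernel is 2.4/2.4/0.8 voxels). The scaling to the
coarsest axis matters: staircase steps on anisotropic grids extend laterally
over max(spacing)/spacing voxels, and smoothing only along z leaves a +4–5%
surface bias on flattened nuclei. With this estimator a ball of radius 20
voxels measures sphericity 0.99, a cube 0.82 (closed form 0.806), and
rasterized oblate nuclei are recovered within 0.01–0.02 of their analytic
sphericity. Volume is always the voxel count times the voxel volume —
never taken from the mesh. Single-voxel objects have a degenerate mesh and
are reported `NA` with a warning.

Compartment-to-nucleus assignment follows majority overlap: a child is
assigned to the parent holding the most of its pixels provided that is at
least 50%; otherwise it is an orphan; an exact 50/50 split goes to the lower
parent label for determinism.

## Transcriptomic and phospho scoring

The DE filter keeps records with FDR strictly below 0.05 and |log2FC| of at
least 0.75 (the boundary value 0.75 is kept; FDR exactly 0.05 is dropped).
The nuclear panel is the filtered set restricted to the chromatin-remodeling,
nuclear-membrane and nucleolus GO cellular-component categories, supplied as
an annotation column — no ontology service is queried. The NTRS is the
unweighted arithmetic mean of log2 fold changes, computed separately over
positive and negative values; zeros contribute to neither, and an empty
direction is reported as `NA` rather than 0, because 0 would masquerade as a
valid score. Sign concordance between two conditions is
(matching − opposite) / shared over genes nonzero in both.

The phospho chain follows the array-quantification convention: each
antibody's value on an array is the mean of its duplicate spot medians;
arrays are normalized to their global median (median of an even count =
mean of the central pair, so the post-normalization median is exactly 1);
normalized signals are averaged over the three biological replicates;
phospho signal is divided by the paired total-protein signal per site; and
the +doxy/−doxy log2 fold change is classified up/down at inclusive
boundaries ±1. Normalization is per array (condition × doxycycline state ×
replicate) — the chain is then invariant to global array scaling because the
ratio cancels the normalization constant. Replicates are averaged after
normalization and before fold change to minimize replicate-scale artifacts.
No p-values are attached to phospho calls anywhere; sites are classified by
fold change only. Total-protein abundance is classified the same way but
without the ratio step.

The DE simulator assigns each gene a GO category and a fixed base direction
shared across conditions; a responsive subset of the nuclear genes receives
condition-specific effects (with an `invert` flag to emulate a
dominant-negative, inversely regulated program), affected genes draw FDR
uniformly below 0.05 with probability 0.95 — only the threshold crossing
matters downstream — and null genes draw log2FC from N(0, 0.3) and FDR
uniform on (0, 1).

## Reporting and statistics

Cohort reports carry n, mean, SD and a t-distribution 95% CI (exact at
small n) per condition/metric/time point, the percent change of the mean
versus the 0-h baseline, and a baseline contrast per non-baseline time
point: a pooled two-group one-way ANOVA p-value, Sidak-adjusted with m =
number of non-baseline time points, then star coded with strict bins
(`*` < 0.05 down to `****` < 1e-4; p = 0.05 is `n.s.`). The literal
repeated-measures ("paired") reading of the ANOVA is impossible for
destructive imaging — individual cells are not matched across time points —
so the contrasts are unpaired with Sidak family correction, which is what
the figure-level comparisons against the 0-h control amount to. Reported
percentages round half away from zero (base R's `round` is half-to-even and
would print 41.28% → 41 but 2.5 → 2). One printed value in the source
system (−7.3% for 823.0 → 762.2, which recomputes to −7.39%) suggests
unrounded internal means upstream; this package always computes from its
own data and does not special-case it.

Simulated type-I calibration: under the null, the fraction of cohort
families with any Sidak-adjusted baseline contrast below 0.05 stays within
[0.03, 0.07] over 1000 runs. The two contrasts share the baseline group and
are therefore positively correlated, which pushes the familywise rate
slightly below the independent-contrast 5%; this is expected behavior of
the correction, not a defect.

## Problem sizes used in validation

The packaged validation runs at sizes chosen to exercise every code path at
full fidelity while staying desk-sized: shape-limit checks on discs of
radius 50–200 px and balls of radius 5–40 voxels; cohort recovery at
n = 150–200 nuclei per cohort (2D at 0.1 µm/px; 3D at 0.16 × 0.16 × 0.32 µm
voxels with 350 µm³ nuclei — sphericity is dimensionless and its estimator
is validated separately on closed-form solids, so recovery does not depend
on running at the full 823 µm³ scale); a full-pipeline demo with six
cohorts × ~200 cells in 2D and 256 × 256 × 64 stacks with 8 nuclei per
cohort at 823 µm³ in 3D; 1000 null simulations for type-I calibration; and
phospho arrays at the full 584-site scale for the null-rate check.

## What the synthetic validation shows — and what it does not

Passing tests demonstrate that the measurement chain is *correct*: the
estimators converge to closed forms, recover known generator parameters
with the advertised precision, hold their nominal error rates, and are
deterministic under seeding. They do not demonstrate that real nuclei meet
the model's assumptions. Specifically, the generator does not emulate:
touching or overlapping nuclei (no watershed splitting is implemented, by
design); intensity heterogeneity within compartments; chromatic aberration,
drift, or depth-dependent PSF broadening; mitotic figures or cell-cycle
state; and speckle shapes more complex than discs/spheres (measured speckle
circularity ~0.58 in real data reflects irregular speckles the simulator
does not generate — its compartments are circular by construction, and
their measured circularity is correspondingly high). Small compartments near
the resolution limit (≲ 10 voxels across) have upward-biased sphericity
after smoothing; per-compartment shape statistics are therefore most
trustworthy for the nucleus itself.

## Other deliberate choices

* 2D images are single focal planes, not projections of the 3D model; the
  2D and 3D generators are separate models sharing the same machinery.
* The z-step of the emulated confocal acquisitions (0.03 µm nominal) would
  oversample absurdly; defaults use 0.25–0.3 µm axial spacing, configurable.
* Otsu's threshold on a constant image is undefined; segmentation returns
  zero objects rather than erroring.
* The pipeline segments only channels with configured content; thresholding
  a channel that contains nothing but background noise is meaningless.
* Manifests contain a config hash, seed, package version and file list but
  no timestamps, so reruns of identical (config, seed) are byte-identical;
  wall-clock logging goes to `run.log` only.
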