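---
title: "Probabilistic tractography connectivity profiling: models and methods"
author: "picotract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic tractography connectivity profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`picotract` implements a complete desk-scale analogue of a structural
connectivity-profiling study: given diffusion-weighted volumes, it estimates
per-voxel fibre orientation distributions (FODs) by constrained spherical
deconvolution (CSD), propagates Monte-Carlo streamlines through the FOD
field in the PICo style, aggregates per-seed-voxel visitation counts into a
seed-ROI x target-region *maximum connectivity* matrix (values in
0..10,000 with the default 10,000 streamlines per seed voxel), and applies a
two-level inference: a per-participant Poisson threshold at p = .05, then
group consistency under a strict (>75% of participants, i.e. at least 10/13
with N = 13) and a relaxed (>50%, at least 7/13) criterion.

Because acquired human data are not part of the package, every stage is
exercised on digital fibre phantoms with known ground truth, and the tests
ask whether the pipeline recovers connections that exist by design and
rejects ones that do not.

## The phantom and its forward model

A phantom is a set of tubular bundles on an isotropic voxel grid (default
40x40x40 voxels at 1 mm). Within a tube every voxel carries the local
tangent as its fibre orientation; tube caps (the first/last 3 mm of
arclength) define endpoint regions that play the role of atlas target
labels, and each bundle declares one ground-truth connection between its two
endpoints. The `two_arcs` preset places two concentric semicircular tubes
(radii 8 and 17 mm, tube radius 2 mm) in one plane, mimicking an inner and
an outer crescent of a dorsal pathway; the 5 mm clearance between tube
surfaces makes the bundles genuinely disjoint, which is what the
no-spurious-connection checks rely on.

The signal follows the standard multi-tensor model,

S(g) = S0 [ sum_j f_j exp(-b g' D_j g) + (1 - sum_j f_j) exp(-b lambda_iso) ],

with axially symmetric tensors (lambda_par = 1.7e-3, lambda_perp = 3e-4
mm^2/s along/across each population) and an isotropic compartment
(lambda_iso = 7e-4 mm^2/s) for the non-fibre fraction — typical
white-matter values, chosen once as defaults. The emulated acquisition is 61
unique gradient directions at b = 1200 s/mm^2 plus one b = 0 volume;
direction sets are generated by seeded electrostatic repulsion (500
iterations) because the study's own direction table is not published — any
near-uniform antipodally-symmetric set is equivalent for these purposes.
Rician noise is applied as S_noisy = sqrt((S + n1)^2 + n2^2) with
n1, n2 ~ N(0, sigma^2) and sigma = S0/SNR; the default SNR of 30 at b0 is
typical of 3 T DWI. The brain mask is the tube union dilated by 2 voxels:
inside it non-fibre tissue is isotropic, outside it there is no signal,
mirroring skull-stripped data and bounding the tracking domain.

A cohort is a set of participants sharing one anatomy envelope (the brain
mask and target labels) in which each bundle's connection is present or
absent by design; per-participant noise streams derive from
`master_seed + participant index`, so cohorts are bit-reproducible.

What the phantom deliberately does *not* emulate: EPI distortion,
eddy-current and motion artefacts, cardiac pulsation, partial-volume
gradients at grey/white boundaries, multi-shell acquisitions, and realistic
anatomical geometry. Passing tests therefore demonstrate correctness of the
algorithms under the stated forward model, not performance on acquired
scans.

## CSD: basis, conventions, and the regularisation trade-off

FODs are expanded in a real, orthonormal, antipodally symmetric
spherical-harmonic basis (even orders only; within order l the columns run
m = -l..l with sine harmonics for negative m, the zonal harmonic at m = 0,
cosine harmonics for positive m). Self-consistency of the sign and
normalisation conventions is enforced by tests: numerical orthonormality of
the Gram matrix and rotation equivariance of fitted peaks.

The single-fibre response is the axially symmetric signal profile stored as
zonal coefficients. It can be estimated from voxels known (from phantom
truth) to hold one coherent population — each voxel's gradient frame is
rotated so its fibre axis maps onto z, the b0-normalised profiles are
averaged and projected onto the zonal harmonics — or computed analytically
for the prolate tensor by Gauss–Legendre quadrature. By the Funk–Hecke
theorem, convolution with the response multiplies each order l by
sqrt(4 pi/(2l+1)) r_l, giving a linear forward operator from FOD
coefficients to signal.

The constrained fit iterates: solve the penalised least-squares system, find
the sphere directions (default 300) where the FOD amplitude falls below
tau x mean(initial amplitude) with tau = 0.1, add those rows to a soft
penalty that pushes their amplitudes towards zero, and repeat until the
active set stabilises (at most 50 iterations). The penalty weight is
`lambda` times the Frobenius-norm ratio of the data and constraint
operators.

`lambda` embodies a genuine trade-off that deserves an honest statement.
With a fully determined scheme at lmax = 8, a *strictly* non-negative FOD
cannot reproduce the signal of a 30 degree crossing with two distinct
peaks: the exactly constrained solution (computed with a QP solver during
design) merges the peaks at the bisector and leaves a reconvolution
residual of several percent. Two sharp fibre populations 30 degrees apart
are band-limited to one broad lobe unless small negative side-lobes are
tolerated. The package therefore uses a *soft* penalty and two default
strengths: `fit_csd()` defaults to `lambda = 0.01`, which preserves the
documented angular resolution (crossings resolve down to 30 degrees on a
dense noise-free scheme, merging at 25) and keeps the kernel-signal
reconvolution residual below 1e-3 x S0; the cohort pipeline defaults to
`csd_lambda = 1`, because under measurement noise the stronger penalty is
what suppresses spurious FOD lobes — with it, streamline survival through a
noisy tube matches the noise-free field, while the weak penalty loses an
order of magnitude. Matching the regularisation strength to the noise
regime is standard practice; both defaults are fixed, and tests cover both
regimes.

Peak extraction evaluates the FOD on a 724-point spherical Fibonacci grid,
takes grid-local maxima, refines each by derivative-free ascent in the local
tangent plane, merges antipodal duplicates, and discards peaks below 0.25 of
the largest amplitude or within 15 degrees of a stronger peak.

## Tracking: sampling rule and stopping rules

Streamlines advance in 0.50 mm steps. At each step the SH coefficients are
interpolated trilinearly at the current position — implemented as trilinear
interpolation of precomputed per-voxel amplitudes on a fixed 724-direction
set, which is algebraically identical because the amplitude is linear in
the coefficients — and a direction is drawn with probability proportional
to the FOD amplitude, restricted to (a) the hemisphere within 90 degrees of
the previous direction and (b) amplitudes at or above the tracking
threshold (default 0.1). Restriction (b), the standard cutoff of
amplitude-sampled CSD tracking, matters: FOD side-lobes and the isotropic
baseline otherwise receive enough probability mass that streamlines leak
out of thin bundles. Termination follows the printed rules: cumulative
turning angle within one voxel above 180 degrees (the rule is implemented
literally and is deliberately permissive; no per-step angle cap is added),
a physical path limit of 500 mm, leaving the mask, or no permitted
amplitude above threshold.

Propagation is bidirectional — the two half-tracks start in opposite
hemispheres and share the 1000-step budget sequentially — because a
unidirectional walker from a mid-pathway seed could never reach both ends.
Start points are jittered uniformly within the seed voxel to avoid lattice
artefacts. Visitation is binary per streamline per voxel, so a voxel's
count is the number of distinct streamlines that encountered it and the
seed voxel's count always equals the number initiated. Each seed voxel's
RNG stream is `rng_seed + linear voxel index`, making maps independent and
the whole run deterministic.

## Connectivity and the two-level inference

Seed ROIs are voxel sets within an inclusive Euclidean radius of a centre
(the inclusive boundary is the convention under which a 5 mm sphere on a
1 mm grid holds exactly 515 voxels), optionally clipped to a probabilistic
mask with a strictly-positive default threshold. The connectivity value of
a seed ROI to a target region is the *maximum* visitation count over the
ROI's per-voxel maps and the region's voxels — max, not sum, which is what
keeps the printed 0..10,000 range independent of ROI size.

Per participant, a Poisson rate is fitted (MLE = mean) to the pooled
seed x target values — excluding each seed's own host region, since the
analysed target scheme excludes the seed regions themselves — and the
individual threshold is the smallest integer t with P(X > t) < .05;
connections strictly above t survive. Zeros are pooled by default (the
value distribution is zero-inflated as a result; a flag allows excluding
them for sensitivity analysis). At the group level, a connection passes the
strict criterion when its participant count strictly exceeds 75% of N
(count >= floor(0.75 N) + 1, giving 10 of 13) and the relaxed criterion
beyond 50% (7 of 13); strict passes are a subset of relaxed passes by
construction.

## Numerical choices and degenerate inputs

* Poisson threshold at lambda = 0 is 0; the implementation uses the
  quantile function with an explicit strict-inequality correction and is
  tested against direct pmf summation up to lambda = 1000.
* Peak finding on an identically zero FOD returns an empty set; antipodal
  duplicates are merged by canonicalising signs.
* `fit_csd` refuses responses with no power at a required order and
  schemes with fewer directions than coefficients.
* Voxel indices are 0-based; world coordinates run through the NIfTI
  affine; voxel centres sit at integer voxel coordinates; all geometry is
  in mm.
* TCK streamline files use little-endian float32 with NaN separators, the
  format's standard layout; bvec files use the FSL dialect (3 rows).

## Problem sizes used by tests

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen so a full run stays comfortable on one CPU: the cohort
recovery check uses the `two_arcs` phantom with 13 participants at 1,000
streamlines per seed voxel and 1.5 mm seed spheres (clipped to the 2 mm
tubes — a 5 mm sphere is the right scale for a human gyrus, not for a 2 mm
phantom tube); the range contract runs one seed voxel at the full 10,000
streamlines; resolution sweeps use 300 directions at b = 3000. The
determinism check repeats a reduced two-participant run and compares output
bytes.

## Known limitations

* The soft non-negativity penalty does not produce strictly non-negative
  FODs (see the trade-off discussion above); amplitudes are clamped at
  zero during tracking.
* The per-voxel curvature rule as printed (180 degrees cumulative) hardly
  ever binds at these geometries; most terminations are by mask exit or
  amplitude threshold.
* PICo's original calibrated PDFs and residual-bootstrap uncertainty are
  replaced by direct FOD-amplitude importance sampling; the bootstrap
  would be a natural extension.
* Connectivity values are not normalised for distance or ROI size, exactly
  as in the emulated procedure; they are counts, not probabilities of
  anatomical connection.
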