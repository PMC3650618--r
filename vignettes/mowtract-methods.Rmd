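---
title: "Multi-fiber tractography by mixture-of-Wisharts deconvolution: methods and design"
author: "mowtract"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-fiber tractography by mixture-of-Wisharts deconvolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diffusion-weighted MRI measures the attenuation of the MR signal caused by
water diffusion along a set of gradient directions.  In white matter,
diffusion is fastest along axons, so the directional profile of the signal
carries the local fiber orientation.  The classical single-tensor model
assigns one orientation per voxel and fails wherever fiber populations
cross, kiss, or branch — precisely the regions that long association and
projection pathways must traverse.  `mowtract` implements a multi-fiber
pipeline: per-voxel orientation distributions estimated by deconvolution
against a dictionary of Wishart-distributed tensors, discrete peak
extraction on a sphere tessellation, dense-seed deterministic streamline
propagation, and ROI-based connectivity filtering with track-volume
statistics.  A synthetic multi-tensor phantom generator makes every stage
testable against known ground truth.

## The signal model

A voxel's ensemble of microscopic diffusion environments is modelled as a
mixture of Wishart distributions over symmetric positive-definite $3\times3$
tensors.  The Laplace-transform property of the Wishart density gives each
mixture component a closed-form attenuation, so the normalised signal for
b-value $b$ and unit gradient $\mathbf g$ is linear in the mixture weights
$w_j \ge 0$:

$$\frac{S(b, \mathbf g)}{S_0} \;=\; \sum_{j=1}^{162} w_j\,
\bigl(1 + b\, \mathbf g^{\mathsf T} (\mathbf D_j / p)\, \mathbf g\bigr)^{-p},$$

where $\mathbf D_j$ is the *expected* tensor of the $j$-th component and $p$
is the Wishart shape parameter.  The dictionary holds 162 atoms with fixed
eigenvalues $(1.5, 0.4, 0.4)\ \mu m^2/ms$ — a prototypical single-fiber
tensor — whose principal axes are the vertices of a level-2 icosphere, so
orientation space is covered evenly.  Because the eigenvalue pair is
degenerate, each atom is simply
$\mathbf D_j = \lambda_\perp \mathbf I + (\lambda_\parallel - \lambda_\perp)
\mathbf v_j \mathbf v_j^{\mathsf T}$.

Weights are estimated per voxel by non-negative least squares
(Lawson–Hanson active set, via `pracma::lsqnonneg`), which is robust to
noise and returns sparse solutions; sparsity is what turns the dictionary
fit into a *few*-fiber model.  The b0 volumes act purely as the
normaliser ($S_0$ = mean across b0 volumes) and are excluded from the
design; the low-b ($b \approx 100$) volumes enter as ordinary rows with
their own b-value.

From the fitted weights the water displacement probability profile is the
corresponding mixture of zero-mean Gaussians, probed on a sphere of radius
$r$ at diffusion time $t$:

$$P(r\mathbf u) \;=\; \sum_j w_j\, (4\pi t)^{-3/2} |\mathbf D_j|^{-1/2}
\exp\!\left(-\frac{r^2\, \mathbf u^{\mathsf T} \mathbf D_j^{-1} \mathbf u}{4t}\right),$$

evaluated at the 642 vertices of a level-3 icosphere.  Its local maxima are
the per-voxel fiber directions.

### Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| dictionary eigenvalues | (1.5, 0.4, 0.4) | $\mu m^2/ms$ | single-fiber prototype tensor |
| $p$ (Wishart shape) | 2 | — | sharpness of the component distributions |
| $t$ (diffusion time) | 20 | ms | PDF probe time, $t = \Delta - \delta/3$ |
| $r$ (probe radius) | 12 | $\mu m$ | displacement shell radius |
| peaks per voxel $K$ | 3 | — | crossing-fiber capacity |
| dedup tolerance | 15 | degrees | duplicate-maximum merging |
| step | 0.25 | mm | Euler integration increment |
| max turn | 50 | degrees | per-step stopping criterion |
| seeds per voxel | 64 | — | $4^3$ sub-voxel lattice |

$p$ is exposed but defaults to 2, the value used by the reference
formulation of the deconvolution.  $t$ and $r$ influence only the contrast
of the PDF, not the *locations* of its maxima for a fixed-eigenvalue
dictionary; a property test varies $t$ over 15–40 ms and verifies the
extracted peak set is unchanged.  The 15° dedup tolerance sits safely above
the level-3 grid spacing (about 8°): fiber populations closer than that are
unresolvable on this tessellation no matter the tolerance.

## Peak extraction

The 642-point profile is maximised by multi-start discrete gradient ascent:
the 42 level-1 icosphere vertices (a subset of the level-3 vertex set, since
subdivision nests) each seed a hill climb that moves to the
largest-valued neighbour while that value exceeds the current one.  Strict
ascent on a finite graph terminates; ties between equally valued neighbours
go to the lower vertex index so the procedure is deterministic.  Terminal
vertices are folded antipodally (orientations are axes, and the Gaussian
mixture is centrally symmetric, so $P(\mathbf u) = P(-\mathbf u)$ exactly),
deduplicated within 15°, sorted by PDF value, and truncated to $K$.  A
numerically constant profile yields an empty peak set flagged isotropic; an
optional peak-to-mean ratio filter (off by default) can additionally
suppress near-isotropic voxels.

The multi-start design is validated against a brute-force oracle: over
1000 random mixture profiles, the global argmax vertex is always among the
returned peaks.

## Seeding and propagation

Each brain-mask voxel receives a $4 \times 4 \times 4$ lattice of seeds at
fractional offsets $(k+0.5)/4$ across the voxel, producing a globally
uniform seed field whose spacing (voxel/4) is continuous across voxel
boundaries.  From each seed one bidirectional streamline is launched per
seed-voxel peak (configurable to primary-peak-only).  Propagation is plain
Euler integration: at every 0.25 mm step the current voxel's peak most
inline with the travel direction (largest $|\mathbf d \cdot \mathbf m|$;
ties by PDF value, then rank) is chosen and sign-aligned.  A streamline
stops when the chosen direction would turn it by more than 50°, when it
leaves the brain mask, when it enters a stop mask (stop-at-target
tracking), or when a voxel offers no peak.  Fractional anisotropy is
deliberately absent from the stopping logic — FA is ambiguous exactly where
multi-fiber models are needed — and the tracking interface accepts no FA
input, which a test enforces.

Peaks are looked up voxel-wise (nearest voxel) rather than interpolated:
interpolating a multi-valued direction field is ill-defined, so the
pipeline instead supports interpolating the *raw data* to an isotropic grid
(`resample_isotropic`, trilinear) before fitting, mirroring common
practice of tracking on 1 mm resampled data acquired at 2 mm.

A hard cap (2000 steps per direction, 500 mm at the default step) guards
against cycles; the 50° rule makes loop-backs practically impossible but a
bound is still recorded as a termination reason.

## Connectivity and track volumes

A streamline connects a pathway if at least one of its points falls in
*every* inclusion mask and none in any exclusion mask (nearest-voxel
lookup).  The track volume of a filtered bundle is the number of distinct
grid voxels visited times the voxel volume — a binary visitation map, which
is invariant to streamline order and duplication and yields integer mm³ on
a 1 mm grid.  Group summaries report per-pathway means and $n-1$ standard
deviations with untraceable (zero-volume) pathways *included* as
observations; the bundled ten-participant reference table
(`example_track_volumes()`) reproduces its published summary statistics
only under this convention, which fixed the choice.  For one of its four
pathways the table-derived mean (683.6 mm³) disagrees with the summary
value printed alongside the original table (778.2 mm³) while the printed
standard deviation does match; `mowtract` reports the table-derived value.

## The phantom generator

`simulate_dwi()` renders a declarative `phantom_spec()`: cylindrical fiber
bundles (capsules around polyline centerlines) in an isotropic background
on a 1 mm grid, imaged with the default `hardi_scheme()` of 64 unique
b = 1000 s/mm² directions, six b = 100 volumes and two b = 0 volumes.
Voxels inside a bundle carry an axially symmetric tensor compartment along
the local centerline tangent with the same (1.5, 0.4, 0.4) diffusivities
as the dictionary prototype; voxels crossed by two bundles split the signal
evenly; background voxels are isotropic at 0.7 $\mu m^2/ms$.  The forward
attenuation uses the same Wishart law as the deconvolution.  Rician noise
is applied per volume as $\sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}$ with
$\sigma = S_0/\mathrm{SNR}$ and a fixed seed, so outputs are
bit-reproducible.  The brain mask extends 1 mm beyond the bundles.

Five standard geometries probe distinct failure modes: `STRAIGHT`
(propagation and volumes), `CROSS90` (two-peak recovery and bundle
separation at a 90° crossing), `BRANCH` (a 40° fork; off-axis stem seeds
enter single-branch territory, so a deterministic tracker populates both
branches), `CURVE` (a 90° cumulative turn executed over a 10 mm radius arc,
i.e. ~1.4° per 0.25 mm step — far below the per-step limit), and
`DISJOINT` (parallel, unconnected bundles; the negative control for
false-positive connections).

What the phantoms *do not* emulate — and hence what passing tests do not
demonstrate about scanner data: partial-volume fractions at bundle
boundaries (membership is binary at voxel centres), spatially varying
$S_0$, susceptibility and eddy-current distortion, subject motion, gyral
geometry, and more than two fiber populations per voxel.  Phantom results
bound the method's geometric behaviour, not its robustness to acquisition
artefacts.

## Numerical choices

* **Icosphere construction.**  Midpoint subdivision of the regular
  icosahedron with re-projection to the unit sphere; midpoints are
  deduplicated by parent edge (no coordinate rounding), parents keep their
  indices, so vertex sets nest exactly across levels and are closed under
  negation to the last bit.
* **Canonical hemisphere.**  An axis is represented by whichever of
  $\pm\mathbf u$ has a positive last nonzero coordinate — total,
  deterministic and idempotent.
* **Voxel lookup.**  World points map through the inverse affine to
  continuous 0-based indices; the containing voxel is the nearest centre
  (`floor(x + 0.5)`), with boundary points resolving upward.
* **Degenerate voxels.**  Non-finite or all-zero signals yield a flagged
  all-zero weight vector rather than an error; negative normalised values
  are clipped to zero and counted.  The NNLS zero solution bounds the
  residual, so flagged voxels never poison neighbours.
* **Tie-breaks.**  Ascent ties go to the lower vertex index; most-inline
  ties (|Δdot| < 1e-9) go to the higher PDF value, then peak rank.  All
  orderings are deterministic, so a fixed configuration and seed give
  bit-identical tractograms.
* **Resampling.**  Trilinear with border clamping; reproduces degree-1
  intensity fields exactly at interior sample points and preserves the
  world position of the grid corner.

## Problem sizes used by the test-suite and acceptance runs

Phantom grids are 18–25 voxels per side at 1 mm with 8 seeds per voxel
(2 per axis), which exercises every code path while keeping each
simulate–fit–track cycle in the tens of seconds; the orientation-recovery
phantom scores 700 bundle voxels, comfortably above the 500-voxel target
for the noisy condition.  Full 64-seed density is the shipping default and
is exercised on single- and two-voxel masks where the lattice geometry is
checked exactly.

## Known limitations

The dictionary's fixed eigenvalues assume a single tissue response; voxels
whose true anisotropy differs (oedema, partial volume with CSF) are fitted
as weight spread, not as a different tensor shape.  Peak directions are
quantised to the 642-point grid (~8° resolution) — there is no continuous
refinement.  Deterministic most-inline propagation follows one path per
seed-peak; it reports no uncertainty, and branching coverage relies on
dense seeding rather than probabilistic sampling.  Track volumes depend on
the tracking grid via the visitation map and on seeding density near the
detection threshold.  Streamline polarity (which end is "origin") is not
inferable from diffusion data.
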