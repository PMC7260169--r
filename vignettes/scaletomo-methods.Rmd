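---
title: "Whole-scale nano-tomography processing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-scale nano-tomography processing: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

High-resolution X-ray nano-holotomography images a field of view of a few
tens of micrometres, so a whole biological object such as an ultra-white
beetle scale (200-400 um long) must be captured as a series of vertically
overlapping scans and assembled afterwards. The scales of *Cyphochilus* and
*Lepidiota stigma* beetles contain a disordered chitin/air network whose
chitin volume fraction ("filling fraction") is the headline quantity: about
31% and 34% respectively when measured on intact scales, far below the
45-70% reported from sectioned samples whose fragile networks had collapsed.

`scaletomo` implements the full processing chain downstream of
reconstruction:

1. **simulate** - a ground-truthed synthetic porous scale (so every stage
   can be validated at desk scale without the 25-40 GB deposited volumes);
2. **stitch** - overlap-frame registration and assembly of the sub-scans;
3. **segment** - saturation, chunked non-local means denoising, and
   dual-mode thresholding into a material/air binary volume;
4. **metrics** - filling fraction with cube-sampling uncertainty,
   directional two-point correlations, and representative-cube selection.

Conventions used throughout: axes `(x, y, z)` with `z` the scan/length axis
and `x` the thin axis of the scale; voxel pitch 25 nm; 8-bit greyscale
volumes use the 0-254 range; binary volumes store material as 0 and air as
1, and are bit-packed MSB-first in row-major `(x, y, z)` order. Storage
sizes are quoted in decimal GB (1e9 bytes), matching the deposit manifests.

# The synthetic scale generator

The generator is the package's study-condition definition, not a fixture.
A porous two-phase network with a single characteristic length is modelled
as a level set of a Gaussian random field: seeded white noise is smoothed
with an isotropic Gaussian kernel of standard deviation
`correlation_length_nm` (default 150 nm = 6 voxels) and thresholded at the
sample quantile of the interior field equal to `target_fill` (default
0.31), so the interior filling fraction is met to within `1/n` by
construction and truths at different fills are nested level sets of one
field. Smoothing is done by circular (FFT) convolution: reflecting
boundaries would inflate the local variance near the faces and, after
quantile thresholding, systematically deplete the core; the circular field
is exactly stationary, and the wrap-around correlation only couples voxels
a full box apart. A solid cuticle shell (default 12 voxels = 300 nm) is
stamped on the two large (x) faces.

Rendering draws material at grey level 60 and air at 180 (dark chitin,
light air), applies a multiplicative concentric-ring artefact
`1 + A sin(2 pi r / P)` in every xy-slice about the slice centre (the
tomographic rotation axis; defaults A = 0.05, P = 40 voxels = 1 um),
adds Gaussian noise (default sigma = 20 grey levels, i.e. contrast-to-noise
6 for the 120-level phase separation), and rounds/clips to 0-254. Scan
splitting cuts the volume into fields of view of 2160 frames (54 um)
overlapping by 400 frames (10 um) - the real acquisition geometry - with
optional seeded integer z-jitter and lateral shifts emulating stage
repositioning; the true offsets are recorded for validation.

What the generator does *not* emulate: beam/phase-contrast physics,
reconstruction streaks other than the ring model, partial-volume voxels
(the rendered phases are pure before noise), anisotropic or layered
networks, and intensity drift between scans. Tests that pass on synthetic
scales therefore validate the *pipeline logic and its statistical
behaviour* under realistic contrast, noise, and artefact levels - not the
biological correctness of any particular reconstruction.

One integer seed drives everything; per-stage seeds are derived as
`(16*seed + k) mod 2147483629` with a fixed stage index `k` (truth 1,
render 2, split 3, cube sampling 4), so stages are independently
reproducible.

# Assembly

Consecutive scans nominally share `overlap_um * 1000 / pitch_nm` frames
(400 at the study geometry). The registration automates what was done by
eye for the real scales: the centre frame of the earlier scan's overlap
region is compared against candidate frames of the next scan within
`search_window` frames of the nominal offset and lateral shifts within
`lateral_window` voxels, scored by normalized cross-correlation (invariant
to the affine intensity rescaling that per-scan normalization introduces).
Ties break towards the nominal offset, then the smallest lateral shift.
Registration is integer-voxel only - subvoxel resampling would alter the
data. Seams are placed at the centre of the matched overlap, avoiding the
artefact-prone extreme frames of each scan. On noiseless, jitter-free
synthetic scan sets the split-match-stitch cycle is bit-exact, and offsets
are still recovered exactly with independent per-scan noise of 5 grey
levels.

Mounting-tilt correction estimates the Euler angles (degrees, `Rz Ry Rx`)
that align the scale's principal axes with the grid. The estimator selects
dark voxels below the midpoint of the robust 5%/95% intensity quantiles
(robust to noise and ring modulation, unlike the volume median), smooths
the indicator (5 voxels) and cuts at a quarter of the interior plateau
level, then closes the porous texture by filling each x-column between its
first and last material voxel - the scale is a shell-bounded slab, thin
along x, and the solid slab gives texture-free second moments. Eigenvectors
of the coordinate covariance, matched greedily to grid axes with positive
diagonal signs, give the correction. A volume whose dark phase is spread
like the uniform grid (relative Frobenius deviation of the covariance from
the grid moment below 5%) is rejected as having no dominant object; tilt is
likewise unobservable if the object fills the grid entirely. At desk scale
the estimator recovers known 2-3 degree rotations to better than 0.1
degree.

Rotations resample on the inverse-mapped lattice with cubic convolution
(Catmull-Rom, a = -1/2) by default; nearest-neighbour and trilinear modes
exist, out-of-bounds positions fill with the air grey level, and 8-bit
inputs are rounded and re-clipped. Cubic B-spline prefiltering was
deliberately not used: cubic convolution is local, needs no prefilter pass
over a ~25 GB matrix, and its forward-backward residual on smooth content
is well under one grey level RMS.

# Segmentation

The chain is: saturate, normalize, denoise, threshold twice, combine.

* **Saturation** clips the darkest 0.5% and lightest 0.5% of voxels at the
  corresponding linear-interpolation sample percentiles, computed over the
  *whole* volume (per-chunk percentiles would make the result depend on the
  chunk grid).
* **Normalization** maps the clip window linearly onto `[0, 1]`. The
  published thresholds refer to a "normalized" intensity that is otherwise
  undefined; the saturation window is the only scale the pipeline has
  established, so that is the definition frozen here.
* **Non-local means** (patch size 5, patch distance 7) replaces each voxel
  by a similarity-weighted average with weights
  `exp(-max(d^2 - 2 sigma^2, 0)/h^2)` on patch mean-squared differences.
  Patches are 3-D by default (a 2-D slice-wise mode exists for
  comparison). The filtering strength `h` is not a published value; the
  default derives it at run time as `0.8 sigma_hat`, with `sigma_hat` the
  median-absolute-deviation estimate from slice-wise Laplacian residuals,
  and both are recorded in the provenance. Numerical choices frozen for
  reproducibility: internal single-precision arithmetic; weights below
  `exp(-25)` treated as exactly zero; `exp` evaluated from a 4096-entry
  interpolation table (absolute error < 1e-5); volume edges reflect-padded
  (half-sample) so every patch sum is complete.
* **Chunked application**: the denoiser's true spatial support radius is
  `patch_distance + (patch_size - 1)/2 = 9` voxels - the patch terms reach
  beyond the search radius - so chunks carry a halo of at least 9 (default
  10, the published section overlap). Per-voxel summation order is
  position-independent, which makes halo-chunked processing bit-identical
  to monolithic processing; chunks are therefore freely parallelisable, and
  a halo below the support radius is refused outright rather than silently
  degrading seams.
* **Adaptive Gaussian threshold** (region 60, offset 0.06): material where
  the value is strictly below the Gaussian-weighted local mean
  (`sigma = (region-1)/6`, kernel truncated at `ceiling(4 sigma)` taps,
  reflecting boundaries) minus the offset. It captures the fine network but
  calls large solid areas air.
* **Global threshold** (0.4, strict `<`): captures solid chitin - the
  cuticle - but nothing subtle. Both thresholds use strict inequality,
  applied to the denoised volume (the processing-chain order).
* **Combination**: voxelwise product in air = 1 polarity, i.e. the union
  of the material sets, representing both the internal structure and the
  cuticle.

Degenerate inputs behave predictably: a constant volume saturates to
itself, normalizes to 0, and thresholds to all air; `region_size = 1`
(sigma 0) is flagged as degenerate; an even patch size is an error.

On noiseless two-level renderings the chain reproduces the ground truth
exactly; at the default noise and artefact levels it recovers the interior
filling fraction to within a few tenths of a percentage point.

# Metrics

The filling fraction is the material share in percent; interior variants
exclude a per-axis margin (cuticle plus an edge guard). Cube sampling draws
seeded uniform corners for cubes (deposit convention: 200 voxels = 5 um)
fully inside the interior; the quoted uncertainty is the *sample standard
deviation across cubes* - a standard error over 275 cubes would be far
smaller than the published +/-1-2%, so the spread interpretation is the
consistent one. Note that on small synthetic volumes, cubes only a few
correlation lengths across have intrinsically large fill spread; the
statistic is about the real 200-voxel cubes, where the ratio of cube edge
to structural length is much larger.

The directional two-point correlation `S2(r)` is the probability that two
voxels separated by `r` lattice steps along x, y or z are both material,
over all in-bounds pairs with no wrap-around (the cubes are physical
samples, not periodic cells); `S2(0)` equals the filling fraction. The
representative cube minimises the mean squared deviation of its three
directional curves from the cube-averaged curves (mean over directions and
lags, ties to the lowest index); the default maximum lag is 100 voxels
(2.5 um), capped below the cube edge.

# Pipeline, determinism and problem sizes

`run_pipeline()` executes simulate-stitch-segment-metrics, writing every
intermediate, a deposit-style manifest, JSON-lines logs, per-stage
provenance and a final report; a stage failure aborts with the stage name
and preserves earlier outputs. Everything is deterministic: re-running a
configuration with the same seed reproduces the packed mask byte for byte,
for any worker count (chunk independence is guaranteed by the halo design,
and results are reassembled by index).

The test suite and examples run at deliberately desk-scale sizes chosen
once: synthetic scales of 96 x 96 x 224 voxels for the fill-recovery
checks (2.4 x 2.4 x 5.6 um at 25 nm pitch - large enough for several
hundred structural correlation volumes between the shells), 64^3 for the
chunked-versus-monolithic equivalence, 48 x 48 x 300 with a 120-frame field
of view and 40-frame overlap for registration round trips, and 10-60 cubes
of edge 16-48 for the statistics. The real matrices (up to 40.6 GB) differ
only in extent, not in code path: the chunk planner, halo logic and packed
IO are exactly what a full-scale run would use, with chunks sized to about
128^3 voxels by default.

# Known limitations

* The NLM strength `h` and the patch dimensionality of the original
  processing are unrecorded; defaults here are reasoned reconstructions,
  flagged in provenance, not published values.
* Whether the published global threshold applied to the raw, saturated or
  denoised normalized volume is ambiguous; this package thresholds the
  denoised volume, following the processing-figure order.
* Registration is integer-voxel and pairwise-sequential; there is no
  global bundle adjustment over more than two scans, no deformable model,
  and no pre-reconstruction radiograph alignment (out of scope).
* The tilt estimator assumes one dominant slab-like object thin along x
  and strictly inside the volume; it reports an error otherwise, and a
  manual override (passing explicit angles to `rotate_volume()`) remains
  available.
* The generator's structural correlation length is a free parameter, not a
  measured property of the real scales.
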