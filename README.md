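# scaletomo

Stitching, segmentation and microstructure statistics for whole-sample
X-ray nano-holotomography of porous biological structures — built around
the processing chain used for intact ultra-white beetle scales
(*Cyphochilus*, *Lepidiota stigma*), whose chitin/air networks scatter
light more efficiently than any engineered white material.

A single scale is hundreds of micrometres long, but a nano-tomography scan
at 25 nm voxel pitch covers only a 64 × 54 µm field of view, so a whole
scale is acquired as 6–8 vertically overlapping scans (10 µm overlap) that
must be registered and assembled into one matrix, denoised, and thresholded
into a chitin/air binary volume before any structural statistic — above
all the **filling fraction** φ (chitin volume percent, ≈31 % and ≈34 % for
intact scales) — can be measured.

## What the package computes

* **Assembly** — the number of scans needed to cover a sample of length
  *L* is ⌈(L − FOV)/(FOV − overlap)⌉ + 1; consecutive scans nominally share
  `overlap·1000/pitch` frames (400 at 10 µm / 25 nm). `find_overlap()`
  registers consecutive scans by normalized cross-correlation over a z and
  lateral search window, `stitch()` assembles with seams at the centre of
  each matched overlap, and `estimate_tilt()`/`rotate_volume()` correct
  small mounting rotations (principal-axis estimate, cubic interpolation).
* **Segmentation** — `segment()` runs the chain: 0.5 %/99.5 % percentile
  saturation → min–max normalization to [0, 1] → 3-D non-local means
  (patch size 5, patch distance 7), applied over chunks with a 10-voxel
  halo that makes chunked output bit-identical to monolithic → adaptive
  Gaussian thresholding (region 60, σ = (region−1)/6, offset 0.06) →
  global threshold (material iff intensity < 0.4) → union of the two
  material sets.
* **Metrics** — `fill_fraction()`, `sample_cubes()` (e.g. 275 random
  interior 5 µm cubes), `fill_stats()` (mean ± sd across cubes),
  `directional_correlation()` (two-point probability S₂(r) along x/y/z,
  S₂(0) = φ), and `representative_cube()` (least mean-squared deviation
  from the cube-averaged curves).
* **Synthetic scales** — `generate_truth()`/`render_greyscale()` build a
  seeded Gaussian-random-field porous network at an exact target fill,
  wrapped in a solid cuticle shell and rendered with noise and concentric
  ring artefacts, so the whole chain is testable at desk scale.
* **IO** — NPY containers, zip-wrapped single arrays, TIFF stacks, and the
  deposit's bit-packed mask format (material = 0 / air = 1, MSB-first,
  row-major (x, y, z)) with manifest arithmetic in decimal GB.

## Worked example

```r
library(scaletomo)

# a synthetic scale: 31 % chitin network in a cuticle shell, rendered with
# noise and ring artefacts, then cut into overlapping scans
cfg <- run_config(seed = 3, out_dir = tempfile("run"))
cfg$synthetic$shape <- c(48L, 48L, 220L)
cfg$fov_voxels <- 100L; cfg$overlap_voxels <- 40L; cfg$jitter <- 1L
cfg$cube_edge <- 16L; cfg$n_cubes <- 10L; cfg$r_max <- 8L
cfg$interior_margin <- 4L

report <- run_pipeline(cfg)
str(report[c("interior_fill", "truth_interior_fill",
             "cube_fill_mean", "cube_fill_sd", "stitch_scores")])
#> List of 5
#>  $ interior_fill      : num 32.9
#>  $ truth_interior_fill: num 33
#>  $ cube_fill_mean     : num 29.7
#>  $ cube_fill_sd       : num 24.7
#>  $ stitch_scores      : num [1:2] 1 1
```

The report says: the two scan junctions matched with perfect
cross-correlation (the jittered offsets were recovered exactly), and the
segmentation chain recovered the interior chitin fill to within 0.1
percentage points of the generated truth (33 % here — the realized fill
of a small sub-volume fluctuates around the 31 % target). The large
per-cube spread is expected at this miniature scale, where a 16-voxel cube
is only a few structural correlation lengths across; the deposit's 200-voxel
cubes are far larger relative to the structure. The run directory holds the
packed mask, every intermediate volume, a deposit-style manifest, stitch
diagnostics, provenance and logs.

Scan-coverage arithmetic for the real acquisitions:

```r
scan_count(240, 54, 10)        # Cyphochilus, 240 um long -> 6 scans
scan_count(350, 54, 10)        # L. stigma,   350 um long -> 8 scans
nominal_overlap_frames(10, 25) # 10 um overlap at 25 nm    -> 400 frames
```

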