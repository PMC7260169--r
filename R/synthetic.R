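# One user seed drives every stochastic draw; each stage re-seeds with a
# fixed documented offset so stages are reproducible independently.
stage_seed <- function(seed, stage) {
  offs <- c(truth = 1, render = 2, split = 3, cubes = 4)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 16 + offs[[stage]]) %% 2147483629)
}

#' Configuration for the synthetic porous-scale generator
#'
#' Describes a two-phase porous network (dark chitin, light air) with one
#' characteristic structural length, enclosed in a solid cuticle shell on the
#' two large (x) faces, rendered to 8-bit greyscale with additive Gaussian
#' noise and concentric ring artefacts about the z (rotation) axis.
#'
#' Defaults mirror the study conditions where stated: 25 nm voxel pitch,
#' chitin filling fraction 0.31 (0.34 for the second species), material
#' darker than air. The structural correlation length, shell thickness,
#' grey levels and artefact amplitudes are not reported for the real scales;
#' the defaults are realistic choices for this class of microstructure and
#' are exposed here rather than claimed.
#'
#' @param shape Volume dimensions in voxels `(nx, ny, nz)`.
#' @param pitch_nm Voxel pitch in nanometres.
#' @param target_fill Material (chitin) volume fraction of the interior
#'   network, in `(0, 1)`.
#' @param correlation_length_nm Gaussian-kernel standard deviation used to
#'   smooth the random field, i.e. the characteristic structural length.
#' @param cuticle_thickness_voxels Solid shell thickness stamped on the two
#'   large faces (low/high x).
#' @param grey_material,grey_air Mean rendered 8-bit intensities of the two
#'   phases (`grey_material < grey_air`).
#' @param noise_sigma Additive Gaussian noise standard deviation (grey
#'   levels).
#' @param ring_amplitude,ring_period_voxels Multiplicative concentric-ring
#'   artefact model: each xy-slice is modulated by
#'   `1 + ring_amplitude * sin(2*pi*r/ring_period_voxels)` about the slice
#'   centre.
#' @param eight_bit Render to rounded, clipped 0-254 integers (the volume
#'   convention) rather than floats.
#' @param seed Integer seed; all stochastic draws derive from it.
#' @return A list of class `synthetic_scale_config`.
#' @export
synthetic_scale_config <- function(shape = c(128, 128, 448),
                                   pitch_nm = 25,
                                   target_fill = 0.31,
                                   correlation_length_nm = 150,
                                   cuticle_thickness_voxels = 12,
                                   grey_material = 60,
                                   grey_air = 180,
                                   noise_sigma = 20,
                                   ring_amplitude = 0.05,
                                   ring_period_voxels = 40,
                                   eight_bit = TRUE,
                                   seed = 1) {
  stopifnot(length(shape) == 3L, all(shape >= 1))
  if (!(target_fill > 0 && target_fill < 1))
    stop("synthetic_scale_config: target_fill must be in (0, 1)")
  if (!(grey_material < grey_air))
    stop("synthetic_scale_config: grey_material must be < grey_air")
  if (noise_sigma < 0)
    stop("synthetic_scale_config: noise_sigma must be >= 0")
  structure(list(shape = as.integer(shape), pitch_nm = pitch_nm,
                 target_fill = target_fill,
                 correlation_length_nm = correlation_length_nm,
                 cuticle_thickness_voxels = as.integer(cuticle_thickness_voxels),
                 grey_material = grey_material, grey_air = grey_air,
                 noise_sigma = noise_sigma, ring_amplitude = ring_amplitude,
                 ring_period_voxels = ring_period_voxels,
                 eight_bit = isTRUE(eight_bit), seed = as.integer(seed)),
            class = "synthetic_scale_config")
}

# Smooth white noise with a truncated Gaussian kernel by circular (FFT)
# convolution. Circular convolution keeps the field exactly stationary -
# reflecting boundaries would inflate the local variance near faces and
# deplete the core after quantile thresholding. The wrap-around correlation
# only couples voxels a full box apart and is harmless for box sizes well
# above the correlation length.
grf_smooth_fft <- function(field, sigma_vox) {
  shape <- dim(field)
  kf <- lapply(shape, function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    w <- ifelse(d <= ceiling(4 * sigma_vox),
                exp(-0.5 * d^2 / sigma_vox^2), 0)
    stats::fft(w / sum(w))
  })
  k3 <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  Re(stats::fft(stats::fft(field) * k3, inverse = TRUE)) / length(field)
}

# interior (network) region: everything between the two cuticle shells
interior_x_range <- function(shape, cuticle) {
  if (2 * cuticle >= shape[1])
    stop("cuticle shells leave no interior (2*thickness >= nx)")
  (cuticle + 1L):(shape[1] - cuticle)
}

#' Generate a ground-truth two-phase porous network
#'
#' Seeded white noise is smoothed with a Gaussian kernel of width
#' `correlation_length_nm` and thresholded at the sample quantile of the
#' interior field that yields exactly the target filling fraction, so the
#' interior fill matches `target_fill` by construction (within 1/n). A solid
#' material shell of `cuticle_thickness_voxels` is stamped on the two large
#' (x) faces. Deterministic given `config$seed`.
#'
#' For one fixed seed the material sets are nested in `target_fill`: the
#' truth at a higher fill strictly contains the truth at a lower fill
#' (level sets of the same field).
#'
#' @param config A [synthetic_scale_config()].
#' @return A [binary_volume()] (material = 0, air = 1) with the generating
#'   `config` attached as an attribute.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_scale_config"))
  shape <- config$shape
  sigma_vox <- config$correlation_length_nm / config$pitch_nm
  if (sigma_vox >= min(shape) / 2)
    stop("generate_truth: degenerate structure - correlation length (",
         sigma_vox, " voxels) must be < half the smallest dimension")
  set.seed(stage_seed(config$seed, "truth"))
  field <- array(stats::rnorm(prod(shape)), dim = shape)
  field <- grf_smooth_fft(field, sigma_vox)
  ct <- config$cuticle_thickness_voxels
  xr <- interior_x_range(shape, ct)
  q <- stats::quantile(field[xr, , ], config$target_fill, names = FALSE)
  data <- array(1L, dim = shape)
  data[xr, , ][field[xr, , ] < q] <- 0L
  if (ct > 0L) {
    data[1:ct, , ] <- 0L
    data[(shape[1] - ct + 1L):shape[1], , ] <- 0L
  }
  out <- binary_volume(data, pitch_nm = config$pitch_nm)
  attr(out, "config") <- config
  out
}

#' Render a binary truth volume to greyscale
#'
#' Material voxels are drawn at `grey_material`, air at `grey_air`; each
#' xy-slice is modulated by the concentric-ring factor
#' `1 + ring_amplitude*sin(2*pi*r/ring_period_voxels)` about the slice
#' centre (the tomographic rotation axis), then seeded additive Gaussian
#' noise is applied and, for 8-bit output, values are rounded and clipped to
#' 0-254.
#'
#' @param truth A [binary_volume()] ground truth.
#' @param config The [synthetic_scale_config()] used to generate it.
#' @return A [grey_volume()].
#' @export
render_greyscale <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_scale_config"))
  data <- as_vol_array(truth)
  shape <- dim(data)
  if (!all(shape == config$shape))
    stop("render_greyscale: truth and config shapes disagree")
  out <- ifelse(data == 0L, config$grey_material, config$grey_air)
  if (config$ring_amplitude > 0) {
    cx <- (shape[1] + 1) / 2
    cy <- (shape[2] + 1) / 2
    r <- sqrt(outer((seq_len(shape[1]) - cx)^2,
                    (seq_len(shape[2]) - cy)^2, `+`))
    ring <- 1 + config$ring_amplitude *
      sin(2 * pi * r / config$ring_period_voxels)
    out <- out * as.vector(ring)  # recycles the xy factor over z
  }
  if (config$noise_sigma > 0) {
    set.seed(stage_seed(config$seed, "render"))
    out <- out + stats::rnorm(length(out), 0, config$noise_sigma)
  }
  if (config$eight_bit) {
    out <- array(as.integer(round(pmin(pmax(out, 0), 254))), dim = shape)
  } else {
    dim(out) <- shape
  }
  grey_volume(out, pitch_nm = config$pitch_nm)
}

#' Number of overlapping scans needed to cover a sample
#'
#' One scan if the sample fits in the field of view, otherwise
#' `ceiling((length - fov) / (fov - overlap)) + 1`: consecutive scans
#' advance by `fov - overlap`.
#'
#' @param length_um Sample length along the scan axis (micrometres).
#' @param fov_um Field of view along the scan axis (micrometres).
#' @param overlap_um Overlap between consecutive scans (micrometres).
#' @return Integer scan count.
#' @examples
#' scan_count(240, 54, 10)  # 6
#' scan_count(350, 54, 10)  # 8
#' @export
scan_count <- function(length_um, fov_um, overlap_um) {
  if (fov_um <= 0) stop("scan_count: field of view must be positive")
  if (overlap_um < 0 || overlap_um >= fov_um)
    stop("scan_count: need 0 <= overlap < fov")
  if (length_um <= 0) stop("scan_count: sample length must be positive")
  if (length_um <= fov_um) return(1L)
  as.integer(ceiling((length_um - fov_um) / (fov_um - overlap_um)) + 1)
}

# laterally shift a 3-D block by integer (dx, dy), filling exposed voxels
shift_xy <- function(block, dx, dy, fill) {
  if (dx == 0 && dy == 0) return(block)
  d <- dim(block)
  out <- array(if (is.integer(block)) as.integer(fill) else fill, dim = d)
  xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
  ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
  out[xs, ys, ] <- block[xs - dx, ys - dy, , drop = FALSE]
  out
}

#' Split a volume into vertically overlapping sub-scans
#'
#' Cuts the volume into scans of `fov_voxels` frames advancing by
#' `fov_voxels - overlap_voxels`, emulating the acquisition of consecutive
#' holotomography scans from the top of the sample. Scan 1 starts at frame 1;
#' later scans may receive a seeded integer z-jitter and a seeded integer
#' lateral (x, y) shift, both bounded by the jitter arguments, emulating
#' stage repositioning. The last scan is clipped so the union of scans covers
#' the volume exactly (set `pad_last = TRUE` to air-pad it to the full field
#' of view instead). True offsets and shifts are recorded for validation.
#'
#' Defaults are the study scan geometry at 25 nm pitch: 54 um field of view
#' (2160 frames) overlapping by 10 um (400 frames).
#'
#' @param vol A [grey_volume()] (or 3-D array).
#' @param fov_voxels Frames per scan.
#' @param overlap_voxels Frames shared by consecutive scans.
#' @param lateral_jitter Bound (voxels) on the per-scan lateral shift.
#' @param seed Integer seed for the jitter draws.
#' @param z_jitter Bound (voxels) on the per-scan z-offset jitter; defaults
#'   to `lateral_jitter`.
#' @param pad_last Air-pad the final scan to `fov_voxels` frames.
#' @param fill Air grey level used for padding/exposed voxels; defaults to
#'   the volume maximum (air is the light phase).
#' @return A list of class `scan_set`: `scans` (list of [grey_volume()]),
#'   `z_offsets` (0-based true start offsets), `lateral_shifts` (n x 2
#'   integer matrix), `overlap_voxels`, `fov_voxels`, `source_z`.
#' @export
split_into_scans <- function(vol, fov_voxels = 2160, overlap_voxels = 400,
                             lateral_jitter = 0, seed = 1,
                             z_jitter = lateral_jitter, pad_last = FALSE,
                             fill = NULL) {
  data <- as_vol_array(vol)
  nz <- dim(data)[3]
  if (overlap_voxels < 0 || overlap_voxels >= fov_voxels)
    stop("split_into_scans: need 0 <= overlap < fov")
  if (nz < fov_voxels)
    stop("split_into_scans: volume z-extent shorter than the field of view")
  if (is.null(fill)) fill <- max(data)
  step <- fov_voxels - overlap_voxels
  n <- if (nz <= fov_voxels) 1L
       else as.integer(ceiling((nz - fov_voxels) / step) + 1)
  set.seed(stage_seed(seed, "split"))
  zj <- c(0L, if (n > 1) sample(-z_jitter:z_jitter, n - 1, replace = TRUE))
  sh <- cbind(c(0L, if (n > 1) sample(-lateral_jitter:lateral_jitter,
                                      n - 1, replace = TRUE)),
              c(0L, if (n > 1) sample(-lateral_jitter:lateral_jitter,
                                      n - 1, replace = TRUE)))
  offsets <- pmin(pmax((seq_len(n) - 1L) * step + zj, 0L), nz - 1L)
  scans <- vector("list", n)
  for (k in seq_len(n)) {
    len <- min(fov_voxels, nz - offsets[k])
    block <- data[, , (offsets[k] + 1L):(offsets[k] + len), drop = FALSE]
    if (pad_last && len < fov_voxels) {
      padded <- array(if (is.integer(data)) as.integer(fill) else fill,
                      dim = c(dim(data)[1:2], fov_voxels))
      padded[, , seq_len(len)] <- block
      block <- padded
    }
    scans[[k]] <- grey_volume(shift_xy(block, sh[k, 1], sh[k, 2], fill),
                              pitch_nm = vol_pitch(vol))
  }
  structure(list(scans = scans, z_offsets = as.integer(offsets),
                 lateral_shifts = sh, overlap_voxels = as.integer(overlap_voxels),
                 fov_voxels = as.integer(fov_voxels), source_z = nz,
                 fill = fill),
            class = "scan_set")
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set> %d scans, fov %d frames, overlap %d frames\n",
              length(x$scans), x$fov_voxels, x$overlap_voxels))
  cat("  true z offsets:", paste(x$z_offsets, collapse = ", "), "\n")
  invisible(x)
}
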