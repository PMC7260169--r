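#' Nominal number of common frames between consecutive scans
#'
#' `overlap_um * 1000 / pitch_nm`, which must be integral: 10 um overlap at
#' 25 nm pitch gives 400 common frames.
#'
#' @param overlap_um Scan overlap in micrometres.
#' @param pitch_nm Voxel pitch in nanometres.
#' @return Integer frame count.
#' @export
nominal_overlap_frames <- function(overlap_um, pitch_nm = 25) {
  if (pitch_nm <= 0) stop("nominal_overlap_frames: pitch must be positive")
  if (overlap_um < 0) stop("nominal_overlap_frames: overlap must be >= 0")
  x <- overlap_um * 1000 / pitch_nm
  if (abs(x - round(x)) > 1e-6)
    stop("nominal_overlap_frames: overlap of ", overlap_um,
         " um is not an integer number of ", pitch_nm, " nm frames")
  as.integer(round(x))
}

ncc_frames <- function(fa, fb) {
  if (stats::sd(fa) == 0 || stats::sd(fb) == 0) return(NA_real_)
  stats::cor(as.vector(fa), as.vector(fb))
}

#' Locate the common frame between two overlapping scans
#'
#' Automates overlap-frame selection: the centre frame of scan A's overlap
#' region (its last `nominal_frames` frames) is compared by normalized
#' cross-correlation against candidate frames of scan B within
#' `search_window` frames of the nominal position, over lateral shifts
#' within `lateral_window` voxels. The best-scoring candidate wins; ties are
#' broken by smallest deviation from the nominal offset, then smallest
#' `|dx|+|dy|`, then lowest candidate frame. The score is invariant to
#' affine intensity rescaling of either scan.
#'
#' `z_offset` is the estimated start offset of B relative to A's start
#' (frames); `lateral_shift` is the `(dx, dy)` translation that aligns B's
#' content to A. With `nominal_frames = 0` the scans are assumed nominally
#' coincident and A's centre frame is matched.
#'
#' @param scan_a,scan_b [grey_volume()] objects sharing xy shape.
#' @param nominal_frames Theoretical common-frame count
#'   (see [nominal_overlap_frames()]).
#' @param search_window Half-width of the z search (frames).
#' @param lateral_window Half-width of the lateral search (voxels).
#' @return A list of class `overlap_match` with `z_offset`, `lateral_shift`,
#'   `score`, `nominal_frames` and the windows used.
#' @export
find_overlap <- function(scan_a, scan_b, nominal_frames,
                         search_window = 100, lateral_window = 20) {
  a <- as_vol_array(scan_a)
  b <- as_vol_array(scan_b)
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop("find_overlap: scans must share xy shape")
  nza <- dim(a)[3]; nzb <- dim(b)[3]
  if (nominal_frames >= nza || nominal_frames >= nzb)
    stop("find_overlap: nominal_frames must be < both z-extents")
  if (nominal_frames > 0) {
    off0 <- nza - nominal_frames
    ca <- off0 + as.integer(ceiling(nominal_frames / 2))
  } else {
    off0 <- 0L
    ca <- as.integer(ceiling(nza / 2))
  }
  fa <- a[, , ca]
  if (stats::sd(fa) == 0)
    stop("find_overlap: no texture in the reference overlap frame")
  j0 <- ca - off0
  dzs <- -search_window:search_window
  dxy <- -lateral_window:lateral_window
  cand <- expand.grid(dz = dzs, dx = dxy, dy = dxy)
  cand <- cand[cand$dz + j0 >= 1 & cand$dz + j0 <= nzb, , drop = FALSE]
  if (nrow(cand) == 0)
    stop("find_overlap: search window contains no valid frames")
  nx <- dim(a)[1]; ny <- dim(a)[2]
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    dz <- cand$dz[i]; dx <- cand$dx[i]; dy <- cand$dy[i]
    fb <- b[, , j0 + dz]
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)
    ncc_frames(fa[xs, ys], fb[xs - dx, ys - dy])
  }, numeric(1))
  if (all(is.na(scores)))
    stop("find_overlap: all candidate frames are constant (no texture)")
  ord <- order(-scores, abs(cand$dz), abs(cand$dx) + abs(cand$dy),
               cand$dz + j0, na.last = TRUE)
  best <- ord[1]
  structure(list(z_offset = as.integer(ca - (j0 + cand$dz[best])),
                 lateral_shift = c(dx = as.integer(cand$dx[best]),
                                   dy = as.integer(cand$dy[best])),
                 score = scores[best],
                 nominal_frames = as.integer(nominal_frames),
                 search_window = as.integer(search_window),
                 lateral_window = as.integer(lateral_window)),
            class = "overlap_match")
}

#' @export
print.overlap_match <- function(x, ...) {
  cat(sprintf("<overlap_match> z_offset %d, shift (%d, %d), score %.4f\n",
              x$z_offset, x$lateral_shift[1], x$lateral_shift[2], x$score))
  invisible(x)
}

#' Stitch overlapping scans into one matrix
#'
#' Scans are laterally aligned using the cumulative matched shifts and
#' concatenated along z with the seam of each junction at the centre of the
#' matched overlap region (frame `offset_{k+1} + nominal/2`), avoiding the
#' artefact-prone extreme top and bottom frames of each scan. Voxels shifted
#' outside any scan's footprint are filled with the air grey level. The
#' output z-extent is the last scan's matched offset plus its length.
#'
#' @param scans A `scan_set` (see [split_into_scans()]) or list of
#'   [grey_volume()] scans.
#' @param matches List of [find_overlap()] results for consecutive pairs
#'   (length `n - 1`).
#' @param fill Air grey level for exposed voxels (default: maximum value
#'   over the scans).
#' @return A [grey_volume()] with a `stitch_plan` attribute recording
#'   offsets, seams and scores.
#' @export
stitch <- function(scans, matches, fill = NULL) {
  scan_list <- if (inherits(scans, "scan_set")) scans$scans else scans
  n <- length(scan_list)
  if (n == 0) stop("stitch: no scans")
  arrs <- lapply(scan_list, as_vol_array)
  xy <- dim(arrs[[1]])[1:2]
  if (!all(vapply(arrs, function(a) all(dim(a)[1:2] == xy), logical(1))))
    stop("stitch: inconsistent xy shapes")
  if (n > 1 && length(matches) != n - 1)
    stop("stitch: need one match per consecutive pair")
  if (is.null(fill)) fill <- max(vapply(arrs, max, numeric(1)))
  offs <- integer(n); offs[1] <- 0L
  cum_sh <- matrix(0L, n, 2)
  if (n > 1) for (k in 1:(n - 1)) {
    offs[k + 1] <- offs[k] + matches[[k]]$z_offset
    cum_sh[k + 1, ] <- cum_sh[k, ] + matches[[k]]$lateral_shift
    if (offs[k + 1] <= offs[k])
      stop("stitch: non-increasing z offsets at junction ", k)
  }
  nzs <- vapply(arrs, function(a) dim(a)[3], integer(1))
  total_z <- offs[n] + nzs[n]
  seams <- integer(n)
  if (n > 1) for (k in 1:(n - 1)) {
    s <- offs[k + 1] + matches[[k]]$nominal_frames %/% 2L
    seams[k] <- min(max(s, offs[k + 1]), offs[k] + nzs[k])
  }
  seams[n] <- total_z
  if (n > 1 && any(diff(seams) <= 0))
    stop("stitch: seams do not strictly increase along z")
  is_int <- all(vapply(arrs, is.integer, logical(1)))
  out <- array(if (is_int) as.integer(fill) else fill,
               dim = c(xy, total_z))
  lo <- 1L
  for (k in seq_len(n)) {
    block <- shift_xy(arrs[[k]], cum_sh[k, 1], cum_sh[k, 2], fill)
    hi <- seams[k]
    out[, , lo:hi] <- block[, , (lo - offs[k]):(hi - offs[k]), drop = FALSE]
    lo <- hi + 1L
  }
  res <- grey_volume(out, pitch_nm = vol_pitch(scan_list[[1]]))
  attr(res, "stitch_plan") <- list(
    z_offsets = offs, seams = seams, lateral_shifts = cum_sh,
    scores = if (n > 1) vapply(matches, `[[`, numeric(1), "score") else numeric(0))
  res
}

#' Estimate small mounting-tilt angles of the dominant object
#'
#' Takes the below-median voxels (the dark material phase), closes the
#' porous texture by smoothing the material indicator (`envelope_sigma`
#' voxels) and thresholding at 0.5 to obtain the solid envelope of the
#' scale, then computes the second-moment (covariance) tensor of the
#' envelope coordinates and returns the Euler angles (degrees,
#' `Rz Ry Rx` convention, as used by [rotate_volume()]) that align the
#' object's principal axes with the grid axes - i.e. the correction to
#' apply. The object must sit inside the volume (tilt is unobservable for
#' material that fills the grid); a volume whose dark phase is spread like
#' the whole grid is rejected.
#'
#' @param vol A [grey_volume()] (or 3-D array).
#' @param envelope_sigma Gaussian width (voxels) used to close the porous
#'   texture before taking moments.
#' @return Named numeric vector `c(theta_x, theta_y, theta_z)` in degrees.
#' @export
estimate_tilt <- function(vol, envelope_sigma = 5) {
  data <- as_vol_array(vol)
  d <- dim(data)
  # midpoint between the dark (material) and light (air) levels; robust to
  # noise and ring modulation, unlike the median of an air-dominated volume
  q <- stats::quantile(data, c(0.05, 0.95), names = FALSE)
  sel <- data < (q[1] + q[2]) / 2
  if (sum(sel) < 30)
    stop("estimate_tilt: too few dark voxels to define an object")
  ind <- array(0, d)
  ind[sel] <- 1
  sm <- gaussian_smooth_cpp(ind, d, envelope_sigma, 4)
  # cut well below the interior plateau (but above the empty surround),
  # then close the porous interior by filling every x-column between its
  # first and last material voxel: the scale is a shell-bounded slab, thin
  # along x, and the solid slab gives clean, texture-free moments
  core <- sel & (sm > 0.25 * stats::median(sm[sel]))
  dim(core) <- c(d[1], d[2] * d[3])
  first <- apply(core, 2, match, x = TRUE)
  last <- d[1] + 1L - apply(core[d[1]:1, , drop = FALSE], 2, match, x = TRUE)
  first[is.na(first)] <- d[1] + 1L  # empty column: no span
  last[is.na(last)] <- 0L
  xs <- seq_len(d[1])
  env <- outer(xs, first, `>=`) & outer(xs, last, `<=`)
  dim(env) <- d
  if (sum(env) < 30)
    stop("estimate_tilt: dark phase too sparse to form an envelope")
  coords <- which(env, arr.ind = TRUE)
  cs <- stats::cov(coords)
  c0 <- diag((d^2 - 1) / 12)  # covariance of a uniform grid
  rel <- norm(cs - c0, "F") / norm(c0, "F")
  if (rel < 0.05)
    stop("estimate_tilt: no dominant object (dark phase fills the volume ",
         "like a uniform field)")
  ev <- eigen(cs, symmetric = TRUE)$vectors
  axis_of <- apply(abs(ev), 2, which.max)
  if (anyDuplicated(axis_of))
    stop("estimate_tilt: ambiguous principal axes")
  m <- matrix(0, 3, 3)
  for (j in 1:3) {
    v <- ev[, j]
    if (v[axis_of[j]] < 0) v <- -v
    m[, axis_of[j]] <- v
  }
  r <- t(m)  # correction rotation
  theta_y <- asin(min(max(-r[3, 1], -1), 1))
  theta_x <- atan2(r[3, 2], r[3, 3])
  theta_z <- atan2(r[2, 1], r[1, 1])
  c(theta_x = theta_x, theta_y = theta_y, theta_z = theta_z) * 180 / pi
}

#' Rotate a volume about its centre
#'
#' Applies `Rz(theta_z) Ry(theta_y) Rx(theta_x)` about the volume centre,
#' sampling with cubic convolution by default (nearest-neighbour and
#' trilinear are available); positions falling outside the input are filled
#' with the air grey level. Shape is preserved. For 8-bit input the result
#' is rounded and clipped back to 0-254.
#'
#' @param vol A [grey_volume()] (or 3-D array).
#' @param angles Numeric length-3, degrees `(theta_x, theta_y, theta_z)`.
#' @param order Interpolation: `"nearest"`, `"linear"` or `"cubic"`.
#' @param fill Fill value for out-of-bounds samples (default: volume
#'   maximum, the light air phase).
#' @return A [grey_volume()] of the same shape.
#' @export
rotate_volume <- function(vol, angles, order = c("cubic", "linear", "nearest"),
                          fill = NULL) {
  order <- match.arg(order)
  data <- as_vol_array(vol)
  if (length(angles) != 3 || any(!is.finite(angles)))
    stop("rotate_volume: `angles` must be 3 finite degrees")
  if (is.null(fill)) fill <- max(data)
  iord <- c(nearest = 0L, linear = 1L, cubic = 3L)[[order]]
  was_int <- is.integer(data)
  out <- rotate_volume_cpp(if (was_int) array(as.numeric(data), dim(data))
                           else data,
                           dim(data), angles[1], angles[2], angles[3],
                           iord, as.numeric(fill))
  if (was_int)
    out <- array(as.integer(round(pmin(pmax(out, 0), 254))), dim(data))
  grey_volume(out, pitch_nm = vol_pitch(vol))
}
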