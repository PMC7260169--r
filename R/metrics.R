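#' Filling fraction of a binary volume
#'
#' Percent of material (0) voxels: `100 * n_material / n_total`. Invariant
#' under axis permutation and reflection.
#'
#' @param mask A [binary_volume()], cube sample, or 3-D array of 0/1.
#' @return Percent material.
#' @export
fill_fraction <- function(mask) {
  data <- if (inherits(mask, "cube_sample")) mask$data else as_vol_array(mask)
  100 * mean(data == 0)
}

#' Filling fraction of the interior region
#'
#' [fill_fraction()] restricted to the volume minus a margin on every face
#' (per-axis margins allowed), used to exclude the cuticle shell and edge
#' effects when quoting the internal-network fill.
#'
#' @param mask A [binary_volume()] or 3-D array.
#' @param margin Scalar or length-3 margin in voxels
#'   (`(x, y, z)`, applied to both faces of each axis).
#' @return Percent material in the interior box.
#' @export
interior_fill_fraction <- function(mask, margin) {
  data <- as_vol_array(mask)
  d <- dim(data)
  m <- rep_len(as.integer(margin), 3L)
  if (any(2L * m >= d)) stop("interior_fill_fraction: margin leaves no interior")
  100 * mean(data[(m[1] + 1):(d[1] - m[1]),
                  (m[2] + 1):(d[2] - m[2]),
                  (m[3] + 1):(d[3] - m[3])] == 0)
}

#' Sample random interior cubes from a mask
#'
#' Draws `n` cube corners uniformly at random (seeded; overlaps permitted)
#' such that each cube of edge `edge` lies fully inside the volume minus
#' `interior_margin`, excluding the cuticle and edges so the cubes sample
#' the internal structure only.
#'
#' @param mask A [binary_volume()] or 3-D array.
#' @param edge Cube edge length in voxels (default 200 = 5 um at 25 nm).
#' @param n Number of cubes (default 275).
#' @param seed Integer seed for the corner draws.
#' @param interior_margin Scalar or length-3 margin in voxels.
#' @return A list of class `cube_samples`; each element is a `cube_sample`
#'   with `corner`, `edge` and `data`.
#' @export
sample_cubes <- function(mask, edge = 200, n = 275, seed = 1,
                         interior_margin = 100) {
  data <- as_vol_array(mask)
  d <- dim(data)
  m <- rep_len(as.integer(interior_margin), 3L)
  lo <- m + 1L
  hi <- d - m - as.integer(edge) + 1L
  if (any(hi < lo))
    stop("sample_cubes: infeasible geometry - no interior position for a ",
         edge, "-voxel cube inside margins (", paste(m, collapse = ", "), ")")
  set.seed(stage_seed(seed, "cubes"))
  corners <- cbind(
    lo[1] + sample.int(hi[1] - lo[1] + 1L, n, replace = TRUE) - 1L,
    lo[2] + sample.int(hi[2] - lo[2] + 1L, n, replace = TRUE) - 1L,
    lo[3] + sample.int(hi[3] - lo[3] + 1L, n, replace = TRUE) - 1L)
  cubes <- lapply(seq_len(n), function(i) {
    co <- corners[i, ]
    structure(list(corner = co, edge = as.integer(edge),
                   data = data[co[1]:(co[1] + edge - 1L),
                               co[2]:(co[2] + edge - 1L),
                               co[3]:(co[3] + edge - 1L)]),
              class = "cube_sample")
  })
  structure(cubes, class = "cube_samples", seed = as.integer(seed))
}

#' Fill statistics over sampled cubes
#'
#' Mean and sample standard deviation of the per-cube filling fractions -
#' the "mean +/- spread" convention behind quoted fills such as 31 +/- 2%.
#'
#' @param cubes A `cube_samples` list from [sample_cubes()] (or any list of
#'   binary cubes).
#' @return A list of class `fill_stats`: `mean`, `sd` (percent), `n`,
#'   `fills` (per-cube values), `seed`.
#' @export
fill_stats <- function(cubes) {
  if (length(cubes) < 2) stop("fill_stats: need at least 2 cubes")
  fills <- vapply(cubes, fill_fraction, numeric(1))
  structure(list(mean = mean(fills), sd = stats::sd(fills),
                 n = length(fills), fills = fills,
                 seed = attr(cubes, "seed")),
            class = "fill_stats")
}

#' @export
print.fill_stats <- function(x, ...) {
  cat(sprintf("<fill_stats> %.1f +/- %.1f%% material over %d cubes\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Directional two-point correlation function
#'
#' `S2(r)`: the fraction of voxel pairs separated by lag `r` along a
#' lattice direction with both voxels in the material phase, over all
#' in-bounds pairs (no wrap-around; the cubes are physical samples, not
#' periodic cells). `S2(0)` equals the material fraction, and
#' `0 <= S2(r) <= S2(0)`.
#'
#' @param cube A `cube_sample`, [binary_volume()] or 3-D 0/1 array.
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param r_max Maximum lag (must be below the cube extent along
#'   `direction`).
#' @return A `data.frame` of class `correlation_curve` with columns `lag`
#'   and `s2` and a `direction` attribute.
#' @export
directional_correlation <- function(cube, direction = c("x", "y", "z"),
                                    r_max) {
  direction <- match.arg(direction)
  data <- if (inherits(cube, "cube_sample")) cube$data else as_vol_array(cube)
  axis <- match(direction, c("x", "y", "z"))
  n <- dim(data)[axis]
  if (r_max >= n)
    stop("directional_correlation: r_max must be < the cube extent")
  m <- data == 0
  s2 <- numeric(r_max + 1)
  s2[1] <- mean(m)
  if (r_max >= 1) for (r in 1:r_max) {
    idx1 <- 1:(n - r)
    idx2 <- (1 + r):n
    pairs <- switch(axis,
                    m[idx1, , , drop = FALSE] & m[idx2, , , drop = FALSE],
                    m[, idx1, , drop = FALSE] & m[, idx2, , drop = FALSE],
                    m[, , idx1, drop = FALSE] & m[, , idx2, drop = FALSE])
    s2[r + 1] <- sum(pairs) / length(pairs)
  }
  structure(data.frame(lag = 0:r_max, s2 = s2),
            class = c("correlation_curve", "data.frame"),
            direction = direction)
}

#' Select the representative cube
#'
#' Computes each cube's directional correlation functions along x, y and z,
#' averages them across cubes per direction, scores each cube by the mean
#' (over directions and lags) squared deviation from the average curves,
#' and returns the index of the least-MSE cube - the sub-volume whose
#' structure best represents the sampled population. Ties break to the
#' lowest index.
#'
#' @param cubes A `cube_samples` list (or list of binary cubes of equal
#'   edge).
#' @param r_max Maximum lag; default 100 voxels (2.5 um at 25 nm pitch),
#'   capped below the cube edge.
#' @return The winning index (integer) with attributes `scores` (per-cube
#'   MSE) and `avg_curves` (named list of average `S2` vectors).
#' @export
representative_cube <- function(cubes, r_max = NULL) {
  if (length(cubes) < 1) stop("representative_cube: need at least 1 cube")
  edge <- min(vapply(cubes, function(cb) {
    d <- dim(if (inherits(cb, "cube_sample")) cb$data else as_vol_array(cb))
    min(d)
  }, numeric(1)))
  if (is.null(r_max)) r_max <- min(100L, edge - 1L)
  dirs <- c("x", "y", "z")
  curves <- lapply(dirs, function(dd)
    t(vapply(cubes,
             function(cb) directional_correlation(cb, dd, r_max)$s2,
             numeric(r_max + 1))))
  names(curves) <- dirs
  avg <- lapply(curves, colMeans)
  per_dir <- vapply(dirs, function(dd)
    rowMeans((curves[[dd]] - matrix(avg[[dd]], nrow = length(cubes),
                                    ncol = r_max + 1, byrow = TRUE))^2),
    numeric(length(cubes)))
  scores <- rowMeans(matrix(per_dir, nrow = length(cubes)))
  idx <- which.min(scores)
  structure(as.integer(idx), scores = as.numeric(scores), avg_curves = avg)
}
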