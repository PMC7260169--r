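#' Greyscale volume container
#'
#' A dense 3-D scalar field with voxel-pitch metadata. Axes are ordered
#' `(x, y, z)` with `z` the scan/length axis. Values are either 8-bit
#' integers in `0..254` (the convention of reconstructed holotomography
#' volumes) or reals, typically on the unit interval after normalization.
#'
#' @param data A 3-D numeric or integer array.
#' @param pitch_nm Voxel edge length in nanometres (default 25).
#' @return An object of class `grey_volume` with fields `data` and `pitch_nm`.
#' @examples
#' v <- grey_volume(array(0L, c(4, 4, 4)))
#' dim(v)
#' @export
grey_volume <- function(data, pitch_nm = 25) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("grey_volume: `data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("grey_volume: all dimensions must be >= 1")
  if (!is.numeric(data)) stop("grey_volume: `data` must be numeric")
  if (!is.numeric(pitch_nm) || length(pitch_nm) != 1L || pitch_nm <= 0)
    stop("grey_volume: `pitch_nm` must be a positive scalar")
  if (is.integer(data) && length(data) && max(data, na.rm = TRUE) > 254L)
    warning("grey_volume: 8-bit volume contains values > 254 ",
            "(convention is 0-254); keeping them as-is")
  structure(list(data = data, pitch_nm = as.numeric(pitch_nm)),
            class = "grey_volume")
}

#' Binary (two-phase) volume container
#'
#' A 3-D volume thresholded into material and air, with the fixed on-disk
#' polarity `material = 0`, `air = 1`.
#'
#' @param data A 3-D array containing only 0 and 1 (material = 0, air = 1).
#' @param pitch_nm Voxel edge length in nanometres (default 25).
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, pitch_nm = 25) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("binary_volume: `data` must be a 3-D array")
  if (any(dim(data) < 1L)) stop("binary_volume: all dimensions must be >= 1")
  if (!all(data == 0 | data == 1))
    stop("binary_volume: polarity violation - values must be exactly 0 ",
         "(material) or 1 (air)")
  if (!is.numeric(pitch_nm) || length(pitch_nm) != 1L || pitch_nm <= 0)
    stop("binary_volume: `pitch_nm` must be a positive scalar")
  storage.mode(data) <- "integer"
  structure(list(data = data, pitch_nm = as.numeric(pitch_nm)),
            class = "binary_volume")
}

#' @export
dim.grey_volume <- function(x) dim(x$data)

#' @export
dim.binary_volume <- function(x) dim(x$data)

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<grey_volume> %d x %d x %d voxels, pitch %g nm (%s)\n",
              d[1], d[2], d[3], x$pitch_nm,
              if (is.integer(x$data)) "8-bit" else "float"))
  cat(sprintf("  extent %g x %g x %g um; values in [%g, %g]\n",
              d[1] * x$pitch_nm / 1000, d[2] * x$pitch_nm / 1000,
              d[3] * x$pitch_nm / 1000, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binary_volume> %d x %d x %d voxels, pitch %g nm\n",
              d[1], d[2], d[3], x$pitch_nm))
  cat(sprintf("  material (0) fraction: %.2f%%\n", fill_fraction(x)))
  invisible(x)
}

# internal: accept a bare array or a volume object, return the array
as_vol_array <- function(x) {
  if (inherits(x, "grey_volume") || inherits(x, "binary_volume")) x$data
  else if (is.array(x) && length(dim(x)) == 3L) x
  else stop("expected a 3-D array, grey_volume or binary_volume")
}

# internal: pitch of a volume-ish object, with default
vol_pitch <- function(x, default = 25) {
  if (inherits(x, "grey_volume") || inherits(x, "binary_volume")) x$pitch_nm
  else default
}
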