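#' Pack a binary volume into a bit stream
#'
#' Flattens the volume in row-major order over `(x, y, z)` (`z` fastest) and
#' packs 8 voxels per byte, most-significant-bit first, zero-padding the tail
#' of the last byte. This is the deposit convention for thresholded matrices
#' (`material = 0`, `air = 1`), which unpacks with `numpy.unpackbits()`.
#'
#' @param vol A [binary_volume()] (or 3-D array of 0/1).
#' @return A list of class `packed_volume` with `bytes` (raw vector), `shape`
#'   (integer dimensions) and `pitch_nm`.
#' @seealso [unpack_binary()]
#' @export
pack_binary <- function(vol) {
  if (!inherits(vol, "binary_volume"))
    vol <- binary_volume(as_vol_array(vol))
  bits <- as.logical(aperm(vol$data, c(3L, 2L, 1L)))
  n <- length(bits)
  pad <- (8L - n %% 8L) %% 8L
  if (pad > 0L) bits <- c(bits, logical(pad))
  m <- matrix(bits, nrow = 8L)
  bytes <- packBits(as.vector(m[8:1, , drop = FALSE]), type = "raw")
  structure(list(bytes = bytes, shape = dim(vol$data),
                 pitch_nm = vol$pitch_nm),
            class = "packed_volume")
}

#' Unpack a bit stream into a binary volume
#'
#' Inverse of [pack_binary()]: bytes are expanded most-significant-bit first
#' and reshaped in row-major order over `(x, y, z)`.
#'
#' @param bytes Raw vector (or a `packed_volume`, in which case `shape` is
#'   taken from it).
#' @param shape Integer vector of length 3, the voxel dimensions.
#' @param pitch_nm Voxel pitch in nanometres.
#' @return A [binary_volume()].
#' @export
unpack_binary <- function(bytes, shape = NULL, pitch_nm = 25) {
  if (inherits(bytes, "packed_volume")) {
    if (is.null(shape)) shape <- bytes$shape
    pitch_nm <- bytes$pitch_nm
    bytes <- bytes$bytes
  }
  if (is.null(shape)) stop("unpack_binary: `shape` is required")
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("unpack_binary: `shape` must be 3 positive integers")
  n <- prod(shape)
  if (length(bytes) != ceiling(n / 8))
    stop(sprintf(
      "unpack_binary: shape mismatch - %d bytes cannot hold a %s volume (need %d)",
      length(bytes), paste(shape, collapse = "x"), ceiling(n / 8)))
  bits <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)
  bits <- as.vector(bits[8:1, , drop = FALSE])[seq_len(n)]
  data <- aperm(array(bits, dim = rev(shape)), c(3L, 2L, 1L))
  binary_volume(data, pitch_nm = pitch_nm)
}

#' Unpacked storage size in decimal gigabytes
#'
#' `prod(shape) * bytes_per_element / 1e9`, the convention behind the deposit
#' tables' "Size (GB)" column (decimal GB, not GiB): full greyscale and
#' thresholded matrices at 1 byte/voxel, slabs and cubes at 8 bytes/element.
#'
#' @param shape Positive integer dimensions.
#' @param bytes_per_element Bytes per stored element (1 for 8-bit, 4 for
#'   32-bit float, 8 for 64-bit float).
#' @return Size in decimal GB (unrounded; the tables print 3 significant
#'   figures).
#' @export
storage_size_gb <- function(shape, bytes_per_element = 1) {
  if (any(shape <= 0) || bytes_per_element <= 0)
    stop("storage_size_gb: shape and bytes_per_element must be positive")
  prod(as.numeric(shape)) * bytes_per_element / 1e9
}

#' Manifest entry for a stored volume
#'
#' One row describing a stored matrix the way the deposit tables do: shape in
#' voxels, physical extent in micrometres (`voxels * pitch_nm / 1000`), and
#' unpacked size in decimal GB rounded to 3 significant figures.
#'
#' @param file File name.
#' @param shape Integer dimensions (voxels).
#' @param bytes_per_element Bytes per stored element when unpacked.
#' @param pitch_nm Voxel pitch in nanometres.
#' @param type Image type tag, `"greyscale"` or `"thresholded"`.
#' @return A one-row `data.frame` with columns `file`, `nx`, `ny`, `nz`,
#'   `um_x`, `um_y`, `um_z`, `size_gb`, `type`.
#' @export
volume_manifest <- function(file, shape, bytes_per_element = 1,
                            pitch_nm = 25,
                            type = c("greyscale", "thresholded")) {
  type <- match.arg(type)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), pitch_nm > 0)
  um <- shape * pitch_nm / 1000
  data.frame(file = file, nx = shape[1], ny = shape[2], nz = shape[3],
             um_x = um[1], um_y = um[2], um_z = um[3],
             size_gb = signif(storage_size_gb(shape, bytes_per_element), 3),
             type = type, stringsAsFactors = FALSE)
}

## ---- NPY dense container --------------------------------------------------

npy_descr <- function(data, dtype) {
  if (dtype == "auto") dtype <- if (is.integer(data)) "uint8" else "float64"
  switch(dtype,
         uint8 = "|u1", float32 = "<f4", float64 = "<f8",
         stop("write_npy: unsupported dtype ", dtype))
}

#' Write an array as an NPY v1.0 file
#'
#' Shape + dtype header followed by a row-major payload
#' (`fortran_order: False`). Supported dtypes: `uint8` (used for 0-254
#' greyscale), `float32` and `float64`.
#'
#' @param data An array (any rank) or vector.
#' @param path Output path.
#' @param dtype `"auto"` (uint8 for integer storage, float64 otherwise),
#'   `"uint8"`, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(data, path, dtype = "auto") {
  con <- file(path, "wb")
  on.exit(close(con))
  write_npy_con(data, con, dtype)
  invisible(path)
}

write_npy_con <- function(data, con, dtype = "auto") {
  descr <- npy_descr(data, dtype)
  shp <- dim(data)
  if (is.null(shp)) shp <- length(data)
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%s), }",
                    descr,
                    if (length(shp) == 1L) paste0(shp, ",")
                    else paste(shp, collapse = ", "))
  total <- 10L + nchar(header) + 1L  # magic(6) + ver(2) + len(2) + header + \n
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  writeBin(c(as.raw(0x93), as.raw(utf8ToInt("NUMPY")), as.raw(1L), as.raw(0L)),
           con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  flat <- if (length(shp) > 1L) as.vector(aperm(data, rev(seq_along(shp))))
          else as.vector(data)
  if (descr == "|u1") {
    if (any(flat < 0 | flat > 255)) stop("write_npy: uint8 values out of range")
    writeBin(as.raw(flat), con)
  } else {
    writeBin(as.numeric(flat), con,
             size = if (descr == "<f4") 4L else 8L, endian = "little")
  }
  invisible(con)
}

#' Read an NPY file
#'
#' Accepts v1.0/v2.0 headers, C or Fortran order, dtypes `|u1`, `|i1`,
#' `<f4`, `<f8`.
#'
#' @param path Path to a `.npy` file (or a connection opened in `"rb"` mode).
#' @return An array (integer storage for 8-bit dtypes, double otherwise).
#' @export
read_npy <- function(path) {
  con <- if (inherits(path, "connection")) path else {
    fc <- file(path, "rb"); on.exit(close(fc)); fc
  }
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), as.raw(utf8ToInt("NUMPY")))))
    stop("read_npy: corrupt header (bad magic)")
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) == 1L)
    readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  else
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'([^']+)'$", "\\1", descr)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shp_str <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shp <- as.integer(strsplit(gsub("[^0-9,]", "", shp_str), ",")[[1]])
  n <- prod(shp)
  flat <- switch(descr,
    "|u1" = as.integer(readBin(con, "raw", n)),
    "|i1" = readBin(con, "integer", n, size = 1L),
    "<f4" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("read_npy: unsupported dtype '", descr,
         "' (need 8-bit int or 32/64-bit float)"))
  if (length(flat) != n) stop("read_npy: truncated payload")
  if (length(shp) <= 1L) return(flat)
  if (fortran) array(flat, dim = shp)
  else aperm(array(flat, dim = rev(shp)), rev(seq_along(shp)))
}

## ---- store-only zip container (NPZ-like) ----------------------------------

crc32_tab <- local({
  tab <- integer(256L)
  poly <- -306674912L  # 0xEDB88320
  for (i in 0:255) {
    cc <- i
    for (k in 1:8)
      cc <- if (bitwAnd(cc, 1L) != 0L) bitwXor(bitwShiftR(cc, 1L), poly)
            else bitwShiftR(cc, 1L)
    tab[i + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  cc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b))
    cc <- bitwXor(bitwShiftR(cc, 8L),
                  crc32_tab[bitwAnd(bitwXor(cc, b[i]), 255L) + 1L])
  bitwXor(cc, -1L)
}

# minimal store-only (no compression) zip writer; entries: named list of raw
zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  le <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  offsets <- integer(length(entries))
  crcs <- integer(length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    le(0x04034b50, 4); le(20, 2); le(0, 2); le(0, 2); le(0, 2); le(0, 2)
    le(crcs[i], 4); le(length(data), 4); le(length(data), 4)
    le(length(name), 2); le(0, 2)
    writeBin(name, con); writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    le(0x02014b50, 4); le(20, 2); le(20, 2); le(0, 2); le(0, 2)
    le(0, 2); le(0, 2)
    le(crcs[i], 4); le(length(data), 4); le(length(data), 4)
    le(length(name), 2); le(0, 2); le(0, 2); le(0, 2); le(0, 2); le(0, 4)
    le(offsets[i], 4)
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  le(0x06054b50, 4); le(0, 2); le(0, 2)
  le(length(entries), 2); le(length(entries), 2)
  le(pos - cd_start, 4); le(cd_start, 4); le(0, 2)
  invisible(path)
}

serialize_npy <- function(data, dtype = "auto") {
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  write_npy_con(data, con, dtype)
  rawConnectionValue(con)
}

#' Write an array into a single-entry zip archive
#'
#' The array is serialized as NPY and stored (uncompressed) in a zip wrapper
#' under the conventional key `arr_0.npy`, mirroring the deposit's zipped
#' single-array containers.
#'
#' @param data Array to store.
#' @param path Output `.npz`/`.zip` path.
#' @param dtype Passed to [write_npy()].
#' @param name Entry name inside the archive.
#' @return `path`, invisibly.
#' @export
write_npz <- function(data, path, dtype = "auto", name = "arr_0.npy") {
  entries <- list(serialize_npy(data, dtype))
  names(entries) <- name
  zip_store(entries, path)
  invisible(path)
}

#' Read the single array stored in a zip archive
#'
#' Accepts any archive holding exactly one array; if several entries are
#' present, the conventional default key `arr_0.npy` is used.
#'
#' @param path Path to the archive.
#' @return The stored array.
#' @export
read_npz <- function(path) {
  listing <- utils::unzip(path, list = TRUE)
  entry <- if (nrow(listing) == 1L) listing$Name[1]
           else if ("arr_0.npy" %in% listing$Name) "arr_0.npy"
           else stop("read_npz: archive has multiple entries and no 'arr_0.npy'")
  exdir <- tempfile("npz")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  f <- utils::unzip(path, files = entry, exdir = exdir)
  read_npy(f)
}

## ---- TIFF stacks -----------------------------------------------------------

write_tiff_stack <- function(data, path) {
  if (!is.integer(data) || min(data) < 0L || max(data) > 255L)
    stop("write_volume: TIFF stacks are supported for 8-bit volumes only")
  slices <- lapply(seq_len(dim(data)[3]),
                   function(z) t(data[, , z]) / 255)
  tiff::writeTIFF(slices, path, bits.per.sample = 8L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_tiff_stack <- function(path) {
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  dims <- dim(slices[[1]])
  data <- array(0L, dim = c(dims[2], dims[1], length(slices)))
  for (z in seq_along(slices))
    data[, , z] <- as.integer(round(t(slices[[z]]) * 255))
  data
}

## ---- format dispatch -------------------------------------------------------

vol_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         npy = "npy", npz = "npz", zip = "npz", tif = "tiff", tiff = "tiff",
         stop("unsupported volume container extension: .", ext))
}

#' Read a greyscale volume from a supported container
#'
#' Dispatches on the file extension: `.npy` (dense array), `.npz`/`.zip`
#' (zip-wrapped single array), `.tif`/`.tiff` (one image per z-slice).
#'
#' @param path Input path.
#' @param pitch_nm Voxel pitch to attach (the containers do not carry it).
#' @return A [grey_volume()].
#' @export
read_volume <- function(path, pitch_nm = 25) {
  data <- switch(vol_format(path),
                 npy = read_npy(path),
                 npz = read_npz(path),
                 tiff = read_tiff_stack(path))
  if (length(dim(data)) != 3L)
    stop("read_volume: container does not hold a 3-D array")
  grey_volume(data, pitch_nm = pitch_nm)
}

#' Write a greyscale volume to a supported container
#'
#' Lossless round trip of data, shape and storage type for `.npy` and
#' `.npz`/`.zip`; `.tif`/`.tiff` stacks support 8-bit volumes.
#'
#' @param vol A [grey_volume()] (or 3-D array).
#' @param path Output path; the extension selects the container.
#' @param dtype For NPY/zip containers, passed to [write_npy()].
#' @return The [volume_manifest()] row for the written file, invisibly.
#' @export
write_volume <- function(vol, path, dtype = "auto") {
  data <- as_vol_array(vol)
  switch(vol_format(path),
         npy = write_npy(data, path, dtype),
         npz = write_npz(data, path, dtype),
         tiff = write_tiff_stack(data, path))
  bpe <- if (is.integer(data)) 1 else 8
  if (dtype == "float32") bpe <- 4
  invisible(volume_manifest(basename(path), dim(data), bpe,
                            pitch_nm = vol_pitch(vol), type = "greyscale"))
}

#' Write a packed binary volume (raw bits + JSON sidecar)
#'
#' The packed byte stream is written as-is; a `<path>.json` sidecar records
#' the shape, pitch and polarity needed to unpack it.
#'
#' @param vol A [binary_volume()].
#' @param path Output path for the packed bytes.
#' @return The [volume_manifest()] row, invisibly.
#' @export
write_packed <- function(vol, path) {
  pk <- pack_binary(vol)
  writeBin(pk$bytes, path)
  jsonlite::write_json(
    list(shape = pk$shape, pitch_nm = pk$pitch_nm,
         polarity = "material=0,air=1", bit_order = "msb_first",
         flatten_order = "row_major_xyz"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(volume_manifest(basename(path), pk$shape, 1,
                            pitch_nm = vol$pitch_nm, type = "thresholded"))
}

#' Read a packed binary volume written by [write_packed()]
#'
#' @param path Path to the packed bytes (the `<path>.json` sidecar must
#'   exist).
#' @return A [binary_volume()].
#' @export
read_packed <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bytes <- readBin(path, "raw", file.size(path))
  unpack_binary(bytes, shape = meta$shape, pitch_nm = meta$pitch_nm)
}
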