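# Minimal NIfTI-1 I/O.
#
# Scope: single-image 3D .nii / .nii.gz files, scalar datatypes
# (uint8/int8/int16/uint16/int32/float32/float64), scl_slope/scl_inter
# scaling, pixdim spacing, both endiannesses on read; little-endian
# float32 (volumes) or uint8 (masks) on write. Orientation metadata
# beyond pixdim (qform/sform) is not interpreted: voxel axes are taken
# as-is, with disk order (x, y, x-fastest) transposed to the package's
# (z, y, x) convention on load and back on save.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

rb <- function(raw, offset, what, n, size, endian, signed = TRUE) {
  readBin(raw[(offset + 1L):length(raw)], what = what, n = n, size = size,
          endian = endian, signed = signed)
}

#' Read a 3D NIfTI-1 image
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D numeric array in `(z, y, x)` order),
#'   `spacing` (mm triple `(z, y, x)`), and `datatype` (NIfTI code).
#' @seealso [write_nifti()], [load_volume()]
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  if (rb(hdr, 0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rb(hdr, 0L, "integer", 1L, 4L, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic,
                                        "' in ", path)
  dim0 <- rb(hdr, 40L, "integer", 8L, 2L, endian)
  ndim <- dim0[1L]
  if (ndim < 3L || (ndim > 3L && any(dim0[5:(ndim + 1L)] > 1L)))
    stop("only 3D NIfTI images are supported (dim = ",
         paste(dim0[2:(ndim + 1L)], collapse = "x"), ") in ", path)
  nx <- dim0[2L]; ny <- dim0[3L]; nz <- dim0[4L]
  datatype <- rb(hdr, 70L, "integer", 1L, 2L, endian)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  pixdim <- rb(hdr, 76L, "double", 8L, 4L, endian)
  vox_offset <- rb(hdr, 108L, "double", 1L, 4L, endian)
  scl_slope <- rb(hdr, 112L, "double", 1L, 4L, endian)
  scl_inter <- rb(hdr, 116L, "double", 1L, 4L, endian)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- as.numeric(nx) * ny * nz
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- aperm(array(as.numeric(vals), c(nx, ny, nz)), c(3L, 2L, 1L))
  sp <- pixdim[2:4]
  spacing <- if (all(is.finite(sp)) && all(sp > 0)) rev(sp) else c(1, 1, 1)
  list(data = arr, spacing = spacing, datatype = datatype)
}

#' Write a 3D array as a NIfTI-1 image
#'
#' @param data 3D numeric array in `(z, y, x)` order.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param spacing mm triple `(z, y, x)` stored in pixdim.
#' @param datatype `"float32"` (default) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  dcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L
  d <- dim(data)  # (z, y, x)
  hdr <- raw(348L)
  poke <- function(offset, values, size) {
    b <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(offset + 1L):(offset + length(b))] <<- b
    invisible(NULL)
  }
  poke(0L, 348L, 4L)
  poke(40L, as.integer(c(3L, d[3L], d[2L], d[1L], 1L, 1L, 1L, 1L)), 2L)
  poke(70L, dcode, 2L)
  poke(72L, bitpix, 2L)
  poke(76L, as.numeric(c(1, rev(spacing), 0, 0, 0, 0)), 4L)
  poke(108L, 352, 4L)          # vox_offset
  poke(112L, c(1, 0), 4L)      # scl_slope, scl_inter
  poke(252L, 1L, 2L)           # qform_code = 0 would also be fine; use 1
  b <- writeBin(charToRaw("n+1"), raw())
  hdr[345:348] <- c(b, as.raw(0L))
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)       # extension flag
  disk <- aperm(data, c(3L, 2L, 1L))  # (x, y, z), x fastest
  if (datatype == "float32") {
    writeBin(as.numeric(disk), con, size = 4L, endian = "little")
  } else {
    v <- as.integer(round(disk))
    if (any(v < 0L | v > 255L)) stop("uint8 overflow when writing ", path)
    writeBin(v, con, size = 1L, endian = "little")
  }
  invisible(path)
}

#' Load a multi-channel volume from per-channel NIfTI files
#'
#' Each channel (MRI sequence) lives in its own NIfTI file, as in the
#' BraTS layout. Channels are stacked in the order given; all files must
#' share one spatial shape. Header spacing of the first file is carried
#' into the returned volume.
#'
#' @param paths character vector, one readable NIfTI path per channel.
#' @param channel_names optional channel labels (defaults to file
#'   basenames without extension).
#' @return A [volume()].
#' @export
load_volume <- function(paths, channel_names = NULL) {
  stopifnot(length(paths) >= 1L)
  imgs <- lapply(paths, read_nifti)
  shapes <- lapply(imgs, function(im) dim(im$data))
  if (length(unique(vapply(shapes, paste, "", collapse = "x"))) != 1L)
    stop("channel files have mismatched shapes: ",
         paste(vapply(shapes, paste, "", collapse = "x"), collapse = ", "))
  if (is.null(channel_names))
    channel_names <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  sh <- shapes[[1L]]
  data <- array(0, c(length(imgs), sh))
  for (i in seq_along(imgs)) data[i, , , ] <- imgs[[i]]$data
  volume(data, channel_names, imgs[[1L]]$spacing)
}

#' Save a volume as per-channel NIfTI files
#'
#' @param v a [volume()].
#' @param paths one output path per channel.
#' @return `paths`, invisibly.
#' @export
save_volume <- function(v, paths) {
  stopifnot(inherits(v, "volume"), length(paths) == n_channels(v))
  sp <- if (is.null(v$spacing)) c(1, 1, 1) else v$spacing
  for (i in seq_along(paths)) {
    ch <- v$data[i, , , ]
    dim(ch) <- spatial_shape(v)
    write_nifti(ch, paths[i], spacing = sp, datatype = "float32")
  }
  invisible(paths)
}

#' Save a binary mask as NIfTI
#'
#' Written with integer (uint8) datatype. Geometry (voxel spacing) is
#' copied from `reference` when given, else from the mask itself.
#'
#' @param m a [binary_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @param reference optional `volume` or `binary_mask` supplying spacing.
#' @return `path`, invisibly.
#' @export
save_mask <- function(m, path, reference = NULL) {
  stopifnot(inherits(m, "binary_mask"))
  sp <- c(1, 1, 1)
  if (!is.null(reference) && !is.null(reference$spacing)) sp <- reference$spacing
  else if (!is.null(m$spacing)) sp <- m$spacing
  write_nifti(m$data, path, spacing = sp, datatype = "uint8")
  invisible(path)
}

#' Load a binary mask from NIfTI
#'
#' @param path NIfTI file whose voxel values are 0/1 (nonzero is
#'   foreground).
#' @return A [binary_mask()].
#' @export
load_mask <- function(path) {
  im <- read_nifti(path)
  binary_mask(array(as.integer(im$data != 0), dim(im$data)),
              spacing = im$spacing)
}
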