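#' Construct a multi-channel 3D volume
#'
#' A `volume` is the universal image currency of the package: a real-valued
#' intensity grid with axis order `(channel, z, y, x)`, an ordered set of
#' channel names (e.g. `"T1w"`, `"T1wCE"`, `"T2w"`, `"FLAIR"`), and optional
#' voxel spacing in millimetres carried through from file headers.
#'
#' @param data numeric array. Either a 4D array with dimensions
#'   `(channel, z, y, x)` or a 3D array `(z, y, x)`, which is promoted to a
#'   single-channel volume.
#' @param channel_names character vector of channel labels, one per channel.
#'   Defaults to `"ch1"`, `"ch2"`, ...
#' @param spacing optional numeric triple of voxel sizes in mm `(z, y, x)`.
#' @return An object of class `volume`.
#' @examples
#' v <- volume(array(runif(2 * 8^3), c(2, 8, 8, 8)))
#' spatial_shape(v)
#' @export
volume <- function(data, channel_names = NULL, spacing = NULL) {
  if (!is.array(data) && !is.numeric(data))
    stop("`data` must be a numeric array")
  if (length(dim(data)) == 3L) dim(data) <- c(1L, dim(data))
  if (length(dim(data)) != 4L)
    stop("`data` must be a 3D (z,y,x) or 4D (channel,z,y,x) array")
  nc <- dim(data)[1L]
  if (nc < 1L) stop("channel count must be >= 1")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("length(channel_names) [", length(channel_names),
         "] does not match channel count [", nc, "]")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    stopifnot(length(spacing) == 3L, all(spacing > 0))
  }
  structure(list(data = data, channel_names = as.character(channel_names),
                 spacing = spacing),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<volume> ", d[1L], " channel(s) [",
      paste(x$channel_names, collapse = ", "), "], spatial ",
      paste(d[-1L], collapse = "x"),
      if (!is.null(x$spacing))
        paste0(", spacing ", paste(signif(x$spacing, 4), collapse = "x"), " mm"),
      "\n", sep = "")
  invisible(x)
}

#' Spatial shape of a volume or mask
#'
#' @param x a `volume` or `binary_mask`.
#' @return Integer triple `(z, y, x)`.
#' @export
spatial_shape <- function(x) {
  if (inherits(x, "volume")) return(dim(x$data)[-1L])
  if (inherits(x, "binary_mask")) return(dim(x$data))
  stop("`x` must be a volume or binary_mask")
}

#' Number of channels of a volume
#' @param v a `volume`.
#' @return Integer.
#' @export
n_channels <- function(v) {
  stopifnot(inherits(v, "volume"))
  dim(v$data)[1L]
}

#' Construct a binary voxel mask
#'
#' A `binary_mask` is a `{0,1}` grid over one spatial shape `(z, y, x)` with
#' no channel axis. It is the carrier for superpixel-derived segmentations
#' and reference annotations, i.e. the X and Y of the Dice coefficient.
#'
#' @param data 3D array whose values are exactly 0 or 1 (logical arrays are
#'   coerced).
#' @param spacing optional mm triple, as in [volume()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = NULL) {
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D (z,y,x) array")
  if (!all(data == 0 | data == 1))
    stop("mask values must be exactly 0 or 1")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = "x"), ", ",
      sum(x$data), " foreground voxel(s)\n", sep = "")
  invisible(x)
}

#' Per-channel min-max normalization
#'
#' Each channel is normalized independently to `[0, 1]`:
#' `(x - min) / (max - min)`. A constant channel (max == min) maps to all
#' zeros, preserving "no signal" semantics while keeping the function total.
#'
#' @param v a `volume`.
#' @return A `volume` with every channel in `[0, 1]`.
#' @export
normalize_minmax <- function(v) {
  stopifnot(inherits(v, "volume"))
  d <- v$data
  for (c in seq_len(dim(d)[1L])) {
    ch <- d[c, , , , drop = FALSE]
    lo <- min(ch); hi <- max(ch)
    d[c, , , ] <- if (hi > lo) (ch - lo) / (hi - lo) else 0
  }
  volume(d, v$channel_names, v$spacing)
}

#' Center crop of a volume
#'
#' Extracts the centered sub-volume of the given spatial shape, identically
#' on all channels. For an odd size difference the offset is
#' `floor((size - crop) / 2)` (0-based, half-open intervals), so the extra
#' voxel is dropped from the high side.
#'
#' @param v a `volume`.
#' @param crop_shape integer triple `(z, y, x)`; must not exceed the spatial
#'   shape in any dimension.
#' @return The cropped `volume`.
#' @export
center_crop <- function(v, crop_shape) {
  stopifnot(inherits(v, "volume"))
  crop_shape <- as.integer(crop_shape)
  stopifnot(length(crop_shape) == 3L, all(crop_shape >= 1L))
  sh <- spatial_shape(v)
  if (any(crop_shape > sh))
    stop("crop_shape (", paste(crop_shape, collapse = "x"),
         ") exceeds spatial shape (", paste(sh, collapse = "x"), ")")
  off <- (sh - crop_shape) %/% 2L
  idx <- lapply(1:3, function(i) seq.int(off[i] + 1L, off[i] + crop_shape[i]))
  volume(v$data[, idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE],
         v$channel_names, v$spacing)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of the relevance-map pipeline. Defaults
#' follow the published setup: 100 requested superpixels computed on the
#' T2w sequence, with blank perturbation as the naive baseline.
#'
#' @param n_superpixels_requested positive integer, superpixels requested
#'   from SLIC (the realized count K may be lower).
#' @param compactness positive real, SLIC intensity/space trade-off on
#'   normalized intensities.
#' @param superpixel_channel channel name or 1-based index on which
#'   superpixels are computed.
#' @param perturbation_kind one of `"blank"`, `"min"`, `"max"`, `"optimal"`.
#' @param seed integer master seed; all stage seeds are derived from it.
#' @param crop_shape spatial triple for [center_crop()], or `NULL` to skip
#'   cropping.
#' @param normalize_order `"after_crop"` (default) or `"before_crop"`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_superpixels_requested = 100L,
                            compactness = 0.1,
                            superpixel_channel = "T2w",
                            perturbation_kind = c("blank", "min", "max", "optimal"),
                            seed = 1L,
                            crop_shape = NULL,
                            normalize_order = c("after_crop", "before_crop")) {
  perturbation_kind <- match.arg(perturbation_kind)
  normalize_order <- match.arg(normalize_order)
  stopifnot(n_superpixels_requested >= 1L, compactness > 0)
  structure(list(n_superpixels_requested = as.integer(n_superpixels_requested),
                 compactness = compactness,
                 superpixel_channel = superpixel_channel,
                 perturbation_kind = perturbation_kind,
                 seed = as.integer(seed),
                 crop_shape = if (!is.null(crop_shape)) as.integer(crop_shape),
                 normalize_order = normalize_order),
            class = "pipeline_config")
}

#' Resolve a channel name or index against a volume
#' @param v a `volume`.
#' @param channel channel name or 1-based index.
#' @return 1-based integer channel index.
#' @export
resolve_channel <- function(v, channel) {
  stopifnot(inherits(v, "volume"))
  if (is.character(channel)) {
    i <- match(channel, v$channel_names)
    if (is.na(i)) stop("unknown channel name: ", channel)
    return(i)
  }
  i <- as.integer(channel)
  if (i < 1L || i > n_channels(v)) stop("channel index out of range: ", i)
  i
}

# Deterministic substream seeds: all stage randomness flows from one master
# seed through this map. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stream, index = 0L) {
  sid <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + sid * 16807 + as.numeric(index) * 69621) %%
               2147483647)
}
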