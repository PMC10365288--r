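# Naive perturbation operators and the generic multiplicative-mask
# application. All perturbations are local: identity outside the target
# region, enforced structurally.

check_region <- function(v, region) {
  stopifnot(inherits(v, "volume"), inherits(region, "binary_mask"))
  if (!identical(spatial_shape(v), dim(region$data)))
    stop("volume and region shapes differ")
}

#' Blank perturbation
#'
#' Turns off all voxels in the region by replacing their intensity with
#' zero, on every channel.
#'
#' @param v a [volume()].
#' @param region a [binary_mask()] of the same spatial shape.
#' @return The perturbed [volume()].
#' @export
perturb_blank <- function(v, region) {
  check_region(v, region)
  keep <- region$data == 0L
  d <- v$data
  for (c in seq_len(dim(d)[1L])) d[c, , , ] <- d[c, , , ] * keep
  volume(d, v$channel_names, v$spacing)
}

perturb_extremum <- function(v, region, fun) {
  check_region(v, region)
  inside <- region$data == 1L
  if (!any(inside)) stop("empty region: local extremum undefined")
  d <- v$data
  for (c in seq_len(dim(d)[1L])) {
    ch <- d[c, , , ]
    ch[inside] <- fun(ch[inside])   # per-channel local extremum
    d[c, , , ] <- ch
  }
  volume(d, v$channel_names, v$spacing)
}

#' Min / max perturbation
#'
#' Replaces the region's voxels with the minimum (resp. maximum) of the
#' volume over that region, computed per channel independently — the
#' "local region" is the superpixel's own voxel set.
#'
#' @inheritParams perturb_blank
#' @return The perturbed [volume()].
#' @export
perturb_min <- function(v, region) perturb_extremum(v, region, min)

#' @rdname perturb_min
#' @export
perturb_max <- function(v, region) perturb_extremum(v, region, max)

#' Apply a multiplicative perturbation mask inside a region
#'
#' Multiplies `v` voxelwise by `mask` inside `region`; outside the region
#' the output equals `v` exactly, regardless of what the mask contains
#' there. This clamping keeps per-superpixel scores attributable to one
#' region even when a learned generator emits values everywhere.
#'
#' @param v a [volume()].
#' @param region a [binary_mask()].
#' @param mask a [volume()] with values in `[0, 1]` and the same spatial
#'   shape; either single-channel (broadcast over `v`'s channels) or one
#'   channel per channel of `v`.
#' @return The perturbed [volume()].
#' @export
apply_perturbation_mask <- function(v, region, mask) {
  check_region(v, region)
  stopifnot(inherits(mask, "volume"))
  if (!identical(spatial_shape(mask), spatial_shape(v)))
    stop("mask and volume spatial shapes differ")
  if (!(n_channels(mask) %in% c(1L, n_channels(v))))
    stop("mask must have 1 channel or match the volume's channel count")
  if (min(mask$data) < 0 || max(mask$data) > 1)
    stop("mask values must lie in [0, 1]")
  inside <- region$data == 1L
  d <- v$data
  for (c in seq_len(dim(d)[1L])) {
    mc <- if (n_channels(mask) == 1L) 1L else c
    ch <- d[c, , , ]
    m <- mask$data[mc, , , ]
    ch[inside] <- ch[inside] * m[inside]
    d[c, , , ] <- ch
  }
  volume(d, v$channel_names, v$spacing)
}

#' Dispatch a perturbation by kind
#'
#' @param v a [volume()].
#' @param region a [binary_mask()].
#' @param kind one of `"blank"`, `"min"`, `"max"`, `"optimal"`.
#' @param generator required when `kind == "optimal"`: a generator from
#'   [train_generator()] (or any object honouring
#'   [generate_optimal_mask()]).
#' @param sp_volume the extracted superpixel volume fed to the generator
#'   (computed from `v` and `region` when missing).
#' @return The perturbed [volume()].
#' @export
perturb <- function(v, region, kind = c("blank", "min", "max", "optimal"),
                    generator = NULL, sp_volume = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    blank = perturb_blank(v, region),
    min = perturb_min(v, region),
    max = perturb_max(v, region),
    optimal = {
      if (is.null(generator))
        stop("kind = 'optimal' requires a trained generator")
      if (is.null(sp_volume)) {
        check_region(v, region)
        d <- v$data
        keep <- region$data == 1L
        for (c in seq_len(dim(d)[1L])) d[c, , , ] <- d[c, , , ] * keep
        sp_volume <- volume(d, v$channel_names, v$spacing)
      }
      mask <- generate_optimal_mask(generator, sp_volume)
      apply_perturbation_mask(v, region, mask)
    })
}
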