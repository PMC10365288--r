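# 3D superpixel (supervoxel) generation: the partition every relevance
# computation iterates over.

#' Compute 3D superpixels with SLIC
#'
#' Runs SLIC-style clustering on a single configured channel (the best
#' single sequence in the published setup; here the phantom's
#' high-contrast channel by default): k-means in intensity+space with
#' distance `D^2 = dI^2 + compactness^2 * ds^2 / S^2`, followed by
#' connectivity enforcement and relabeling to contiguous `1..K` in
#' first-occurrence order. Clustering may merge similar regions, so the
#' realized count `K` can be below `requested_n`, never above.
#'
#' The implementation is fully deterministic (grid-initialized centers);
#' `seed` is accepted for interface symmetry and ignored.
#'
#' @param v a [volume()].
#' @param channel channel name or index clustered on.
#' @param requested_n requested superpixel count (>= 1, at most the voxel
#'   count).
#' @param compactness intensity/space trade-off on normalized intensities
#'   (default 0.1).
#' @param seed ignored (deterministic algorithm); kept for call symmetry.
#' @param max_iter k-means iterations (default 10).
#' @return An object of class `superpixel_map` with `labels` (integer
#'   array over the spatial shape, values `1..K`), `K`, `source_channel`,
#'   `requested_n`, `compactness`.
#' @export
compute_superpixels <- function(v, channel, requested_n, compactness = 0.1,
                                seed = NULL, max_iter = 10L) {
  stopifnot(inherits(v, "volume"), requested_n >= 1L)
  ch <- resolve_channel(v, channel)
  sh <- spatial_shape(v)
  if (requested_n > prod(sh))
    stop("requested_n (", requested_n, ") exceeds voxel count (", prod(sh), ")")
  img <- v$data[ch, , , ]
  dim(img) <- sh
  labels <- slic3d_cpp(as.numeric(img), as.integer(sh),
                       as.integer(requested_n), compactness,
                       as.integer(max_iter))
  structure(list(labels = labels, K = max(labels), source_channel = ch,
                 requested_n = as.integer(requested_n),
                 compactness = compactness),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat("<superpixel_map> K = ", x$K, " (requested ", x$requested_n,
      "), channel ", x$source_channel, ", compactness ", x$compactness,
      "\n", sep = "")
  invisible(x)
}

#' Voxel mask of one superpixel
#'
#' @param sp a `superpixel_map`.
#' @param label superpixel label in `1..K`.
#' @return A [binary_mask()] of that superpixel's voxels.
#' @export
superpixel_mask <- function(sp, label) {
  stopifnot(inherits(sp, "superpixel_map"))
  label <- as.integer(label)
  if (label < 1L || label > sp$K) stop("unknown superpixel label: ", label)
  binary_mask(array(as.integer(sp$labels == label), dim(sp$labels)))
}

#' Extract one superpixel into its own volume
#'
#' Returns a volume of the full input shape that equals `v` inside the
#' labelled region on all channels and is zero elsewhere — one training
#' sample for the optimal-perturbation generator.
#'
#' @param v a [volume()].
#' @param sp a `superpixel_map` over the same spatial shape.
#' @param label superpixel label in `1..K`.
#' @return A [volume()].
#' @export
extract_superpixel_volume <- function(v, sp, label) {
  stopifnot(inherits(v, "volume"), inherits(sp, "superpixel_map"))
  if (!identical(spatial_shape(v), dim(sp$labels)))
    stop("volume and superpixel map shapes differ")
  label <- as.integer(label)
  if (label < 1L || label > sp$K) stop("unknown superpixel label: ", label)
  keep <- sp$labels == label
  d <- v$data
  for (c in seq_len(dim(d)[1L])) d[c, , , ] <- d[c, , , ] * keep
  volume(d, v$channel_names, v$spacing)
}

#' Save a superpixel map as integer NIfTI
#' @param sp a `superpixel_map`.
#' @param path output path.
#' @param reference optional `volume` supplying spacing.
#' @return `path`, invisibly.
#' @export
save_superpixels <- function(sp, path, reference = NULL) {
  sp_mm <- if (!is.null(reference) && !is.null(reference$spacing))
    reference$spacing else c(1, 1, 1)
  if (sp$K > 255L) stop("more than 255 superpixels; cannot write uint8")
  write_nifti(array(as.numeric(sp$labels), dim(sp$labels)), path,
              spacing = sp_mm, datatype = "uint8")
  invisible(path)
}

#' Grid search over superpixel parameters
#'
#' Re-runs superpixel generation and best-grouping evaluation for every
#' combination of channel, requested superpixel count and perturbation
#' kind, reporting the mean best-grouping Dice coefficient per
#' combination — the desk-scale version of the published parameter grid.
#'
#' @param samples list of phantom samples (volume + reference lesion
#'   mask).
#' @param channels vector of channel names/indices to try.
#' @param n_list vector of requested superpixel counts.
#' @param perturbation_kinds subset of `c("blank", "min", "max")`.
#' @param classifier a classifier honouring [predict_prob()].
#' @param compactness SLIC compactness (fixed across the grid).
#' @return A data.frame with columns channel, requested_n, kind,
#'   mean_best_dsc; the attribute `"best"` holds the argmax row index.
#' @export
superpixel_grid_search <- function(samples, channels, n_list,
                                   perturbation_kinds, classifier,
                                   compactness = 0.1) {
  stopifnot(length(samples) >= 1L, length(channels) >= 1L,
            length(n_list) >= 1L, length(perturbation_kinds) >= 1L)
  rows <- expand.grid(channel = channels, requested_n = n_list,
                      kind = perturbation_kinds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$mean_best_dsc <- NA_real_
  for (r in seq_len(nrow(rows))) {
    dscs <- vapply(samples, function(s) {
      sp <- compute_superpixels(s$volume, rows$channel[r],
                                rows$requested_n[r], compactness)
      rm <- compute_relevance_map(classifier, s$volume, sp,
                                  kind = rows$kind[r])
      best_grouping_dsc(rm, sp, s$lesion_mask)$dsc
    }, 0)
    rows$mean_best_dsc[r] <- mean(dscs)
  }
  attr(rows, "best") <- which.max(rows$mean_best_dsc)
  rows
}
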