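# Synthetic multi-channel phantoms with class-dependent ellipsoidal
# lesions: the test bed standing in for a multi-sequence MRI dataset, so
# the whole pipeline runs with no external data.

#' Phantom generator specification
#'
#' Describes the stated world the generator emulates: multi-sequence 3D
#' scans containing one compact lesion whose contrast against the
#' background depends on the class label (the high-grade/low-grade
#' analogue). The configured superpixel channel (the "T2w analogue")
#' carries the full lesion contrast; the other channels carry half,
#' mirroring the finding that one sequence is the most separable.
#'
#' @param spatial_shape integer triple `(z, y, x)`, default `32^3`.
#' @param n_channels number of channels (default 4).
#' @param channel_names channel labels; defaults to the four MRI sequence
#'   names when `n_channels == 4`.
#' @param superpixel_channel name/index of the high-contrast channel.
#' @param lesion_radius_range voxel interval the three ellipsoid
#'   semi-axes are drawn from (default `c(4, 6)`).
#' @param lesion_contrast length-2 numeric, mean lesion intensity offset
#'   over background for class 0 and class 1 (must differ).
#' @param noise_sigma additive white-noise scale (default 0.05).
#' @param background_texture_scale Gaussian smoothing length (voxels) of
#'   the correlated background texture (default 3).
#' @param class_balance fraction of class-1 samples in a dataset
#'   (default 0.6, mirroring a 60/40 class ratio).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(spatial_shape = c(32L, 32L, 32L),
                         n_channels = 4L,
                         channel_names = NULL,
                         superpixel_channel = NULL,
                         lesion_radius_range = c(4, 6),
                         lesion_contrast = c(0.3, 0.6),
                         noise_sigma = 0.05,
                         background_texture_scale = 3,
                         class_balance = 0.6) {
  spatial_shape <- as.integer(spatial_shape)
  stopifnot(length(spatial_shape) == 3L, all(spatial_shape >= 8L),
            n_channels >= 1L,
            length(lesion_radius_range) == 2L,
            lesion_radius_range[1L] > 0,
            diff(lesion_radius_range) >= 0,
            length(lesion_contrast) == 2L,
            noise_sigma >= 0, background_texture_scale > 0,
            class_balance > 0, class_balance < 1)
  if (lesion_contrast[1L] == lesion_contrast[2L])
    stop("lesion_contrast must differ between classes")
  if (2 * lesion_radius_range[2L] + 2 > min(spatial_shape))
    stop("lesion radii too large for spatial_shape")
  if (is.null(channel_names))
    channel_names <- if (n_channels == 4L) c("T1w", "T1wCE", "T2w", "FLAIR")
                     else paste0("ch", seq_len(n_channels))
  stopifnot(length(channel_names) == n_channels)
  if (is.null(superpixel_channel))
    superpixel_channel <- if ("T2w" %in% channel_names) "T2w" else channel_names[1L]
  structure(list(spatial_shape = spatial_shape,
                 n_channels = as.integer(n_channels),
                 channel_names = channel_names,
                 superpixel_channel = superpixel_channel,
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = as.numeric(lesion_contrast),
                 noise_sigma = noise_sigma,
                 background_texture_scale = background_texture_scale,
                 class_balance = class_balance),
            class = "phantom_spec")
}

# separable Gaussian smoothing of a 3D array (dense kernel matrices;
# shapes here are small)
smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  kmat <- function(n) {
    k <- exp(-outer(seq_len(n), seq_len(n), "-")^2 / (2 * sigma^2))
    k / rowSums(k)
  }
  x <- kmat(d[1L]) %*% matrix(arr, d[1L])
  dim(x) <- d
  x <- aperm(x, c(2L, 3L, 1L))            # (Y, X, Z)
  x <- kmat(d[2L]) %*% matrix(x, d[2L])
  dim(x) <- c(d[2L], d[3L], d[1L])
  x <- aperm(x, c(2L, 3L, 1L))            # (X, Z, Y)
  x <- kmat(d[3L]) %*% matrix(x, d[3L])
  dim(x) <- c(d[3L], d[1L], d[2L])
  aperm(x, c(2L, 3L, 1L))                 # back to (Z, Y, X)
}

rasterize_ellipsoid <- function(shape, center, radii) {
  a <- ((seq_len(shape[1L]) - 0.5 - center[1L]) / radii[1L])^2
  b <- ((seq_len(shape[2L]) - 0.5 - center[2L]) / radii[2L])^2
  c_ <- ((seq_len(shape[3L]) - 0.5 - center[3L]) / radii[3L])^2
  q <- outer(outer(a, b, "+"), c_, "+")
  array(as.integer(q <= 1), shape)
}

#' Generate one phantom sample
#'
#' Deterministic for a fixed `(spec, seed)`. The lesion is an
#' axis-aligned ellipsoid at a random interior center; its intensity is
#' background plus a class-dependent contrast plus noise.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @param label optional class label in `{0, 1}`; drawn from
#'   `class_balance` when missing.
#' @param normalize clip intensities to `[0, 1]` (default `TRUE`;
#'   disable to inspect raw constructed contrasts). The phantom's
#'   intensity model is built on a fixed `[0, 1]` scale, so clipping —
#'   not per-sample min-max, which would rescale every lesion peak to
#'   the top of its own volume's range — is what keeps the class label
#'   recoverable from lesion intensity.
#' @return An object of class `phantom_sample`: a list with `volume`
#'   ([volume()]), `lesion_mask` ([binary_mask()]), `label`, and the
#'   drawn `center` and `radii`.
#' @export
generate_phantom <- function(spec, seed, label = NULL, normalize = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(derive_seed(seed, "phantom"))
  if (is.null(label))
    label <- as.integer(stats::runif(1) < spec$class_balance)
  stopifnot(label %in% c(0L, 1L))
  sh <- spec$spatial_shape
  rr <- spec$lesion_radius_range
  radii <- stats::runif(3L, rr[1L], rr[2L])
  center <- vapply(1:3, function(i)
    stats::runif(1L, radii[i] + 1, sh[i] - radii[i] - 1), 0)
  mask <- rasterize_ellipsoid(sh, center, radii)

  sp_ch_idx <- if (is.character(spec$superpixel_channel))
    match(spec$superpixel_channel, spec$channel_names)
  else as.integer(spec$superpixel_channel)
  contrast <- spec$lesion_contrast[label + 1L]

  # intensities live on a fixed [0,1] scale (background mean 0.35,
  # texture sd 0.08): "normalization" is clipping to [0,1], NOT
  # per-sample min-max, which would rescale every lesion peak to 1 and
  # destroy the label-recoverability invariant
  data <- array(0, c(spec$n_channels, sh))
  for (c in seq_len(spec$n_channels)) {
    g <- smooth3d(array(stats::rnorm(prod(sh)), sh),
                  spec$background_texture_scale)
    g <- g / stats::sd(g)
    mult <- if (c == sp_ch_idx) 1.0 else 0.5
    ch <- 0.35 + 0.08 * g + contrast * mult * mask
    if (spec$noise_sigma > 0)
      ch <- ch + stats::rnorm(prod(sh), sd = spec$noise_sigma)
    data[c, , , ] <- ch
  }
  if (normalize) data <- pmin(pmax(data, 0), 1)
  v <- volume(data, spec$channel_names, spacing = c(1, 1, 1))
  structure(list(volume = v,
                 lesion_mask = binary_mask(mask),
                 label = label, center = center, radii = radii,
                 seed = seed),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Class labels are assigned deterministically so the realized class-1
#' fraction is the closest achievable to `class_balance` (Bresenham-style
#' accumulation); per-sample seeds derive from `(seed, index)`.
#'
#' @param spec a [phantom_spec()].
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @inheritParams generate_phantom
#' @return List of `phantom_sample` objects.
#' @export
generate_dataset <- function(spec, n, seed, normalize = TRUE) {
  stopifnot(n >= 1L)
  acc <- 0
  labels <- integer(n)
  for (i in seq_len(n)) {
    acc <- acc + spec$class_balance
    if (acc >= 1 - 1e-12) { labels[i] <- 1L; acc <- acc - 1 }
  }
  lapply(seq_len(n), function(i)
    generate_phantom(spec, derive_seed(seed, "phantom_case", i),
                     label = labels[i], normalize = normalize))
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat("<phantom_sample> label ", x$label, ", lesion ",
      sum(x$lesion_mask$data), " voxels at (",
      paste(signif(x$center, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
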