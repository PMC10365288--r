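# Shared fixtures, built in code at load time. Kept deliberately small:
# most tests run on 8^3-16^3 grids; only the acceptance suite uses the
# full 32^3 phantom world.

# a tiny deterministic multi-channel volume
tiny_volume <- function(shape = c(8L, 8L, 8L), n_channels = 2L, seed = 1L) {
  set.seed(seed)
  volume(array(runif(n_channels * prod(shape)), c(n_channels, shape)),
         channel_names = paste0("ch", seq_len(n_channels)))
}

# hand-built superpixel map (for tests that need exact label geometry)
manual_sp_map <- function(labels) {
  labels <- array(as.integer(labels), dim(labels))
  structure(list(labels = labels, K = max(labels), source_channel = 1L,
                 requested_n = max(labels), compactness = 0.1),
            class = "superpixel_map")
}

# single-channel volume from a 3D array
vol1 <- function(arr) volume(array(arr, c(1L, dim(arr))))

# mask from a logical/0-1 3D array
msk <- function(arr) binary_mask(array(as.integer(arr != 0), dim(arr)))

# random partition of a grid into exactly K nonempty superpixels
# (nearest-seed Voronoi in index space; independent of the SLIC code path)
random_partition <- function(shape, K, seed) {
  set.seed(seed)
  n <- prod(shape)
  seeds <- sample(n, K)
  coords <- arrayInd(seq_len(n), shape)
  sc <- coords[seeds, , drop = FALSE]
  d2 <- sapply(seq_len(K), function(k)
    (coords[, 1] - sc[k, 1])^2 + (coords[, 2] - sc[k, 2])^2 +
      (coords[, 3] - sc[k, 3])^2)
  lab <- max.col(-d2, ties.method = "first")
  manual_sp_map(array(lab, shape))
}

# small phantom cached across tests (32^3, defaults)
phantom32 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_spec(), seed = 42L)
    cache
  }
})

# 16^3 phantom spec for cheap training tests (dims divisible by 8)
spec16 <- function(noise_sigma = 0.02)
  phantom_spec(spatial_shape = c(16L, 16L, 16L), lesion_radius_range = c(3, 4),
               noise_sigma = noise_sigma)

# counting wrapper: records how often the wrapped classifier is called
counting_classifier <- function(inner) {
  env <- new.env()
  env$n <- 0L
  clf <- classifier_contract(function(v) {
    env$n <- env$n + 1L
    predict_prob(inner, v)
  }, id = "counting")
  list(classifier = clf, counter = env)
}
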