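test_that("volume construction enforces its invariants", {
  v <- tiny_volume()
  expect_s3_class(v, "volume")
  expect_identical(spatial_shape(v), c(8L, 8L, 8L))
  expect_identical(n_channels(v), 2L)
  # 3D input promoted to one channel
  v1 <- volume(array(0, c(4, 4, 4)))
  expect_identical(n_channels(v1), 1L)
  expect_error(volume(array(0, c(2, 4, 4, 4)), channel_names = "only_one"),
               "does not match channel count")
  expect_error(binary_mask(array(c(0, 2), c(2, 1, 1))), "exactly 0 or 1")
})

test_that("normalize_minmax matches the per-channel formula and edge cases", {
  # channel with min 5, max 15: value 10 -> 0.5
  arr <- array(5, c(1, 2, 2, 2))
  arr[1, 1, 1, 1] <- 15; arr[1, 2, 1, 1] <- 10
  n <- normalize_minmax(volume(arr))
  expect_equal(n$data[1, 2, 1, 1], 0.5)
  expect_equal(n$data[1, 1, 1, 1], 1)
  expect_equal(min(n$data), 0)
  # constant channel maps to zeros
  cst <- normalize_minmax(volume(array(7, c(1, 3, 3, 3))))
  expect_true(all(cst$data == 0))
  # channel already spanning [0,1] unchanged
  set.seed(4)
  a <- array(runif(27), c(1, 3, 3, 3))
  a[1, 1, 1, 1] <- 0; a[1, 3, 3, 3] <- 1
  expect_equal(normalize_minmax(volume(a))$data, a)
  # channels are independent
  two <- array(c(0, 10), c(2, 1, 1, 1))
  two <- volume(array(rep(c(0, 100), 8), c(2, 2, 2, 2)))
  nn <- normalize_minmax(two)
  expect_true(all(nn$data[1, , , ] == 0) && all(nn$data[2, , , ] == 0))
})

test_that("normalize_minmax is idempotent", {
  for (s in 1:3) {
    v <- tiny_volume(seed = s)
    once <- normalize_minmax(v)
    twice <- normalize_minmax(once)
    expect_lt(max(abs(once$data - twice$data)), 1e-7)
  }
})

test_that("center_crop offsets, identity, idempotence and errors", {
  v <- volume(array(seq_len(10 * 10 * 10), c(1, 10, 10, 10)))
  c8 <- center_crop(v, c(8, 8, 8))
  # size 10, crop 8 -> offset 1 -> voxels 2..9 (1-based)
  expect_equal(c8$data[1, , , ], v$data[1, 2:9, 2:9, 2:9])
  v9 <- volume(array(seq_len(9 * 9 * 9), c(1, 9, 9, 9)))
  c89 <- center_crop(v9, c(8, 8, 8))
  # size 9, crop 8 -> offset floor(0.5) = 0 -> voxels 1..8
  expect_equal(c89$data[1, , , ], v9$data[1, 1:8, 1:8, 1:8])
  # crop equal to shape is identity
  expect_equal(center_crop(v, c(10, 10, 10))$data, v$data)
  # idempotence
  expect_equal(center_crop(c8, c(8, 8, 8))$data, c8$data)
  expect_error(center_crop(v, c(11, 10, 10)), "exceeds spatial shape")
})

test_that("NIfTI volume round-trip preserves values, spacing and channels", {
  v <- tiny_volume(shape = c(6L, 5L, 4L), n_channels = 3L, seed = 9)
  v$spacing <- c(2, 1.5, 1)
  paths <- file.path(tempdir(), paste0("ch", 1:3, ".nii.gz"))
  save_volume(v, paths)
  v2 <- load_volume(paths, channel_names = v$channel_names)
  expect_lt(max(abs(v2$data - v$data)), 1e-6)
  expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
  expect_identical(v2$channel_names, v$channel_names)
  # single file -> one channel
  vone <- load_volume(paths[1])
  expect_identical(n_channels(vone), 1L)
  # uncompressed .nii too
  p <- file.path(tempdir(), "plain.nii")
  write_nifti(v$data[1, , , ], p)
  expect_lt(max(abs(read_nifti(p)$data - v$data[1, , , ])), 1e-6)
})

test_that("load_volume errors name the problem", {
  expect_error(load_volume(file.path(tempdir(), "nope_missing.nii")),
               "nope_missing")
  a <- file.path(tempdir(), "a32.nii"); b <- file.path(tempdir(), "b16.nii")
  write_nifti(array(0, c(8, 8, 8)), a)
  write_nifti(array(0, c(4, 4, 4)), b)
  expect_error(load_volume(c(a, b)), "mismatched shapes")
})

test_that("mask round-trips exactly, including the empty mask", {
  set.seed(7)
  m <- msk(array(runif(5 * 6 * 7) > 0.6, c(5, 6, 7)))
  p <- file.path(tempdir(), "m.nii.gz")
  save_mask(m, p)
  expect_identical(load_mask(p)$data, m$data)
  # empty mask
  m0 <- msk(array(0, c(4, 4, 4)))
  save_mask(m0, p)
  expect_identical(sum(load_mask(p)$data), 0L)
  # spacing carried from reference
  ref <- tiny_volume(shape = c(5L, 6L, 7L))
  ref$spacing <- c(3, 2, 1)
  save_mask(m, p, reference = ref)
  expect_equal(load_mask(p)$spacing, c(3, 2, 1), tolerance = 1e-6)
})

test_that("pipeline_config validates its fields", {
  cfg <- pipeline_config()
  expect_identical(cfg$n_superpixels_requested, 100L)
  expect_identical(cfg$perturbation_kind, "blank")
  expect_error(pipeline_config(perturbation_kind = "fancy"))
  expect_error(pipeline_config(n_superpixels_requested = 0))
})
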