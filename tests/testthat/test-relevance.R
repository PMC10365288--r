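# A hand-built world where the oracle's region mean makes every score
# exactly computable: 10 voxels on a 10x1x1 grid, oracle over all of
# them, three superpixels whose blanking drops the mean by 0 / 0.2 / 0.4.
exact_world <- function() {
  vals <- array(0, c(10, 1, 1))
  vals[1:4, 1, 1] <- 0                 # label 1: sum 0
  vals[5:7, 1, 1] <- c(0.5, 0.5, 1)    # label 2: sum 2 -> |dp| = 0.2
  vals[8:10, 1, 1] <- c(1, 1.5, 1.5)   # label 3: sum 4 -> |dp| = 0.4
  labs <- array(c(rep(1L, 4), rep(2L, 3), rep(3L, 3)), c(10, 1, 1))
  list(v = vol1(vals), sp = manual_sp_map(labs),
       oc = oracle_region_classifier(msk(array(1, c(10, 1, 1))), 1L))
}

test_that("score_superpixel matches exact oracle arithmetic", {
  w <- exact_world()
  expect_equal(score_superpixel(w$oc, w$v, w$sp, 1L, "blank"), 0)
  expect_equal(score_superpixel(w$oc, w$v, w$sp, 2L, "blank"), 0.2)
  expect_equal(score_superpixel(w$oc, w$v, w$sp, 3L, "blank"), 0.4)
  expect_error(score_superpixel(w$oc, w$v, w$sp, 2L, "optimal"), "generator")
})

test_that("partial overlap: blanking 2 of 4 unit voxels scores 0.5 exactly", {
  vals <- array(0, c(4, 2, 2)); vals[1:4, 1, 1] <- 1
  region <- msk(array(as.integer(vals == 1), dim(vals)))
  oc <- oracle_region_classifier(region, 1L)
  labs <- array(2L, c(4, 2, 2)); labs[1:2, 1, 1] <- 1L
  sp <- manual_sp_map(labs)
  expect_equal(score_superpixel(oc, vol1(vals), sp, 1L, "blank"), 0.5,
               tolerance = 1e-12)
})

test_that("compute_relevance_map normalizes, ranks, and reuses y_np", {
  w <- exact_world()
  rm <- compute_relevance_map(w$oc, w$v, w$sp, "blank")
  expect_equal(unname(rm$raw_scores), c(0, 0.2, 0.4))
  expect_equal(unname(rm$normalized_scores), c(0, 50, 100))
  expect_identical(rm$ranking, c(3L, 2L, 1L))
  expect_identical(rm$kind, "blank")
  # classifier called exactly K + 1 times
  cc <- counting_classifier(w$oc)
  compute_relevance_map(cc$classifier, w$v, w$sp, "blank")
  expect_identical(cc$counter$n, w$sp$K + 1L)
})

test_that("all-equal raw scores: zeros, warning, ranking by label", {
  # constant-prediction classifier
  flat <- classifier_contract(function(v) 0.5, id = "flat")
  w <- exact_world()
  expect_warning(rm <- compute_relevance_map(flat, w$v, w$sp, "blank"),
                 "scored equally")
  expect_true(all(rm$normalized_scores == 0))
  expect_identical(rm$ranking, 1:3)
})

test_that("ties in raw scores break by ascending label", {
  two <- classifier_contract(function(v) {
    # depends only on voxel 1: superpixels 2 and 3 tie at zero
    min(max(v$data[1, 1, 1, 1], 0), 1)
  }, id = "voxel1")
  w <- exact_world()
  rm <- suppressWarnings(compute_relevance_map(two, w$v, w$sp, "blank"))
  expect_identical(rm$ranking[2:3], c(2L, 3L))
})

test_that("segmentation_from_ranks: top-k unions, nesting, bounds", {
  w <- exact_world()
  rm <- compute_relevance_map(w$oc, w$v, w$sp, "blank")
  s1 <- segmentation_from_ranks(rm, w$sp, 1)
  expect_identical(s1$data, array(as.integer(w$sp$labels == 3L), c(10, 1, 1)))
  sK <- segmentation_from_ranks(rm, w$sp, rm$K)
  expect_true(all(sK$data == 1L))
  prev <- s1
  for (k in 2:rm$K) {
    cur <- segmentation_from_ranks(rm, w$sp, k)
    expect_true(all(cur$data - prev$data >= 0))   # nested
    prev <- cur
  }
  expect_error(segmentation_from_ranks(rm, w$sp, 0), "1..K")
  expect_error(segmentation_from_ranks(rm, w$sp, rm$K + 1L), "1..K")
})

test_that("relevance_heatmap paints normalized scores voxelwise", {
  w <- exact_world()
  rm <- compute_relevance_map(w$oc, w$v, w$sp, "blank")
  hm <- relevance_heatmap(rm, w$sp)
  expect_identical(n_channels(hm), 1L)
  expect_equal(range(hm$data), c(0, 100))
  x <- hm$data[1, , , ]   # drops to a length-10 vector here
  # every voxel carries exactly its superpixel's normalized score
  for (lab in 1:3)
    expect_identical(unique(x[w$sp$labels == lab]),
                     unname(rm$normalized_scores[[lab]]))
  expect_equal(x[w$sp$labels == 3L], rep(100, 3))
  expect_equal(x[w$sp$labels == 2L], rep(50, 3))
  # thresholding at > 0 recovers the positively scored superpixels
  expect_identical(as.integer(x > 0),
                   as.integer(as.vector(w$sp$labels %in% c(2L, 3L))))
})

test_that("relabeling superpixels permutes scores consistently", {
  w <- exact_world()
  rm <- compute_relevance_map(w$oc, w$v, w$sp, "blank")
  # apply permutation (1->3, 2->1, 3->2) to the label image
  perm <- c(3L, 1L, 2L)
  sp2 <- manual_sp_map(array(perm[w$sp$labels], dim(w$sp$labels)))
  rm2 <- compute_relevance_map(w$oc, w$v, sp2, "blank")
  for (lab in 1:3)
    expect_equal(rm2$raw_scores[[perm[lab]]], rm$raw_scores[[lab]])
  # the top-ranked *region* is unchanged
  expect_identical(segmentation_from_ranks(rm2, sp2, 1)$data,
                   segmentation_from_ranks(rm, w$sp, 1)$data)
})

test_that("oracle completeness: positive scores only where the region is hit", {
  s <- phantom32()
  v16 <- center_crop(s$volume, c(16, 16, 16))
  sp <- compute_superpixels(v16, "T2w", 10L)
  r <- array(0L, c(16, 16, 16)); r[6:10, 6:10, 6:10] <- 1L
  oc <- oracle_region_classifier(msk(r), "T2w")
  rm <- compute_relevance_map(oc, v16, sp, "blank")
  hits <- vapply(seq_len(sp$K), function(lab)
    sum(r[sp$labels == lab]) > 0, TRUE)
  expect_true(all(which(rm$raw_scores > 0) %in% which(hits)))
})
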