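test_that("dsc matches hand values and its algebra", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  x <- msk(a)
  expect_identical(dsc(x, x), 1)
  b <- array(0L, c(4, 4, 4)); b[3:4, 4, 4] <- 1L
  expect_identical(dsc(x, msk(b)), 0)
  # |x| = 4, |y| = 6, overlap 3 -> 0.6
  xa <- array(0L, c(4, 4, 4)); xa[1:4, 1, 1] <- 1L
  ya <- array(0L, c(4, 4, 4)); ya[2:4, 1, 1] <- 1L; ya[1:3, 2, 1] <- 1L
  expect_equal(dsc(msk(xa), msk(ya)), 0.6)
  expect_equal(dsc(msk(ya), msk(xa)), 0.6)   # symmetry
  e <- msk(array(0L, c(4, 4, 4)))
  expect_warning(z <- dsc(e, e), "undefined")
  expect_identical(z, 0)
  expect_error(dsc(x, msk(array(0L, c(3, 3, 3)))), "shapes differ")
})

# independent brute-force oracle: explicit prefix unions + direct dsc
brute_best_grouping <- function(rm, sp, reference) {
  per_k <- vapply(seq_len(rm$K), function(k)
    dsc(segmentation_from_ranks(rm, sp, k), reference), 0)
  list(k = which.max(per_k), dsc = max(per_k), per_k = per_k)
}

# random scored instance over a random partition
random_instance <- function(seed, K = 8L, shape = c(8L, 8L, 8L)) {
  sp <- random_partition(shape, K, seed)
  set.seed(seed + 1000L)
  raw <- stats::runif(K)
  rm <- structure(list(raw_scores = stats::setNames(raw, seq_len(K)),
                       normalized_scores = 100 * (raw - min(raw)) /
                         (max(raw) - min(raw)),
                       ranking = order(-raw, seq_len(K)), K = K,
                       kind = "blank", classifier_id = "synthetic"),
                  class = "relevance_map")
  ref <- msk(array(stats::runif(prod(shape)) > 0.7, shape))
  list(rm = rm, sp = sp, reference = ref)
}

test_that("best_grouping_dsc equals exhaustive prefix enumeration", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    got <- best_grouping_dsc(inst$rm, inst$sp, inst$reference)
    want <- brute_best_grouping(inst$rm, inst$sp, inst$reference)
    expect_identical(got$k, want$k)
    expect_equal(got$dsc, want$dsc)
    expect_equal(got$per_k, want$per_k)
  }
})

test_that("best grouping finds perfect prefixes", {
  inst <- random_instance(77)
  # reference = rank-1 superpixel -> (1, 1.0)
  ref1 <- superpixel_mask(inst$sp, inst$rm$ranking[1])
  bg1 <- best_grouping_dsc(inst$rm, inst$sp, ref1)
  expect_identical(bg1$k, 1L)
  expect_identical(bg1$dsc, 1)
  # reference = union of ranks 1-2 -> (2, 1.0)
  ref2 <- segmentation_from_ranks(inst$rm, inst$sp, 2)
  bg2 <- best_grouping_dsc(inst$rm, inst$sp, ref2)
  expect_identical(bg2$k, 2L)
  expect_identical(bg2$dsc, 1)
  # the search includes k = 1
  expect_gte(bg2$dsc, bg2$per_k[1])
})

test_that("evaluate_ranked and evaluate_combined agree with brute force", {
  cases <- lapply(1:3, random_instance)
  ranked <- evaluate_ranked(cases, max_rank = 4L)
  combined <- evaluate_combined(cases, max_k = 4L)
  expect_identical(nrow(ranked), 4L)
  # row k = 1 of combined == rank-1 row (definitional identity, exact)
  expect_identical(combined$mean_dsc[1], ranked$mean_dsc[1])
  # every row recomputable from explicitly constructed masks
  for (r in 1:4) {
    want_r <- mean(vapply(cases, function(cs)
      dsc(superpixel_mask(cs$sp, cs$rm$ranking[r]), cs$reference), 0))
    expect_equal(ranked$mean_dsc[r], want_r)
    want_c <- mean(vapply(cases, function(cs)
      dsc(segmentation_from_ranks(cs$rm, cs$sp, r), cs$reference), 0))
    expect_equal(combined$mean_dsc[r], want_c)
  }
  # two-case mean sanity: 0.4 / 0.6 -> 0.5
  c2 <- list(cases[[1]], cases[[1]])
  r2 <- evaluate_ranked(c2, 1L)
  expect_equal(r2$mean_dsc[1],
               dsc(superpixel_mask(cases[[1]]$sp, cases[[1]]$rm$ranking[1]),
                   cases[[1]]$reference))
  expect_error(evaluate_ranked(cases, 100L), "exceeds")
})

test_that("faithfulness trace pairs every checkpoint with a map", {
  s <- phantom32()
  v16 <- center_crop(s$volume, c(16, 16, 16))
  ref16 <- binary_mask(center_crop(volume(array(s$lesion_mask$data,
                                                c(1, 32, 32, 32))),
                                   c(16, 16, 16))$data[1, , , ] |>
                         (\(a) array(as.integer(a), c(16, 16, 16)))())
  sp <- compute_superpixels(v16, "T2w", 8L)
  oc <- oracle_region_classifier(s$lesion_mask, "T2w")
  # oracle needs matching shape; use a 16^3 region instead
  r <- array(0L, c(16, 16, 16)); r[4:9, 4:9, 4:9] <- 1L
  oc <- oracle_region_classifier(msk(r), "T2w")
  flat <- classifier_contract(function(v) 0.5, id = "flat")
  cks <- list(list(classifier = flat, val_loss = 0.9),
              list(classifier = flat, val_loss = 0.9),
              list(classifier = oc, val_loss = 0.1))
  tr <- suppressWarnings(faithfulness_trace(cks, v16, sp, "blank"))
  expect_length(tr, 3L)
  # identical checkpoints -> identical maps
  expect_identical(tr[[1]]$rm$raw_scores, tr[[2]]$rm$raw_scores)
  # constant classifier -> all-zero normalized map (sd 0); trained oracle
  # focuses (sd > 0)
  expect_identical(tr[[1]]$score_sd, 0)
  expect_gt(tr[[3]]$score_sd, 0)
  expect_identical(tr[[3]]$val_loss, 0.1)
})
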