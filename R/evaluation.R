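# Dice similarity and the four evaluation protocols: best superpixel
# grouping, per-rank DSC, cumulative combined ranks, and the
# faithfulness-versus-validation-loss trace.

#' Dice similarity coefficient
#'
#' `DSC = 2 |X ∩ Y| / (|X| + |Y|)`; 1 is a perfect match, 0 no overlap.
#' When both masks are empty the coefficient is undefined; it is taken
#' as 0 with a warning so aggregates stay finite.
#'
#' @param x,y [binary_mask()] objects of one spatial shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  stopifnot(inherits(x, "binary_mask"), inherits(y, "binary_mask"))
  if (!identical(dim(x$data), dim(y$data))) stop("mask shapes differ")
  nx <- sum(x$data); ny <- sum(y$data)
  if (nx + ny == 0L) {
    warning("DSC of two empty masks is undefined; returning 0")
    return(0)
  }
  2 * sum(x$data * y$data) / (nx + ny)
}

#' Best superpixel grouping against a reference mask
#'
#' Iterates through the ranked superpixels from highest to lowest,
#' evaluating the DSC of every rank-prefix union `k = 1..K` against the
#' reference, and returns the maximizing prefix (smallest `k` on ties).
#' This is the upper-bound protocol: the best ROI the ranking could
#' yield if the cut-off were chosen with reference knowledge.
#'
#' @param rm a `relevance_map`.
#' @param sp its `superpixel_map`.
#' @param reference a [binary_mask()] (expert annotation analogue).
#' @return List with `k` (best prefix length), `dsc` (its DSC), and
#'   `per_k` (numeric vector of DSC at every prefix).
#' @export
best_grouping_dsc <- function(rm, sp, reference) {
  stopifnot(inherits(reference, "binary_mask"))
  if (!identical(dim(sp$labels), dim(reference$data)))
    stop("reference shape does not match superpixel map")
  # incremental prefix union: add one superpixel's voxels at a time
  sizes <- tabulate(sp$labels, nbins = rm$K)
  ref <- reference$data
  nref <- sum(ref)
  inter <- 0; npred <- 0
  per_k <- numeric(rm$K)
  ref_by_label <- vapply(seq_len(rm$K), function(lab)
    sum(ref[sp$labels == lab]), 0)
  for (k in seq_len(rm$K)) {
    lab <- rm$ranking[k]
    inter <- inter + ref_by_label[lab]
    npred <- npred + sizes[lab]
    per_k[k] <- if (npred + nref > 0) 2 * inter / (npred + nref) else 0
  }
  k_best <- which.max(per_k)   # smallest k on ties
  list(k = k_best, dsc = per_k[k_best], per_k = per_k)
}

#' Mean DSC of single ranked superpixels
#'
#' Row `r` is the mean over cases of the DSC between the rank-`r`
#' superpixel (alone) and the reference — a reference-free segmentation
#' protocol: the ranks are chosen without the annotation.
#'
#' @param cases list of lists with `rm` (`relevance_map`), `sp`
#'   (`superpixel_map`), `reference` ([binary_mask()]).
#' @param max_rank deepest rank evaluated; at most `min(K)` over cases.
#' @return data.frame with columns `rank`, `mean_dsc`.
#' @export
evaluate_ranked <- function(cases, max_rank) {
  stopifnot(length(cases) >= 1L)
  minK <- min(vapply(cases, function(cs) cs$rm$K, 0L))
  if (max_rank > minK)
    stop("max_rank (", max_rank, ") exceeds smallest K (", minK, ")")
  rows <- vapply(seq_len(max_rank), function(r) {
    mean(vapply(cases, function(cs) {
      lab <- cs$rm$ranking[r]
      dsc(superpixel_mask(cs$sp, lab), cs$reference)
    }, 0))
  }, 0)
  data.frame(rank = seq_len(max_rank), mean_dsc = rows)
}

#' Mean DSC of combined top-ranked superpixels
#'
#' Row `k` treats the union of ranks `1..k` as a single segmentation
#' mask; row `k = 1` coincides with rank 1 of [evaluate_ranked()].
#'
#' @inheritParams evaluate_ranked
#' @param max_k deepest cumulative prefix evaluated.
#' @return data.frame with columns `k`, `mean_dsc`.
#' @export
evaluate_combined <- function(cases, max_k) {
  stopifnot(length(cases) >= 1L)
  minK <- min(vapply(cases, function(cs) cs$rm$K, 0L))
  if (max_k > minK)
    stop("max_k (", max_k, ") exceeds smallest K (", minK, ")")
  rows <- vapply(seq_len(max_k), function(k) {
    mean(vapply(cases, function(cs)
      dsc(segmentation_from_ranks(cs$rm, cs$sp, k), cs$reference), 0))
  }, 0)
  data.frame(k = seq_len(max_k), mean_dsc = rows)
}

#' Per-epoch relevance maps against the validation-loss trace
#'
#' For each training checkpoint, recomputes the relevance map of a probe
#' case and pairs it with that epoch's validation loss, plus a
#' variability summary (the standard deviation of normalized scores) —
#' the faithfulness protocol: a well-trained model should produce
#' focused maps, a poorly trained one diffuse or empty ones.
#'
#' @param checkpoints list of lists with `classifier` (honouring
#'   [predict_prob()]) and `val_loss` (numeric). For a `cnn_classifier`
#'   trained with `keep_checkpoints = TRUE`, see
#'   [classifier_checkpoints()].
#' @param probe_volume the probe [volume()].
#' @param sp its `superpixel_map`.
#' @param kind perturbation kind.
#' @param generator optional, for `kind = "optimal"`.
#' @return List of per-epoch records: `epoch`, `val_loss`, `rm`
#'   (`relevance_map`), `score_sd`.
#' @export
faithfulness_trace <- function(checkpoints, probe_volume, sp,
                               kind = "blank", generator = NULL) {
  stopifnot(length(checkpoints) >= 1L)
  lapply(seq_along(checkpoints), function(e) {
    ck <- checkpoints[[e]]
    rm <- suppressWarnings(
      compute_relevance_map(ck$classifier, probe_volume, sp, kind,
                            generator = generator))
    list(epoch = e, val_loss = ck$val_loss, rm = rm,
         score_sd = stats::sd(rm$normalized_scores))
  })
}

#' Extract per-epoch checkpoint classifiers from a trained toy CNN
#'
#' @param model a `cnn_classifier` trained with
#'   `keep_checkpoints = TRUE`.
#' @return List of `list(classifier, val_loss)` suitable for
#'   [faithfulness_trace()].
#' @export
classifier_checkpoints <- function(model) {
  stopifnot(inherits(model, "cnn_classifier"))
  if (is.null(model$checkpoints) || !length(model$checkpoints) ||
      is.null(model$checkpoints[[1L]]))
    stop("model was trained without keep_checkpoints = TRUE")
  lapply(seq_along(model$checkpoints), function(e)
    list(classifier = cnn_snapshot_classifier(
           model$checkpoints[[e]], model$widths, model$c_in,
           id = paste0(model$id, "_epoch", e)),
         val_loss = model$trace$val_loss[e]))
}
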