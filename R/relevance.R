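# The relevance-map engine: score every superpixel by the absolute
# change in the classifier's predicted probability under perturbation,
# normalize to 0-100, rank, and cut segmentations from rank prefixes.

#' Score a single superpixel
#'
#' `|predict_prob(v) - predict_prob(perturb(v, superpixel, kind))|`; the
#' perturbation touches only the labelled region.
#'
#' @param classifier classifier honouring [predict_prob()].
#' @param v a [volume()].
#' @param sp a `superpixel_map`.
#' @param label superpixel label in `1..K`.
#' @param kind perturbation kind (`"blank"`, `"min"`, `"max"`,
#'   `"optimal"`).
#' @param generator required iff `kind == "optimal"`.
#' @param y_np optional precomputed unperturbed probability (computed
#'   once per map by [compute_relevance_map()]).
#' @return Nonnegative raw relevance score.
#' @export
score_superpixel <- function(classifier, v, sp, label,
                             kind = c("blank", "min", "max", "optimal"),
                             generator = NULL, y_np = NULL) {
  kind <- match.arg(kind)
  if (kind == "optimal" && is.null(generator))
    stop("kind = 'optimal' requires a generator")
  if (is.null(y_np)) y_np <- predict_prob(classifier, v)
  region <- superpixel_mask(sp, label)
  pv <- perturb(v, region, kind, generator = generator,
                sp_volume = if (kind == "optimal")
                  extract_superpixel_volume(v, sp, label))
  abs(y_np - predict_prob(classifier, pv))
}

#' Compute a relevance map
#'
#' Scores every superpixel (the unperturbed prediction is computed once
#' and reused, so the classifier is called exactly `K + 1` times),
#' normalizes raw scores to `[0, 100]` via
#' `100 * (raw - min) / (max - min)`, and ranks superpixels by
#' descending raw score with ties broken by ascending label. When all
#' raw scores are equal no region is distinguished: all normalized
#' scores are 0 and a warning is issued.
#'
#' @inheritParams score_superpixel
#' @return An object of class `relevance_map`: `raw_scores` and
#'   `normalized_scores` (numeric, named by label), `ranking` (integer
#'   permutation of `1..K`, best first), `kind`, `classifier_id`, `K`.
#' @export
compute_relevance_map <- function(classifier, v, sp,
                                  kind = c("blank", "min", "max", "optimal"),
                                  generator = NULL) {
  kind <- match.arg(kind)
  if (kind == "optimal" && is.null(generator))
    stop("kind = 'optimal' requires a generator")
  stopifnot(inherits(sp, "superpixel_map"))
  y_np <- predict_prob(classifier, v)
  raw <- vapply(seq_len(sp$K), function(lab)
    score_superpixel(classifier, v, sp, lab, kind, generator, y_np = y_np),
    0)
  names(raw) <- seq_len(sp$K)
  rng <- max(raw) - min(raw)
  if (rng > 0) {
    norm <- 100 * (raw - min(raw)) / rng
  } else {
    warning("all superpixels scored equally; no region distinguished")
    norm <- raw * 0
  }
  ranking <- order(-raw, seq_len(sp$K))
  structure(list(raw_scores = raw, normalized_scores = norm,
                 ranking = ranking, K = sp$K, kind = kind,
                 classifier_id = classifier_id(classifier),
                 y_np = unname(y_np)),
            class = "relevance_map")
}

#' @export
print.relevance_map <- function(x, ...) {
  cat("<relevance_map> K = ", x$K, ", kind = ", x$kind,
      ", top label ", x$ranking[1L], " (raw ",
      signif(x$raw_scores[x$ranking[1L]], 4), ")\n", sep = "")
  invisible(x)
}

#' Segmentation from top-ranked superpixels
#'
#' Union of the voxel sets of the `k` highest-ranked superpixels. Masks
#' are nested in `k`, and `k = K` reproduces the full volume.
#'
#' @param rm a `relevance_map`.
#' @param sp the `superpixel_map` it was computed on.
#' @param k number of top ranks to combine, `1 <= k <= K`.
#' @return A [binary_mask()].
#' @export
segmentation_from_ranks <- function(rm, sp, k) {
  stopifnot(inherits(rm, "relevance_map"), inherits(sp, "superpixel_map"))
  k <- as.integer(k)
  if (k < 1L || k > rm$K) stop("k must lie in 1..K (K = ", rm$K, ")")
  sel <- rm$ranking[seq_len(k)]
  binary_mask(array(as.integer(sp$labels %in% sel), dim(sp$labels)))
}

#' Voxelwise relevance heatmap
#'
#' Each voxel carries the normalized (0-100) score of its superpixel.
#'
#' @param rm a `relevance_map`.
#' @param sp the matching `superpixel_map`.
#' @return A single-channel [volume()] with values in `[0, 100]`.
#' @export
relevance_heatmap <- function(rm, sp) {
  stopifnot(inherits(rm, "relevance_map"), inherits(sp, "superpixel_map"))
  h <- array(rm$normalized_scores[sp$labels], dim(sp$labels))
  volume(array(h, c(1L, dim(sp$labels))), channel_names = "relevance")
}

#' Write a relevance map's JSON sidecar
#'
#' @param rm a `relevance_map`.
#' @param path output `.json` path.
#' @param extra named list merged into the record (e.g. config hash).
#' @return `path`, invisibly.
#' @export
save_relevance_json <- function(rm, path, extra = list()) {
  rec <- c(list(kind = rm$kind, classifier_id = rm$classifier_id,
                K = rm$K, y_np = rm$y_np,
                raw_scores = as.list(rm$raw_scores),
                normalized_scores = as.list(rm$normalized_scores),
                ranking = rm$ranking),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
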