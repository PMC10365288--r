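# The classifier contract: everything downstream of perturbation sees a
# pre-trained model only as an opaque map volume -> probability in [0,1].

#' Predict a class probability from a volume
#'
#' The single entry point of the classifier contract. `v` may be one
#' [volume()] or a list of volumes (batch form); the result is a numeric
#' vector of probabilities in `[0, 1]`, deterministic at inference.
#'
#' @param object a classifier (any object with a `predict_prob` method).
#' @param v a `volume` or list of volumes.
#' @param ... passed to methods.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(object, v, ...) UseMethod("predict_prob")

#' Wrap a plain function as a classifier
#'
#' @param fn function taking one [volume()] and returning a probability.
#' @param id text identifier recorded in relevance maps.
#' @return An object of class `classifier_fn`.
#' @export
classifier_contract <- function(fn, id = "custom") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, id = id), class = "classifier_fn")
}

#' @export
predict_prob.classifier_fn <- function(object, v, ...) {
  if (inherits(v, "volume")) v <- list(v)
  p <- vapply(v, object$fn, 0)
  stopifnot(all(p >= 0 & p <= 1))
  p
}

#' Analytic oracle classifier over a fixed region
#'
#' Predicts `clamp(mean(v over the region voxels on one channel), 0, 1)`.
#' By construction it depends on nothing outside the region, which makes
#' relevance assertions exact: perturbations disjoint from the region
#' change the prediction by exactly zero (oracle locality).
#'
#' @param region a [binary_mask()] (nonempty).
#' @param channel channel index or name evaluated against the volume.
#' @return An object of class `oracle_classifier`.
#' @export
oracle_region_classifier <- function(region, channel = 1L) {
  stopifnot(inherits(region, "binary_mask"), sum(region$data) > 0)
  structure(list(region = region, channel = channel, id = "oracle"),
            class = "oracle_classifier")
}

#' @export
predict_prob.oracle_classifier <- function(object, v, ...) {
  if (inherits(v, "volume")) v <- list(v)
  vapply(v, function(vol) oracle_predict(object, vol), 0)
}

#' Evaluate the oracle classifier on one volume
#'
#' @param oracle an [oracle_region_classifier()].
#' @param v a [volume()] whose spatial shape matches the oracle region.
#' @return The clamped region mean, a probability.
#' @export
oracle_predict <- function(oracle, v) {
  stopifnot(inherits(oracle, "oracle_classifier"), inherits(v, "volume"))
  if (!identical(spatial_shape(v), dim(oracle$region$data)))
    stop("volume spatial shape does not match oracle region")
  ch <- resolve_channel(v, oracle$channel)
  vals <- v$data[ch, , , ][oracle$region$data == 1L]
  min(max(mean(vals), 0), 1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC; ties contribute 1/2.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC requires both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

bce_loss <- function(p, t, eps = 1e-12) {
  -mean(t * log(p + eps) + (1 - t) * log(1 - p + eps))
}

#' Train the toy 3D CNN classifier
#'
#' A small 3-block 3D CNN (conv-relu-pool stacks, global average pooling,
#' sigmoid head) trained with Adam and binary cross-entropy. It is a
#' stand-in for a large pre-trained model: the perturbation method only
#' ever touches it through the [predict_prob()] contract, so the
#' architecture is deliberately modest. The returned model is the epoch
#' checkpoint with the highest validation AUC (earliest epoch on ties);
#' the full per-epoch loss/AUC trace is attached for the
#' faithfulness-versus-validation-loss evaluation.
#'
#' @param dataset list of [generate_phantom()] samples (or any list of
#'   objects with `$volume` and `$label`).
#' @param split fractions `c(train, val)`, default `c(0.75, 0.25)`.
#' @param epochs training epochs (default 20).
#' @param lr Adam learning rate (default 0.01).
#' @param seed integer seed controlling init, split and shuffling.
#' @param batch_size minibatch size (default 4).
#' @param widths conv-block channel widths (default `c(8, 16, 16)`).
#' @param keep_checkpoints retain per-epoch parameter snapshots (needed
#'   by [faithfulness_trace()]); default `FALSE`.
#' @return An object of class `cnn_classifier` with elements `params`,
#'   `trace` (data.frame epoch/train_loss/val_loss/val_auc),
#'   `best_epoch`, and optionally `checkpoints`.
#' @export
train_toy_classifier <- function(dataset, split = c(0.75, 0.25),
                                 epochs = 20L, lr = 0.01, seed = 1L,
                                 batch_size = 4L, widths = c(8L, 16L, 16L),
                                 keep_checkpoints = FALSE) {
  stopifnot(length(dataset) >= 2L, epochs >= 1L)
  labels <- vapply(dataset, function(s) as.numeric(s$label), 0)
  set.seed(derive_seed(seed, "split"))
  n <- length(dataset)
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (!length(idx1) || !length(idx0))
    stop("train and validation splits must each contain both classes")
  # stratified split so both splits see both classes when possible
  take <- function(ix) {
    ix <- sample(ix)
    ntr <- max(1L, round(split[1L] * length(ix)))
    if (ntr >= length(ix)) ntr <- length(ix) - 1L
    list(train = ix[seq_len(ntr)], val = ix[-seq_len(ntr)])
  }
  s1 <- take(idx1); s0 <- take(idx0)
  tr <- c(s1$train, s0$train); va <- c(s1$val, s0$val)
  if (length(unique(labels[tr])) < 2L || length(unique(labels[va])) < 2L)
    stop("train and validation splits must each contain both classes")

  xs <- lapply(dataset, function(s) vol_to_tensor(s$volume))
  c_in <- dim(xs[[1L]])[4L]
  params <- cnn_init(c_in, widths, seed = derive_seed(seed, "cnn_init"))
  state <- adam_init(params)
  set.seed(derive_seed(seed, "shuffle"))
  trace <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), val_auc = numeric())
  checkpoints <- if (keep_checkpoints) vector("list", epochs)
  best <- list(auc = -Inf, epoch = NA_integer_, params = NULL)

  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    ep_losses <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- NULL
      bl <- 0
      for (i in b) {
        fw <- cnn_forward(params, xs[[i]], keep_cache = TRUE)
        t_i <- labels[i]
        bl <- bl + bce_loss(fw$prob, t_i)
        bw <- cnn_backward(params, fw$cache, (fw$prob - t_i) / length(b))
        grads <- add_grads(grads, bw$grads)
      }
      ep_losses <- c(ep_losses, bl / length(b))
      st <- adam_step(params, grads, state, lr)
      params <- st$params; state <- st$state
    }
    vp <- vapply(va, function(i) cnn_forward(params, xs[[i]])$prob, 0)
    vl <- bce_loss(vp, labels[va])
    vauc <- auc_score(labels[va], vp)
    trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                     val_loss = vl, val_auc = vauc))
    if (keep_checkpoints) checkpoints[[ep]] <- params
    if (vauc > best$auc) best <- list(auc = vauc, epoch = ep, params = params)
  }
  structure(list(params = best$params, widths = widths, c_in = c_in,
                 best_epoch = best$epoch, trace = trace,
                 checkpoints = checkpoints,
                 id = paste0("toy_cnn_seed", seed)),
            class = "cnn_classifier")
}

#' @export
predict_prob.cnn_classifier <- function(object, v, ...) {
  if (inherits(v, "volume")) v <- list(v)
  vapply(v, function(vol)
    cnn_forward(object$params, vol_to_tensor(vol))$prob, 0)
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat("<cnn_classifier> widths ", paste(x$widths, collapse = "-"),
      ", best epoch ", x$best_epoch, " (val AUC ",
      signif(x$trace$val_auc[x$best_epoch], 4), ")\n", sep = "")
  invisible(x)
}

# classifier built from a fixed parameter snapshot (used by the
# faithfulness evaluation to score intermediate epochs)
cnn_snapshot_classifier <- function(params, widths, c_in, id = "snapshot") {
  structure(list(params = params, widths = widths, c_in = c_in,
                 best_epoch = NA_integer_, trace = NULL, checkpoints = NULL,
                 id = id),
            class = "cnn_classifier")
}

classifier_id <- function(classifier) {
  if (!is.null(classifier$id)) classifier$id else class(classifier)[1L]
}
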