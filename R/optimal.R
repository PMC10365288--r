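# Learned "optimal" perturbation: a U-net-shaped generator that, given a
# single extracted superpixel volume, emits the multiplicative mask in
# [0,1] that maximally disrupts the frozen classifier's prediction. It is
# trained with the perturbation loss — the batch mean of reciprocal
# absolute prediction differences — so minimizing the loss maximizes
# |y_np - y_p|. Gradients flow from the loss through the frozen
# classifier (whose parameters never update) and the mask application
# back into the generator.

#' Perturbation loss
#'
#' `L = (1/n) * sum_i 1 / (|y_np_i - y_p_i| + epsilon)`, where `y_np` and
#' `y_p` are the classifier's predictions on the unperturbed and
#' perturbed inputs. The published form has no epsilon and is singular at
#' equality; a small epsilon keeps the function total without moving the
#' optimum. The loss is strictly decreasing in each `|y_np_i - y_p_i|`
#' and symmetric under swapping the two prediction vectors.
#'
#' @param y_np numeric vector of unperturbed probabilities in `[0, 1]`.
#' @param y_p numeric vector of perturbed probabilities, same length.
#' @param epsilon nonnegative regularizer added inside the denominator
#'   (default `1e-6`; `0` reproduces the published form).
#' @return Nonnegative scalar.
#' @export
perturbation_loss <- function(y_np, y_p, epsilon = 1e-6) {
  if (length(y_np) == 0L) stop("empty batch")
  if (length(y_np) != length(y_p)) stop("y_np and y_p lengths differ")
  stopifnot(all(y_np >= 0 & y_np <= 1), all(y_p >= 0 & y_p <= 1),
            epsilon >= 0)
  mean(1 / (abs(y_np - y_p) + epsilon))
}

#' Build the generator training set from superpixel decompositions
#'
#' One training sample per (volume, superpixel label) pair: the
#' extracted superpixel volume, tagged with its source case and label so
#' training can pair each perturbed prediction with the correct
#' unperturbed prediction of the *full* source volume.
#'
#' @param samples list of lists with elements `volume` (a [volume()])
#'   and `sp` (a `superpixel_map`); a `case_id` element is used when
#'   present.
#' @return List of class `sp_training_set`: each element has `sp_volume`,
#'   `case_id`, `label`, `region` ([binary_mask()]), and `source_volume`.
#' @export
build_training_set <- function(samples) {
  out <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    stopifnot(inherits(s$volume, "volume"), inherits(s$sp, "superpixel_map"))
    cid <- if (!is.null(s$case_id)) s$case_id else i
    for (lab in seq_len(s$sp$K)) {
      out[[length(out) + 1L]] <- list(
        sp_volume = extract_superpixel_volume(s$volume, s$sp, lab),
        case_id = cid, label = lab,
        region = superpixel_mask(s$sp, lab),
        source_volume = s$volume)
    }
  }
  structure(out, class = "sp_training_set")
}

#' Train the optimal-perturbation mask generator
#'
#' Per batch: the generator maps each extracted superpixel volume to a
#' mask, the mask is applied multiplicatively inside that superpixel's
#' region of the full original volume, the frozen classifier predicts on
#' original and perturbed volumes, and the [perturbation_loss()] is
#' minimized with Adam. Unperturbed predictions are computed once per
#' source case and reused. Following the published selection rule the
#' LAST epoch's generator is returned by default.
#'
#' @param training_set a [build_training_set()] result.
#' @param classifier frozen classifier honouring [predict_prob()]; must
#'   also expose gradients (a `cnn_classifier` or `oracle_classifier`).
#' @param epochs training epochs (default 25, the published setting).
#' @param lr Adam learning rate (default 0.01, the published setting).
#' @param seed integer seed (init + shuffling).
#' @param batch_size minibatch size (default 4).
#' @param widths encoder widths `c(w1, w2)` (default `c(8, 16)`).
#' @param epsilon perturbation-loss regularizer.
#' @param clip_norm global gradient-norm clip (default 5). The
#'   reciprocal loss has gradient magnitude `1/(|dp| + epsilon)^2`,
#'   which explodes as predictions equalize; unclipped steps slam the
#'   bounded output activation into its dead zone and training stalls.
#' @param checkpoint `"last"` (published rule, default) or `"best"`
#'   (lowest epoch loss).
#' @return An object of class `mask_generator` with the trained
#'   parameters and a `trace` data.frame (epoch, loss, mean_abs_dp).
#' @export
train_generator <- function(training_set, classifier, epochs = 25L,
                            lr = 0.01, seed = 1L, batch_size = 4L,
                            widths = c(8L, 16L), epsilon = 1e-6,
                            clip_norm = 5,
                            checkpoint = c("last", "best")) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(length(training_set) >= 1L, epochs >= 1L)
  n <- length(training_set)

  # frozen unperturbed prediction per source case
  case_ids <- vapply(training_set, function(s) as.character(s$case_id), "")
  uniq <- !duplicated(case_ids)
  y_np_by_case <- stats::setNames(
    vapply(training_set[uniq],
           function(s) predict_prob(classifier, s$source_volume), 0),
    case_ids[uniq])

  xs <- lapply(training_set, function(s) vol_to_tensor(s$sp_volume))
  xorig_by_case <- stats::setNames(
    lapply(training_set[uniq], function(s) vol_to_tensor(s$source_volume)),
    case_ids[uniq])
  c_in <- dim(xs[[1L]])[4L]
  params <- gen_init(c_in, widths, seed = derive_seed(seed, "gen_init"))
  state <- adam_init(params)
  set.seed(derive_seed(seed, "gen_shuffle"))
  trace <- data.frame(epoch = integer(), loss = numeric(),
                      mean_abs_dp = numeric())
  best <- list(loss = Inf, params = params)

  grad_wrt_input <- function(x_perturbed, dy_p) {
    # scalar dL/dy_p -> gradient on the perturbed input tensor
    if (inherits(classifier, "cnn_classifier")) {
      fw <- cnn_forward(classifier$params, x_perturbed, keep_cache = TRUE)
      dlogit <- dy_p * fw$prob * (1 - fw$prob)
      list(y_p = fw$prob,
           gx = cnn_backward(classifier$params, fw$cache, dlogit)$gx)
    } else if (inherits(classifier, "oracle_classifier")) {
      # clamped region mean: gradient 1/|R| on the oracle channel inside
      # the region (zero when clamped)
      rmask <- classifier$region$data
      nr <- sum(rmask)
      m <- mean(x_perturbed[, , , classifier$channel][rmask == 1L])
      gx <- array(0, dim(x_perturbed))
      if (m > 0 && m < 1) {
        g <- array(0, dim(rmask)); g[rmask == 1L] <- dy_p / nr
        gx[, , , classifier$channel] <- g
      }
      list(y_p = min(max(m, 0), 1), gx = gx)
    } else {
      stop("generator training needs a differentiable classifier ",
           "(cnn_classifier or oracle_classifier)")
    }
  }

  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    losses <- numeric(0)
    abs_dps <- numeric(0)
    for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- NULL
      bl <- 0
      for (i in b) {
        s <- training_set[[i]]
        y_np <- y_np_by_case[[as.character(s$case_id)]]
        gf <- gen_forward(params, xs[[i]], keep_cache = TRUE)
        inside <- s$region$data == 1L
        xorig <- xorig_by_case[[as.character(s$case_id)]]
        xp <- xorig
        m3 <- gf$mask[, , , 1L]
        for (c in seq_len(dim(xp)[4L]))
          xp[, , , c][inside] <- xorig[, , , c][inside] * m3[inside]
        # per-sample contribution to L and dL/dy_p
        # L_i = 1/(|y_np - y_p| + eps); dL_i/dy_p = sign(y_np - y_p)/(.)^2
        probe <- grad_wrt_input(xp, 1)  # gradient direction, rescaled below
        y_p <- probe$y_p
        delta <- y_np - y_p
        li <- 1 / (abs(delta) + epsilon)
        dy_p <- sign(delta) / (abs(delta) + epsilon)^2 / length(b)
        bl <- bl + li
        abs_dps <- c(abs_dps, abs(delta))
        gx <- probe$gx * dy_p
        # back through mask application: d xp / d mask = x_orig inside
        gm3 <- array(0, dim(m3))
        acc <- 0
        for (c in seq_len(dim(xp)[4L]))
          acc <- acc + gx[, , , c][inside] * xorig[, , , c][inside]
        gm3[inside] <- acc
        gmask <- array(gm3, c(dim(m3), 1L))
        bw <- gen_backward(params, gf$cache, gmask)
        grads <- add_grads(grads, bw$grads)
      }
      losses <- c(losses, bl / length(b))
      gn <- sqrt(sum(unlist(lapply(grads, function(l)
        lapply(l, function(x) sum(x^2))))))
      if (is.finite(clip_norm) && gn > clip_norm)
        grads <- scale_grads(grads, clip_norm / gn)
      st <- adam_step(params, grads, state, lr)
      params <- st$params; state <- st$state
    }
    ep_loss <- mean(losses)
    trace <- rbind(trace, data.frame(epoch = ep, loss = ep_loss,
                                     mean_abs_dp = mean(abs_dps)))
    if (ep_loss < best$loss) best <- list(loss = ep_loss, params = params)
  }
  structure(list(params = if (checkpoint == "last") params else best$params,
                 widths = widths, c_in = c_in, trace = trace,
                 epsilon = epsilon, checkpoint = checkpoint,
                 id = paste0("unet_gen_seed", seed)),
            class = "mask_generator")
}

#' Create an untrained (seed-initialized) mask generator
#'
#' The pipeline must run end-to-end before training; an untrained
#' generator still honours the mask contract (values in `[0, 1]`,
#' deterministic).
#'
#' @param c_in input channel count.
#' @param widths encoder widths.
#' @param seed integer seed for the initialization.
#' @return A `mask_generator`.
#' @export
untrained_generator <- function(c_in, widths = c(8L, 16L), seed = 1L) {
  structure(list(params = gen_init(c_in, widths,
                                   seed = derive_seed(seed, "gen_init")),
                 widths = widths, c_in = c_in, trace = NULL,
                 epsilon = 1e-6, checkpoint = "untrained",
                 id = paste0("unet_gen_untrained_seed", seed)),
            class = "mask_generator")
}

#' Generate an optimal perturbation mask for one superpixel volume
#'
#' @param g a `mask_generator`.
#' @param sp_volume the extracted superpixel [volume()] (all channels).
#' @return A single-channel mask [volume()] with values in `[0, 1]`,
#'   deterministic in its input.
#' @export
generate_optimal_mask <- function(g, sp_volume) {
  stopifnot(inherits(g, "mask_generator"), inherits(sp_volume, "volume"))
  if (n_channels(sp_volume) != g$c_in)
    stop("generator expects ", g$c_in, " channels, got ",
         n_channels(sp_volume))
  m <- gen_forward(g$params, vol_to_tensor(sp_volume))$mask
  tensor_to_vol(m, channel_names = "mask", spacing = sp_volume$spacing)
}

#' @export
print.mask_generator <- function(x, ...) {
  cat("<mask_generator> widths ", paste(x$widths, collapse = "-"),
      ", checkpoint ", x$checkpoint,
      if (!is.null(x$trace))
        paste0(", final loss ", signif(utils::tail(x$trace$loss, 1), 5)),
      "\n", sep = "")
  invisible(x)
}
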