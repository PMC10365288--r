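# Minimal 3D neural-network machinery.
#
# No deep-learning framework is available in this R stack, so the two
# small networks the package needs (a toy 3D CNN classifier and a
# U-net-shaped mask generator) are built from first principles:
# 3x3x3/stride-1/pad-1 convolutions as im2col (C++) + BLAS matmul,
# 2x2x2 max pooling with stored argmax, nearest-neighbour upsampling,
# and reverse-mode gradients for every op — including the gradient with
# respect to the *input*, which generator training needs in order to
# differentiate the perturbation loss through the frozen classifier.
#
# Tensor layout: (Z, Y, X, C) column-major arrays. Volumes (channel
# first) are converted at the model boundary.

vol_to_tensor <- function(v) aperm(v$data, c(2L, 3L, 4L, 1L))

tensor_to_vol <- function(x, channel_names = NULL, spacing = NULL) {
  volume(aperm(x, c(4L, 1L, 2L, 3L)), channel_names, spacing)
}

conv3_init <- function(c_in, c_out) {
  fan_in <- 27L * c_in
  list(W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

conv3_forward <- function(x, p) {
  d <- dim(x)
  cols <- im2col3_cpp(x, d)
  out <- cols %*% p$W
  out <- sweep(out, 2L, p$b, "+")
  dim(out) <- c(d[1:3], ncol(p$W))
  list(out = out, cols = cols, in_dims = d)
}

conv3_backward <- function(gout, p, cache) {
  co <- dim(gout)[4L]
  gm <- matrix(gout, ncol = co)
  list(gx = col2im3_cpp(gm %*% t(p$W), cache$in_dims),
       gW = crossprod(cache$cols, gm),
       gb = colSums(gm))
}

# leaky ReLU (slope 0.1): all-positive image intensities make plain ReLU
# units prone to dying globally when a bias drifts negative
relu_forward <- function(x) {
  pos <- x > 0
  list(out = x * ifelse(pos, 1, 0.1), mask = pos)
}
relu_backward <- function(gout, cache) gout * ifelse(cache$mask, 1, 0.1)

pool_forward <- function(x) {
  r <- maxpool3d_cpp(x, dim(x))
  list(out = r$out, argmax = r$argmax, in_dims = dim(x))
}

pool_backward <- function(gout, cache) {
  gx <- numeric(prod(cache$in_dims))
  gx[cache$argmax + 1L] <- gout   # pooling windows are disjoint
  dim(gx) <- cache$in_dims
  gx
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L),
    rep(seq_len(d[3L]), each = 2L), , drop = FALSE]
}

upsample2_backward <- function(gout) {
  d <- dim(gout)
  g <- array(0, c(d[1:3] / 2L, d[4L]))
  for (oz in 1:2) for (oy in 1:2) for (ox in 1:2)
    g <- g + gout[seq(oz, d[1L], 2L), seq(oy, d[2L], 2L),
                  seq(ox, d[3L], 2L), , drop = FALSE]
  g
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# hard-sigmoid: attains 0 and 1 exactly (unlike the logistic), so a mask
# generator using it can emit the blank perturbation as a special case.
# The backward pass keeps a small slope in the saturated zones
# (straight-through-style) so a mask pushed onto a boundary — where the
# perturbed prediction stops moving and the reciprocal loss goes flat —
# is not absorbed there.
hardsig_forward <- function(x) {
  list(out = pmin(pmax(0.25 * x + 0.5, 0), 1), mask = x > -2 & x < 2)
}
hardsig_backward <- function(gout, cache)
  0.25 * gout * ifelse(cache$mask, 1, 0.05)

# ---- Adam over nested parameter lists ----

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) return(lapply(p, zero_like))
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  Map(function(x, y) if (is.list(x)) add_grads(x, y) else x + y, a, b)
}

scale_grads <- function(g, s) {
  lapply(g, function(x) if (is.list(x)) scale_grads(x, s) else x * s)
}

# ---- toy 3D CNN classifier ----
# conv(Cin->w1) relu pool | conv(w1->w2) relu pool | conv(w2->w3) relu pool
# | global average pool | dense(w3->1) sigmoid

cnn_init <- function(c_in, widths = c(8L, 16L, 16L), seed = 1L) {
  set.seed(seed)
  list(conv1 = conv3_init(c_in, widths[1L]),
       conv2 = conv3_init(widths[1L], widths[2L]),
       conv3 = conv3_init(widths[2L], widths[3L]),
       dense = list(W = matrix(stats::rnorm(widths[3L], sd = sqrt(1 / widths[3L])),
                               widths[3L], 1L),
                    b = 0))
}

cnn_forward <- function(params, x, keep_cache = FALSE) {
  c1 <- conv3_forward(x, params$conv1); r1 <- relu_forward(c1$out)
  p1 <- pool_forward(r1$out)
  c2 <- conv3_forward(p1$out, params$conv2); r2 <- relu_forward(c2$out)
  p2 <- pool_forward(r2$out)
  c3 <- conv3_forward(p2$out, params$conv3); r3 <- relu_forward(c3$out)
  p3 <- pool_forward(r3$out)
  d3 <- dim(p3$out)
  nsp <- prod(d3[1:3])
  fm <- matrix(p3$out, nsp, d3[4L])
  gmp_idx <- apply(fm, 2L, which.max)   # global max pool: a compact bright
  gap <- fm[cbind(gmp_idx, seq_len(d3[4L]))]  # lesion dominates the max
  logit <- sum(gap * params$dense$W) + params$dense$b
  prob <- sigmoid(logit)
  if (!keep_cache) return(list(prob = prob, logit = logit))
  list(prob = prob, logit = logit,
       cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2, r2 = r2, p2 = p2,
                    c3 = c3, r3 = r3, p3 = p3, gap = gap, d3 = d3, nsp = nsp,
                    gmp_idx = gmp_idx))
}

# dlogit: scalar dL/dlogit. Returns parameter grads and the input gradient.
cnn_backward <- function(params, cache, dlogit) {
  gdW <- matrix(cache$gap * dlogit, ncol = 1L)
  ggap <- as.numeric(params$dense$W) * dlogit
  gp3 <- array(0, cache$d3)
  gfm <- matrix(gp3, cache$nsp, cache$d3[4L])
  gfm[cbind(cache$gmp_idx, seq_len(cache$d3[4L]))] <- ggap
  gp3 <- array(gfm, cache$d3)
  g <- pool_backward(gp3, cache$p3)
  g <- relu_backward(g, cache$r3)
  b3 <- conv3_backward(g, params$conv3, cache$c3)
  g <- pool_backward(b3$gx, cache$p2)
  g <- relu_backward(g, cache$r2)
  b2 <- conv3_backward(g, params$conv2, cache$c2)
  g <- pool_backward(b2$gx, cache$p1)
  g <- relu_backward(g, cache$r1)
  b1 <- conv3_backward(g, params$conv1, cache$c1)
  list(grads = list(conv1 = list(W = b1$gW, b = b1$gb),
                    conv2 = list(W = b2$gW, b = b2$gb),
                    conv3 = list(W = b3$gW, b = b3$gb),
                    dense = list(W = gdW, b = dlogit)),
       gx = b1$gx)
}

# ---- U-net-shaped mask generator ----
# enc: conv(Cin->w1) relu | pool | conv(w1->w2) relu | pool |
# bottleneck conv(w2->w2) relu | up + skip(w2) -> conv(2*w2->w1) relu |
# up + skip(w1) -> conv(2*w1->w1) relu | conv(w1->1) hard-sigmoid

gen_init <- function(c_in, widths = c(8L, 16L), seed = 1L) {
  set.seed(seed)
  w1 <- widths[1L]; w2 <- widths[2L]
  p <- list(enc1 = conv3_init(c_in, w1),
            enc2 = conv3_init(w1, w2),
            bott = conv3_init(w2, w2),
            dec2 = conv3_init(2L * w2, w1),
            dec1 = conv3_init(2L * w1, w1),
            outc = conv3_init(w1, 1L))
  # start masks near 0: the generator opens training at (approximately)
  # the blank perturbation — the strongest naive baseline — and the loss
  # moves it away only where that increases |y_np - y_p|
  p$outc$b[] <- -1.9
  p
}

cat4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4L] + dim(b)[4L]))
  out[, , , seq_len(d[4L])] <- a
  out[, , , d[4L] + seq_len(dim(b)[4L])] <- b
  out
}

gen_forward <- function(params, x, keep_cache = FALSE) {
  e1 <- conv3_forward(x, params$enc1); a1 <- relu_forward(e1$out)
  q1 <- pool_forward(a1$out)
  e2 <- conv3_forward(q1$out, params$enc2); a2 <- relu_forward(e2$out)
  q2 <- pool_forward(a2$out)
  bt <- conv3_forward(q2$out, params$bott); ab <- relu_forward(bt$out)
  u2 <- upsample2(ab$out)
  k2 <- cat4(u2, a2$out)
  d2 <- conv3_forward(k2, params$dec2); ad2 <- relu_forward(d2$out)
  u1 <- upsample2(ad2$out)
  k1 <- cat4(u1, a1$out)
  d1 <- conv3_forward(k1, params$dec1); ad1 <- relu_forward(d1$out)
  oc <- conv3_forward(ad1$out, params$outc)
  hs <- hardsig_forward(oc$out)
  if (!keep_cache) return(list(mask = hs$out))
  list(mask = hs$out,
       cache = list(e1 = e1, a1 = a1, q1 = q1, e2 = e2, a2 = a2, q2 = q2,
                    bt = bt, ab = ab, d2 = d2, ad2 = ad2, d1 = d1, ad1 = ad1,
                    oc = oc, hs = hs,
                    w1 = ncol(params$enc1$W), w2 = ncol(params$enc2$W)))
}

gen_backward <- function(params, cache, gmask) {
  g <- hardsig_backward(gmask, cache$hs)
  bo <- conv3_backward(g, params$outc, cache$oc)
  g <- relu_backward(bo$gx, cache$ad1)
  b1 <- conv3_backward(g, params$dec1, cache$d1)
  w1 <- cache$w1; w2 <- cache$w2
  gu1 <- b1$gx[, , , seq_len(w1), drop = FALSE]
  gskip1 <- b1$gx[, , , w1 + seq_len(w1), drop = FALSE]
  g <- upsample2_backward(gu1)
  g <- relu_backward(g, cache$ad2)
  b2 <- conv3_backward(g, params$dec2, cache$d2)
  gu2 <- b2$gx[, , , seq_len(w2), drop = FALSE]
  gskip2 <- b2$gx[, , , w2 + seq_len(w2), drop = FALSE]
  g <- upsample2_backward(gu2)
  g <- relu_backward(g, cache$ab)
  bb <- conv3_backward(g, params$bott, cache$bt)
  g <- pool_backward(bb$gx, cache$q2)
  g <- relu_backward(g + gskip2, cache$a2)
  be2 <- conv3_backward(g, params$enc2, cache$e2)
  g <- pool_backward(be2$gx, cache$q1)
  g <- relu_backward(g + gskip1, cache$a1)
  be1 <- conv3_backward(g, params$enc1, cache$e1)
  list(grads = list(enc1 = list(W = be1$gW, b = be1$gb),
                    enc2 = list(W = be2$gW, b = be2$gb),
                    bott = list(W = bb$gW, b = bb$gb),
                    dec2 = list(W = b2$gW, b = b2$gb),
                    dec1 = list(W = b1$gW, b = b1$gb),
                    outc = list(W = bo$gW, b = bo$gb)))
}
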