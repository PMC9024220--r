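#' @useDynLib ganterfactual, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal CNN engine.
#
# All image tensors are numeric arrays in (H, W, C, N) layout. Convolutions
# are computed as im2col (C++) followed by a single BLAS gemm, which is where
# essentially all training time is spent. Each layer is an environment
# holding `params` and accumulated `grads`; forward passes return an explicit
# cache ("tape") so one network can appear several times in a loss graph
# (G is applied to x, to F(y) and to y within a single CycleGAN iteration)
# and every application can be backpropagated independently.
# ---------------------------------------------------------------------------

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  e$params <- list()
  e$grads <- list()
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("nn_", .kind), "nn_layer")
  e
}

init_weights <- function(dims, fan_in, init = c("normal002", "he")) {
  init <- match.arg(init)
  n <- prod(dims)
  w <- switch(init,
    normal002 = stats::rnorm(n, 0, 0.02),
    he        = stats::rnorm(n, 0, sqrt(2 / fan_in))
  )
  array(w, dims)
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE,
                    init = "normal002") {
  ly <- new_layer("conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad),
                  use_bias = bias)
  ly$params$W <- matrix(init_weights(c(out_ch, k * k * in_ch),
                                     fan_in = k * k * in_ch, init = init),
                        out_ch, k * k * in_ch)
  if (bias) ly$params$b <- numeric(out_ch)
  ly$grads <- lapply(ly$params, function(p) p * 0)
  ly
}

nn_dense <- function(in_features, out_features, init = "he") {
  ly <- new_layer("dense", in_features = in_features,
                  out_features = out_features)
  ly$params$W <- matrix(init_weights(c(out_features, in_features),
                                     fan_in = in_features, init = init),
                        out_features, in_features)
  ly$params$b <- numeric(out_features)
  ly$grads <- lapply(ly$params, function(p) p * 0)
  ly
}

nn_relu    <- function() new_layer("relu")
nn_lrelu   <- function(alpha = 0.2) new_layer("lrelu", alpha = alpha)
nn_tanh    <- function() new_layer("tanh")
nn_sigmoid <- function() new_layer("sigmoid")
nn_softmax <- function() new_layer("softmax")
nn_flatten <- function() new_layer("flatten")
nn_maxpool <- function(k, stride) new_layer("maxpool", k = as.integer(k),
                                            stride = as.integer(stride))
nn_upsample2 <- function() new_layer("upsample2")

nn_instnorm <- function(ch, eps = 1e-5) {
  ly <- new_layer("instnorm", ch = ch, eps = eps)
  ly$params$gamma <- rep(1, ch)
  ly$params$beta <- rep(0, ch)
  ly$grads <- lapply(ly$params, function(p) p * 0)
  ly
}

# residual block: conv-IN-relu-conv-IN plus skip connection
nn_resblock <- function(ch, k = 3L) {
  pad <- (k - 1L) %/% 2L
  new_layer("resblock", sub = list(
    nn_conv(ch, ch, k, 1L, pad), nn_instnorm(ch), nn_relu(),
    nn_conv(ch, ch, k, 1L, pad), nn_instnorm(ch)
  ))
}

# -- forward ----------------------------------------------------------------

ly_forward <- function(ly, x) UseMethod("ly_forward")

ly_forward.nn_conv <- function(ly, x) {
  d <- dim(x)
  cols <- im2col_batch(x, ly$k, ly$stride, ly$pad)
  out <- ly$params$W %*% cols
  if (ly$use_bias) out <- out + ly$params$b
  oh <- (d[1] + 2L * ly$pad - ly$k) %/% ly$stride + 1L
  ow <- (d[2] + 2L * ly$pad - ly$k) %/% ly$stride + 1L
  out <- aperm(array(out, c(ly$out_ch, oh, ow, d[4])), c(2L, 3L, 1L, 4L))
  list(out = out, cache = list(cols = cols, din = d))
}

ly_forward.nn_dense <- function(ly, x) {
  out <- ly$params$W %*% x + ly$params$b
  list(out = out, cache = list(x = x))
}

ly_forward.nn_relu <- function(ly, x) {
  m <- x > 0
  list(out = x * m, cache = list(m = m))
}

ly_forward.nn_lrelu <- function(ly, x) {
  m <- x > 0
  list(out = ifelse(m, x, ly$alpha * x), cache = list(m = m))
}

ly_forward.nn_tanh <- function(ly, x) {
  out <- tanh(x)
  list(out = out, cache = list(out = out))
}

ly_forward.nn_sigmoid <- function(ly, x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = list(out = out))
}

ly_forward.nn_softmax <- function(ly, x) {
  # x: (K, N) matrix of logits
  z <- exp(sweep(x, 2L, apply(x, 2L, max)))
  out <- sweep(z, 2L, colSums(z), "/")
  list(out = out, cache = list(out = out))
}

ly_forward.nn_flatten <- function(ly, x) {
  d <- dim(x)
  list(out = matrix(x, prod(d[1:3]), d[4]), cache = list(din = d))
}

ly_forward.nn_maxpool <- function(ly, x) {
  r <- maxpool_fwd(x, ly$k, ly$stride)
  list(out = r$out, cache = list(idx = r$idx, din = dim(x)))
}

ly_forward.nn_upsample2 <- function(ly, x) {
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
           drop = FALSE]
  list(out = out, cache = list(din = d))
}

ly_forward.nn_instnorm <- function(ly, x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw, d[3] * d[4])
  mu <- colMeans(xm)
  v <- colMeans(xm * xm) - mu * mu
  s <- sqrt(pmax(v, 0) + ly$eps)
  xhat <- (xm - rep(mu, each = hw)) / rep(s, each = hw)
  g <- rep(ly$params$gamma, d[4])
  b <- rep(ly$params$beta, d[4])
  out <- array(xhat * rep(g, each = hw) + rep(b, each = hw), d)
  list(out = out, cache = list(xhat = xhat, s = s, din = d))
}

ly_forward.nn_resblock <- function(ly, x) {
  h <- x
  caches <- vector("list", length(ly$sub))
  for (i in seq_along(ly$sub)) {
    r <- ly_forward(ly$sub[[i]], h)
    h <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x + h, cache = list(sub = caches))
}

# -- backward ---------------------------------------------------------------
# acc: accumulate parameter gradients into ly$grads (FALSE for frozen nets,
# where only the input gradient is needed).

ly_backward <- function(ly, cache, dout, acc = TRUE) UseMethod("ly_backward")

ly_backward.nn_conv <- function(ly, cache, dout, acc = TRUE) {
  d <- cache$din
  dmat <- matrix(aperm(dout, c(3L, 1L, 2L, 4L)), ly$out_ch)
  if (acc) {
    ly$grads$W <- ly$grads$W + tcrossprod(dmat, cache$cols)
    if (ly$use_bias) ly$grads$b <- ly$grads$b + rowSums(dmat)
  }
  dcols <- crossprod(ly$params$W, dmat)
  col2im_batch(dcols, d[1], d[2], d[3], d[4], ly$k, ly$stride, ly$pad)
}

ly_backward.nn_dense <- function(ly, cache, dout, acc = TRUE) {
  if (acc) {
    ly$grads$W <- ly$grads$W + tcrossprod(dout, cache$x)
    ly$grads$b <- ly$grads$b + rowSums(dout)
  }
  crossprod(ly$params$W, dout)
}

ly_backward.nn_relu <- function(ly, cache, dout, acc = TRUE) dout * cache$m

ly_backward.nn_lrelu <- function(ly, cache, dout, acc = TRUE) {
  dout * ifelse(cache$m, 1, ly$alpha)
}

ly_backward.nn_tanh <- function(ly, cache, dout, acc = TRUE) {
  dout * (1 - cache$out^2)
}

ly_backward.nn_sigmoid <- function(ly, cache, dout, acc = TRUE) {
  dout * cache$out * (1 - cache$out)
}

ly_backward.nn_softmax <- function(ly, cache, dout, acc = TRUE) {
  p <- cache$out
  p * sweep(dout, 2L, colSums(dout * p))
}

ly_backward.nn_flatten <- function(ly, cache, dout, acc = TRUE) {
  array(dout, cache$din)
}

ly_backward.nn_maxpool <- function(ly, cache, dout, acc = TRUE) {
  d <- cache$din
  maxpool_bwd(dout, cache$idx, d[1], d[2], d[3], d[4])
}

ly_backward.nn_upsample2 <- function(ly, cache, dout, acc = TRUE) {
  d <- cache$din
  i1 <- seq(1L, 2L * d[1], by = 2L)
  j1 <- seq(1L, 2L * d[2], by = 2L)
  dout[i1, j1, , , drop = FALSE] + dout[i1 + 1L, j1, , , drop = FALSE] +
    dout[i1, j1 + 1L, , , drop = FALSE] + dout[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

ly_backward.nn_instnorm <- function(ly, cache, dout, acc = TRUE) {
  d <- cache$din
  hw <- d[1] * d[2]
  dm <- matrix(dout, hw, d[3] * d[4])
  xhat <- cache$xhat
  if (acc) {
    per_cn_g <- colSums(dm * xhat)
    per_cn_b <- colSums(dm)
    ly$grads$gamma <- ly$grads$gamma + rowSums(matrix(per_cn_g, d[3], d[4]))
    ly$grads$beta <- ly$grads$beta + rowSums(matrix(per_cn_b, d[3], d[4]))
  }
  g <- rep(rep(ly$params$gamma, d[4]), each = hw)
  dxhat <- dm * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- (dxhat - rep(m1, each = hw) - xhat * rep(m2, each = hw)) /
    rep(cache$s, each = hw)
  array(dx, d)
}

ly_backward.nn_resblock <- function(ly, cache, dout, acc = TRUE) {
  dh <- dout
  for (i in rev(seq_along(ly$sub))) {
    dh <- ly_backward(ly$sub[[i]], cache$sub[[i]], dh, acc)
  }
  dout + dh
}
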