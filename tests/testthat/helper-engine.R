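# access to engine internals used across tests
ns <- asNamespace("ganterfactual")
net_forward <- ns$net_forward
net_backward <- ns$net_backward
net_params <- ns$net_params
net_zero_grads <- ns$net_zero_grads
net_grad_abs_sum <- ns$net_grad_abs_sum
param_layers <- ns$param_layers
nn_sequential <- ns$nn_sequential
nn_conv <- ns$nn_conv
nn_dense <- ns$nn_dense
nn_instnorm <- ns$nn_instnorm
nn_softmax <- ns$nn_softmax
nn_flatten <- ns$nn_flatten
nn_resblock <- ns$nn_resblock

# central-difference gradient of a scalar-valued function of an array
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# max relative error between backprop and numeric input gradient for a net
input_gradient_error <- function(net, dims) {
  x <- array(stats::rnorm(prod(dims)), dims)
  out0 <- net_forward(net, x)$out
  w <- array(stats::rnorm(length(out0)), dim(out0))
  fw <- net_forward(net, x)
  dx <- net_backward(net, fw$tape, w, acc = TRUE)
  gnum <- numeric_gradient(function(xx) sum(w * net_forward(net, array(xx, dims))$out),
                           as.numeric(x))
  max(abs(gnum - as.numeric(dx))) / max(1e-8, max(abs(gnum)))
}
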