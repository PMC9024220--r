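# Sequential network container, parameter bookkeeping and optimizers.

nn_sequential <- function(...) {
  net <- list(layers = list(...))
  if (length(net$layers) == 1L && is.list(net$layers[[1]]) &&
      !inherits(net$layers[[1]], "nn_layer")) {
    net$layers <- net$layers[[1]]
  }
  class(net) <- "nn_net"
  net
}

#' @noRd
net_forward <- function(net, x) {
  tape <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    r <- ly_forward(net$layers[[i]], x)
    x <- r$out
    tape[[i]] <- r$cache
  }
  list(out = x, tape = tape)
}

#' @noRd
net_backward <- function(net, tape, dout, acc = TRUE) {
  for (i in rev(seq_along(net$layers))) {
    dout <- ly_backward(net$layers[[i]], tape[[i]], dout, acc)
  }
  dout
}

# flat list of parameterised layer environments (recursing into resblocks)
param_layers <- function(net) {
  out <- list()
  walk <- function(ly) {
    if (inherits(ly, "nn_resblock")) {
      for (s in ly$sub) walk(s)
    } else if (length(ly$params)) {
      out[[length(out) + 1L]] <<- ly
    }
  }
  for (ly in net$layers) walk(ly)
  out
}

net_zero_grads <- function(net) {
  for (ly in param_layers(net)) {
    ly$grads <- lapply(ly$params, function(p) p * 0)
  }
  invisible(net)
}

#' Extract all trainable parameters of a network as a plain list
#' @noRd
net_params <- function(net) {
  lapply(param_layers(net), function(ly) ly$params)
}

net_set_params <- function(net, params) {
  lys <- param_layers(net)
  stopifnot(length(lys) == length(params))
  for (i in seq_along(lys)) {
    stopifnot(identical(lapply(lys[[i]]$params, dim),
                        lapply(params[[i]], dim)))
    lys[[i]]$params <- params[[i]]
  }
  invisible(net)
}

net_param_count <- function(net) {
  sum(vapply(param_layers(net),
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

# deterministic digest of all parameters, used for frozen-network checks
net_checksum <- function(net) {
  v <- unlist(net_params(net), use.names = FALSE)
  c(sum = sum(v), sumsq = sum(v * v), n = length(v))
}

net_grad_abs_sum <- function(net) {
  sum(vapply(param_layers(net),
             function(ly) sum(vapply(ly$grads, function(g) sum(abs(g)), 1)), 1))
}

# -- optimizers -------------------------------------------------------------
# weight decay (classic L2) applies to "W" parameters only.

make_sgd <- function(lr, momentum = 0.9, weight_decay = 0) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$momentum <- momentum; e$weight_decay <- weight_decay
  class(e) <- c("opt_sgd", "optimizer")
  e
}

make_adam <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$weight_decay <- weight_decay; e$t <- 0L
  class(e) <- c("opt_adam", "optimizer")
  e
}

opt_step <- function(opt, net) UseMethod("opt_step")

opt_step.opt_sgd <- function(opt, net) {
  for (ly in param_layers(net)) {
    if (is.null(ly$opt_v)) ly$opt_v <- lapply(ly$params, function(p) p * 0)
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (nm == "W" && opt$weight_decay > 0) {
        g <- g + opt$weight_decay * ly$params[[nm]]
      }
      ly$opt_v[[nm]] <- opt$momentum * ly$opt_v[[nm]] - opt$lr * g
      ly$params[[nm]] <- ly$params[[nm]] + ly$opt_v[[nm]]
    }
  }
  invisible(net)
}

opt_step.opt_adam <- function(opt, net) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (ly in param_layers(net)) {
    if (is.null(ly$opt_m)) {
      ly$opt_m <- lapply(ly$params, function(p) p * 0)
      ly$opt_v2 <- lapply(ly$params, function(p) p * 0)
    }
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (nm == "W" && opt$weight_decay > 0) {
        g <- g + opt$weight_decay * ly$params[[nm]]
      }
      ly$opt_m[[nm]] <- opt$beta1 * ly$opt_m[[nm]] + (1 - opt$beta1) * g
      ly$opt_v2[[nm]] <- opt$beta2 * ly$opt_v2[[nm]] + (1 - opt$beta2) * g * g
      mhat <- ly$opt_m[[nm]] / bc1
      vhat <- ly$opt_v2[[nm]] / bc2
      ly$params[[nm]] <- ly$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(net)
}
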