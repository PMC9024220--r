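#' Configuration for the binary image classifier
#'
#' The classifier is the model the counterfactual generator explains: a
#' convolutional network in the AlexNet mould (five convolutional stages,
#' three fully connected stages, 2-unit softmax head) trained with SGD +
#' momentum on a mean-squared-error loss against one-hot targets, with L2
#' regularization on all weight matrices. Defaults follow the published
#' training configuration (SGD, learning rate 1e-4, momentum 0.9, batch size
#' 32, 1,000 epochs) at full 512-px scale; [toy_classifier_config()] bundles
#' the reduced scale used throughout the package's examples and tests.
#'
#' @param input_size input side length in pixels.
#' @param conv_filters integer vector of length 5: channels of the five
#'   convolutional stages.
#' @param fc_units integer vector of length 2: widths of the first two fully
#'   connected stages (the third is the 2-unit softmax head).
#' @param learning_rate,momentum,batch_size,epochs SGD hyperparameters.
#' @param l2_weight coefficient of the L2 penalty on all weights.
#' @param optimizer,loss identifiers; only `"sgd"` and `"mse"` are
#'   implemented, matching the training configuration this package models.
#' @param seed integer seed governing initialization and batch shuffling.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(input_size = 512L,
                              conv_filters = c(96L, 256L, 384L, 384L, 256L),
                              fc_units = c(4096L, 4096L),
                              learning_rate = 1e-4, momentum = 0.9,
                              batch_size = 32L, epochs = 1000L,
                              l2_weight = 1e-4, optimizer = "sgd",
                              loss = "mse", seed = 0L) {
  stopifnot(length(conv_filters) == 5L, length(fc_units) == 2L)
  if (learning_rate <= 0 || momentum < 0 || batch_size < 1 || epochs < 1 ||
      l2_weight < 0) {
    stop_with("gf_parameter_error", "invalid classifier hyperparameters")
  }
  if (!identical(optimizer, "sgd") || !identical(loss, "mse")) {
    stop_with("gf_parameter_error",
              "only optimizer = 'sgd' with loss = 'mse' is supported")
  }
  structure(list(input_size = as.integer(input_size),
                 conv_filters = as.integer(conv_filters),
                 fc_units = as.integer(fc_units),
                 learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), l2_weight = l2_weight,
                 optimizer = optimizer, loss = loss, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Reduced-scale classifier configuration for 64-px phantom experiments
#'
#' Same topology and loss as [classifier_config()], with layer widths, epoch
#' count and learning rate sized for a small phantom corpus on one CPU:
#' 30 epochs and learning rate 0.01 (MSE gradients are small, and a few
#' hundred SGD steps must suffice at this scale).
#'
#' @param input_size input side length in pixels (default 64).
#' @param epochs training epochs (default 30).
#' @param seed integer seed.
#' @param ... further overrides passed to [classifier_config()].
#' @export
toy_classifier_config <- function(input_size = 64L, epochs = 30L, seed = 0L, ...) {
  classifier_config(input_size = input_size,
                    conv_filters = c(16L, 32L, 48L, 48L, 32L),
                    fc_units = c(128L, 64L),
                    learning_rate = 0.01, epochs = epochs, seed = seed, ...)
}

# spatial size bookkeeping for the conv/pool stack
classifier_spatial <- function(input_size) {
  s <- input_size
  conv <- function(s, k, st, p) (s + 2L * p - k) %/% st + 1L
  s <- conv(s, 11L, 4L, 2L)          # conv1
  s1 <- s
  s <- conv(s, 3L, 2L, 0L)           # pool1
  s <- conv(s, 5L, 1L, 2L)           # conv2
  s <- conv(s, 3L, 2L, 0L)           # pool2
  s <- conv(s, 3L, 1L, 1L)           # conv3..5 keep size
  s_final <- conv(s, 3L, 2L, 0L)     # pool5
  if (s1 < 3L || s_final < 1L) {
    stop_with("gf_config_error",
              "input_size %d is incompatible with the conv/pool stack", input_size)
  }
  s_final
}

#' Build the (untrained) binary classifier
#'
#' @param config a [classifier_config()].
#' @return an object of class `gf_classifier`. Its softmax output is the
#'   probability pair `(p_X, p_Y)` used by the counterfactual loss.
#' @export
build_classifier <- function(config = classifier_config()) {
  f <- config$conv_filters
  u <- config$fc_units
  s_final <- classifier_spatial(config$input_size)
  net <- with_rng_seed(derive_seed(config$seed, "classifier_init"), nn_sequential(
    nn_conv(1L, f[1], 11L, 4L, 2L, init = "he"), nn_relu(), nn_maxpool(3L, 2L),
    nn_conv(f[1], f[2], 5L, 1L, 2L, init = "he"), nn_relu(), nn_maxpool(3L, 2L),
    nn_conv(f[2], f[3], 3L, 1L, 1L, init = "he"), nn_relu(),
    nn_conv(f[3], f[4], 3L, 1L, 1L, init = "he"), nn_relu(),
    nn_conv(f[4], f[5], 3L, 1L, 1L, init = "he"), nn_relu(), nn_maxpool(3L, 2L),
    nn_flatten(),
    nn_dense(f[5] * s_final^2, u[1]), nn_relu(),
    nn_dense(u[1], u[2]), nn_relu(),
    nn_dense(u[2], 2L), nn_softmax()
  ))
  structure(list(net = net, config = config, history = NULL,
                 trained = FALSE, frozen = FALSE),
            class = "gf_classifier")
}

#' Number of trainable parameters of a classifier
#' @param classifier a `gf_classifier`.
#' @export
parameter_count <- function(classifier) net_param_count(classifier$net)

#' Class probabilities for one image or a batch
#'
#' Deterministic forward pass producing the softmax pair `(p_X, p_Y)`. The
#' hard prediction is the argmax, with the exact tie `p_X == p_Y` resolved to
#' `CLASS_X`.
#'
#' @param classifier a `gf_classifier`.
#' @param image a `labeled_image`, a pixel matrix in \[0, 1\], a list of
#'   either, or an `(H, W, 1, N)` array.
#' @return for a single image, a named numeric vector `c(p_X, p_Y)`; for a
#'   batch, an `N x 2` matrix with columns `p_X`, `p_Y`.
#' @export
predict_probabilities <- function(classifier, image) {
  x <- as_image_batch(image)
  d <- dim(x)
  if (d[1] != classifier$config$input_size || d[2] != classifier$config$input_size) {
    stop_with("gf_shape_error", "image is %dx%d but classifier expects %dx%d",
              d[1], d[2], classifier$config$input_size,
              classifier$config$input_size)
  }
  p <- t(net_forward(classifier$net, x)$out)
  colnames(p) <- c("p_X", "p_Y")
  if (nrow(p) == 1L) p[1L, ] else p
}

#' Hard class prediction (ties go to CLASS_X)
#' @param classifier a `gf_classifier`.
#' @param image as in [predict_probabilities()].
#' @export
predict_class <- function(classifier, image) {
  p <- predict_probabilities(classifier, image)
  if (is.matrix(p)) {
    ifelse(p[, "p_Y"] > p[, "p_X"], "CLASS_Y", "CLASS_X")
  } else {
    if (p[["p_Y"]] > p[["p_X"]]) "CLASS_Y" else "CLASS_X"
  }
}

one_hot <- function(labels) {
  t(vapply(labels, function(l) if (l == "CLASS_X") c(1, 0) else c(0, 1),
           numeric(2)))
}

#' Train the classifier by SGD on the mean-squared-error loss
#'
#' Minimizes the mean squared error between the softmax output and the
#' one-hot label (class order X, Y) with SGD + momentum and L2 weight
#' regularization, recording train and validation loss per epoch.
#'
#' @param classifier a `gf_classifier` from [build_classifier()].
#' @param partitions a [split_corpus()] result with non-empty train and
#'   validation partitions.
#' @param config training configuration; defaults to the classifier's own.
#' @param verbose print one line per epoch.
#' @return the trained classifier, with a `history` data frame (epoch,
#'   train_loss, val_loss, val_accuracy).
#' @export
train_classifier <- function(classifier, partitions,
                             config = classifier$config, verbose = FALSE) {
  if (!length(partitions$train) || !length(partitions$validation)) {
    stop_with("gf_parameter_error",
              "train and validation partitions must be non-empty")
  }
  net <- classifier$net
  opt <- make_sgd(config$learning_rate, config$momentum, config$l2_weight)
  xs <- as_image_batch(partitions$train)
  ts <- one_hot(vapply(partitions$train, function(im) im$label, ""))
  xv <- as_image_batch(partitions$validation)
  tv <- one_hot(vapply(partitions$validation, function(im) im$label, ""))
  n <- dim(xs)[4]
  history <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                        val_loss = NA_real_, val_accuracy = NA_real_)
  with_rng_seed(derive_seed(config$seed, "classifier_train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- xs[, , , bi, drop = FALSE]
        tb <- t(ts[bi, , drop = FALSE])
        net_zero_grads(net)
        fw <- net_forward(net, xb)
        p <- fw$out
        loss <- mean((p - tb)^2)
        if (!is.finite(loss)) {
          stop_with("gf_divergence_error",
                    "non-finite training loss at epoch %d", ep)
        }
        net_backward(net, fw$tape, 2 * (p - tb) / length(p))
        opt_step(opt, net)
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      pv <- net_forward(net, xv)$out
      val_loss <- mean((pv - t(tv))^2)
      val_acc <- mean((pv[2, ] > pv[1, ]) == (tv[, 2] == 1))
      history[ep, c("train_loss", "val_loss", "val_accuracy")] <-
        c(ep_loss / nb, val_loss, val_acc)
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  val %.5f  val acc %.3f",
                        ep, ep_loss / nb, val_loss, val_acc))
      }
    }
  })
  classifier$history <- history
  classifier$trained <- TRUE
  classifier
}

#' Mark a classifier as frozen
#'
#' The counterfactual GAN trains against a fixed classifier: gradients flow
#' through it to the generators, but its parameters receive no updates.
#' [train_ganterfactual()] requires this explicit marker.
#'
#' @param classifier a trained `gf_classifier`.
#' @export
freeze_classifier <- function(classifier) {
  classifier$frozen <- TRUE
  classifier
}

fbeta <- function(precision, recall, beta) {
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  if (!is.finite(num) || den == 0) 0 else num / den
}

#' Evaluate a classifier on a labeled test set
#'
#' Computes accuracy and the F1 and F2 scores from the hard-label confusion
#' matrix, with `CLASS_Y` (opacity) as the positive class. F2 weights recall
#' over precision, reflecting that missing disease is costlier than a false
#' alarm.
#'
#' @param classifier a trained `gf_classifier`.
#' @param test non-empty list of `labeled_image` objects.
#' @return an object of class `classifier_metrics`: list with `accuracy`,
#'   `f1`, `f2` and the 2x2 `confusion` matrix (rows = truth, cols = predicted).
#' @export
evaluate_classifier <- function(classifier, test) {
  if (!length(test)) stop_with("gf_parameter_error", "test set is empty")
  truth <- vapply(test, function(im) im$label, "")
  pred <- predict_class(classifier, test)
  if (length(test) == 1L) pred <- pred[1]
  lv <- c("CLASS_X", "CLASS_Y")
  confusion <- table(factor(truth, lv), factor(pred, lv))
  confusion <- matrix(as.integer(confusion), 2, 2,
                      dimnames = list(truth = lv, predicted = lv))
  metrics_from_confusion(confusion)
}

# shared by evaluate_classifier and tests: metrics from a truth x pred matrix
metrics_from_confusion <- function(confusion) {
  tp <- confusion["CLASS_Y", "CLASS_Y"]
  fp <- confusion["CLASS_X", "CLASS_Y"]
  fn <- confusion["CLASS_Y", "CLASS_X"]
  tn <- confusion["CLASS_X", "CLASS_X"]
  precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
  recall <- if (tp + fn == 0) NaN else tp / (tp + fn)
  structure(list(accuracy = (tp + tn) / sum(confusion),
                 f1 = fbeta(precision, recall, 1),
                 f2 = fbeta(precision, recall, 2),
                 precision = precision, recall = recall,
                 confusion = confusion),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%   f1 %.3f   f2 %.3f\n",
              100 * x$accuracy, x$f1, x$f2))
  print(x$confusion)
  invisible(x)
}

#' @export
print.gf_classifier <- function(x, ...) {
  cat("binary image classifier (", x$config$input_size, "px input, ",
      format(parameter_count(x), big.mark = ","), " parameters)\n", sep = "")
  cat("status:", if (x$trained) "trained" else "untrained",
      if (x$frozen) "(frozen)" else "", "\n")
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("after %d epochs: train loss %.5f, val loss %.5f, val acc %.3f\n",
                last$epoch, last$train_loss, last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

#' @export
predict.gf_classifier <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_probabilities(object, newdata)
  else predict_class(object, newdata)
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint echoes the configuration and stores the parameter arrays,
#' so a loaded classifier reproduces the saved one's predictions exactly.
#'
#' @param classifier a `gf_classifier`.
#' @param path file path for the checkpoint.
#' @export
save_classifier <- function(classifier, path) {
  saveRDS(list(config = classifier$config, params = net_params(classifier$net),
               history = classifier$history, trained = classifier$trained),
          path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  ck <- readRDS(path)
  cl <- build_classifier(ck$config)
  net_set_params(cl$net, ck$params)
  cl$history <- ck$history
  cl$trained <- ck$trained
  cl
}

#' Export classifier metrics as JSON
#' @param metrics a `classifier_metrics` object.
#' @param path output file.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(list(accuracy = metrics$accuracy, f1 = metrics$f1,
                            f2 = metrics$f2,
                            confusion = unclass(metrics$confusion)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
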