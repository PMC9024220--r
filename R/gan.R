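#' Loss weights of the counterfactual CycleGAN objective
#'
#' The full objective is
#' \deqn{L = L_{GAN}(G, D_Y) + L_{GAN}(F, D_X) + \lambda L_{cycle} +
#'   \mu L_{identity} + \gamma L_{counter}}
#' with cycle weight \eqn{\lambda = 10}, identity weight \eqn{\mu = 1} and
#' counterfactual weight \eqn{\gamma = 1} by default. Setting
#' `gamma_counter = 0` (and `mu_identity = 0`) recovers the plain CycleGAN
#' objective, the ablation used to demonstrate what the counterfactual term
#' buys.
#'
#' @param lambda_cycle,mu_identity,gamma_counter non-negative scalars.
#' @export
loss_weights <- function(lambda_cycle = 10, mu_identity = 1, gamma_counter = 1) {
  if (lambda_cycle < 0 || mu_identity < 0 || gamma_counter < 0) {
    stop_with("gf_parameter_error", "loss weights must be non-negative")
  }
  structure(list(lambda_cycle = lambda_cycle, mu_identity = mu_identity,
                 gamma_counter = gamma_counter), class = "loss_weights")
}

#' Configuration of the counterfactual CycleGAN
#'
#' Defaults follow the published training configuration: Adam with learning
#' rate 2e-4, beta1 0.5, beta2 0.999, batch size 1, 20 epochs. Architecture
#' scale is tied to resolution: 9 residual blocks and 64 base filters at
#' >= 256 px, 6 blocks and 32 filters below. The counterfactual target
#' vectors default to the fully confident `(0, 1)` for G (X to Y) and
#' `(1, 0)` for F; any probability pair summing to 1 is accepted, e.g.
#' near-boundary targets like `(0.49, 0.51)`.
#'
#' @param image_size side length in pixels, divisible by 4.
#' @param base_filters channels of the first generator stage (discriminators
#'   use the same base width).
#' @param n_residual_blocks residual blocks in the generator bottleneck.
#' @param learning_rate,beta1,beta2,batch_size,epochs Adam/loop parameters.
#' @param adversarial_form `"least_squares"` (default, the form the reference
#'   CycleGAN implementation trains with) or `"log"` (the binary
#'   cross-entropy form of the printed objective).
#' @param pool_size capacity of the replay buffer of past fakes shown to the
#'   discriminators.
#' @param target_vectors list of two probability 2-vectors: counterfactual
#'   targets for G and F.
#' @param seed integer seed for initialization, shuffling and the pool.
#' @export
gan_config <- function(image_size = 64L,
                       base_filters = if (image_size >= 256L) 64L else 32L,
                       n_residual_blocks = if (image_size >= 256L) 9L else 6L,
                       learning_rate = 2e-4, beta1 = 0.5, beta2 = 0.999,
                       batch_size = 1L, epochs = 20L,
                       adversarial_form = c("least_squares", "log"),
                       pool_size = 50L,
                       target_vectors = list(G = c(0, 1), F = c(1, 0)),
                       seed = 0L) {
  adversarial_form <- match.arg(adversarial_form)
  if (image_size %% 4L != 0L) {
    stop_with("gf_config_error", "image_size must be divisible by 4, got %d",
              image_size)
  }
  if (learning_rate <= 0 || epochs < 1 || batch_size < 1) {
    stop_with("gf_parameter_error", "invalid gan hyperparameters")
  }
  for (tv in target_vectors) {
    if (length(tv) != 2L || any(tv < 0) || abs(sum(tv) - 1) > 1e-9) {
      stop_with("gf_parameter_error",
                "target vectors must be non-negative and sum to 1")
    }
  }
  structure(list(image_size = as.integer(image_size),
                 base_filters = as.integer(base_filters),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 adversarial_form = adversarial_form,
                 pool_size = as.integer(pool_size),
                 target_vectors = target_vectors, seed = as.integer(seed)),
            class = "gan_config")
}

#' Build a translation generator
#'
#' Residual encoder-decoder: a 7x7 stem, two stride-2 downsampling stages,
#' `n_residual_blocks` residual blocks, two nearest-neighbour-upsample +
#' convolution stages, and a 7x7 head bounded to \[-1, 1\] by tanh; instance
#' normalization throughout.
#'
#' @param config a [gan_config()].
#' @param stream name used to derive this network's initialization stream
#'   from `config$seed` (G and F must differ).
#' @return an object of class `gf_generator`.
#' @export
build_generator <- function(config = gan_config(), stream = "G") {
  bf <- config$base_filters
  if (config$image_size %% 4L != 0L) {
    stop_with("gf_config_error", "image_size must be divisible by 4")
  }
  net <- with_rng_seed(derive_seed(config$seed, paste0("gen_", stream)), {
    layers <- list(
      nn_conv(1L, bf, 7L, 1L, 3L), nn_instnorm(bf), nn_relu(),
      nn_conv(bf, 2L * bf, 3L, 2L, 1L), nn_instnorm(2L * bf), nn_relu(),
      nn_conv(2L * bf, 4L * bf, 3L, 2L, 1L), nn_instnorm(4L * bf), nn_relu()
    )
    for (i in seq_len(config$n_residual_blocks)) {
      layers <- c(layers, list(nn_resblock(4L * bf)))
    }
    layers <- c(layers, list(
      nn_upsample2(), nn_conv(4L * bf, 2L * bf, 3L, 1L, 1L),
      nn_instnorm(2L * bf), nn_relu(),
      nn_upsample2(), nn_conv(2L * bf, bf, 3L, 1L, 1L),
      nn_instnorm(bf), nn_relu(),
      nn_conv(bf, 1L, 7L, 1L, 3L), nn_tanh()
    ))
    nn_sequential(layers)
  })
  structure(list(net = net, config = config, stream = stream),
            class = "gf_generator")
}

#' Apply a generator to one image or a batch
#'
#' @param generator a `gf_generator`.
#' @param x image(s) in \[-1, 1\]: matrix or `(H, W, 1, N)` array.
#' @return translated image(s), same shape, in \[-1, 1\].
#' @export
translate <- function(generator, x) UseMethod("translate")

#' @export
translate.gf_generator <- function(generator, x) {
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(dim(x), 1L, 1L))
  out <- net_forward(generator$net, x)$out
  if (was_matrix) out <- out[, , 1L, 1L]
  out
}

#' Build a PatchGAN discriminator
#'
#' Fully convolutional stack (4x4 kernels, leaky ReLU, instance norm after
#' the first stage) emitting a 2-D grid of patch validity scores rather than
#' a single scalar. With the `"log"` adversarial form the scores pass through
#' a sigmoid; with least squares they are raw.
#'
#' @param config a [gan_config()].
#' @param stream initialization stream name (`"D_X"` / `"D_Y"`).
#' @return an object of class `gf_discriminator`.
#' @export
build_discriminator <- function(config = gan_config(), stream = "D_X") {
  df <- config$base_filters
  s <- config$image_size
  for (st in c(2L, 2L, 2L, 1L, 1L)) s <- (s + 2L - 4L) %/% st + 1L
  if (s < 1L) {
    stop_with("gf_config_error",
              "image_size %d is below the discriminator's receptive field",
              config$image_size)
  }
  net <- with_rng_seed(derive_seed(config$seed, paste0("disc_", stream)), {
    layers <- list(
      nn_conv(1L, df, 4L, 2L, 1L), nn_lrelu(0.2),
      nn_conv(df, 2L * df, 4L, 2L, 1L), nn_instnorm(2L * df), nn_lrelu(0.2),
      nn_conv(2L * df, 4L * df, 4L, 2L, 1L), nn_instnorm(4L * df), nn_lrelu(0.2),
      nn_conv(4L * df, 8L * df, 4L, 1L, 1L), nn_instnorm(8L * df), nn_lrelu(0.2),
      nn_conv(8L * df, 1L, 4L, 1L, 1L)
    )
    if (config$adversarial_form == "log") layers <- c(layers, list(nn_sigmoid()))
    nn_sequential(layers)
  })
  structure(list(net = net, config = config, stream = stream),
            class = "gf_discriminator")
}

#' Patch validity scores of a discriminator
#' @param discriminator a `gf_discriminator`.
#' @param x image(s) in \[-1, 1\].
#' @return a 2-D matrix of patch scores (single image) or the raw grid array.
#' @export
discriminate <- function(discriminator, x) {
  was_matrix <- is.matrix(x)
  if (was_matrix) x <- array(x, c(dim(x), 1L, 1L))
  out <- net_forward(discriminator$net, x)$out
  if (was_matrix) out <- out[, , 1L, 1L]
  out
}

# -- loss terms -------------------------------------------------------------

#' Adversarial loss over patch grids
#'
#' The `"log"` form is the printed GAN objective,
#' \eqn{E[\log D(y)] + E[\log(1 - D(G(x)))]}, averaged over patches and
#' summed over the two expectation terms, with scores clamped at 1e-8 before
#' the log; the generator role uses the non-saturating target-flipping
#' convention \eqn{-E[\log D(G(x))]}. The `"least_squares"` form trains the
#' discriminator toward targets 1 (real) / 0 (fake) and the generator toward
#' 1 on fakes, averaging the real and fake terms.
#'
#' @param real_scores,fake_scores patch-score grids of identical shape
#'   (`real_scores` may be `NULL` for the generator role).
#' @param role `"generator"` or `"discriminator"`.
#' @param form `"least_squares"` or `"log"`.
#' @return scalar loss.
#' @export
adversarial_loss <- function(real_scores, fake_scores,
                             role = c("generator", "discriminator"),
                             form = c("least_squares", "log")) {
  role <- match.arg(role)
  form <- match.arg(form)
  if (!is.null(real_scores) && !identical(dim(real_scores), dim(fake_scores))) {
    stop_with("gf_shape_error", "real and fake score grids differ in shape")
  }
  eps <- 1e-8
  if (form == "least_squares") {
    if (role == "generator") return(mean((fake_scores - 1)^2))
    (mean((real_scores - 1)^2) + mean(fake_scores^2)) / 2
  } else {
    if (role == "generator") return(-mean(log(pmax(fake_scores, eps))))
    -(mean(log(pmax(real_scores, eps))) +
        mean(log(pmax(1 - fake_scores, eps))))
  }
}

# gradient of adversarial_loss wrt the scores (same conventions)
adversarial_grad <- function(scores, target, form) {
  n <- length(scores)
  eps <- 1e-8
  if (form == "least_squares") {
    2 * (scores - target) / n
  } else {
    if (target == 1) -1 / pmax(scores, eps) / n
    else 1 / pmax(1 - scores, eps) / n
  }
}

#' Cycle-consistency loss
#'
#' Mean absolute pixel difference between each image and its reconstruction
#' after a round trip through both generators, summed over the two
#' directions: `mean|F(G(x)) - x| + mean|G(F(y)) - y|`.
#'
#' @param x,x_reconstructed,y,y_reconstructed images of matching shapes.
#' @return scalar loss.
#' @export
cycle_loss <- function(x, x_reconstructed, y, y_reconstructed) {
  if (!identical(dim(x), dim(x_reconstructed)) ||
      !identical(dim(y), dim(y_reconstructed))) {
    stop_with("gf_shape_error", "cycle_loss shape mismatch")
  }
  mean(abs(x_reconstructed - x)) + mean(abs(y_reconstructed - y))
}

#' Identity loss
#'
#' Penalty on a generator altering an image already in its target domain:
#' `mean|G(y) - y| + mean|F(x) - x|`.
#'
#' @param y,G_of_y,x,F_of_x images of matching shapes.
#' @return scalar loss.
#' @export
identity_loss <- function(y, G_of_y, x, F_of_x) {
  if (!identical(dim(y), dim(G_of_y)) || !identical(dim(x), dim(F_of_x))) {
    stop_with("gf_shape_error", "identity_loss shape mismatch")
  }
  mean(abs(G_of_y - y)) + mean(abs(F_of_x - x))
}

#' Counterfactual loss
#'
#' Squared Euclidean distance of the frozen classifier's softmax output on
#' each translated image to the one-hot vector of the opposite class:
#' `||C2(G(x)) - (0,1)||^2 + ||C2(F(y)) - (1,0)||^2`. Each term lies in
#' \[0, 2\] on the probability simplex. Accepts `2 x N` probability matrices,
#' in which case each term is the mean over the batch.
#'
#' @param probs_GX softmax pair(s) for `G(x)` images.
#' @param probs_FY softmax pair(s) for `F(y)` images.
#' @param targets list of two probability 2-vectors (defaults `(0,1)`, `(1,0)`).
#' @return scalar loss.
#' @export
counterfactual_loss <- function(probs_GX, probs_FY,
                                targets = list(c(0, 1), c(1, 0))) {
  term <- function(p, t) {
    if (is.matrix(p)) mean(colSums((p - t)^2)) else sum((p - t)^2)
  }
  term(probs_GX, targets[[1]]) + term(probs_FY, targets[[2]])
}

#' Combined objective
#'
#' Weighted sum of the five loss components:
#' `adv_G + adv_F + lambda * cycle + mu * identity + gamma * counter`.
#'
#' @param components numeric vector of 5 scalars in the order
#'   `(adv_G, adv_F, cycle, identity, counter)`.
#' @param weights a [loss_weights()] object.
#' @return scalar total.
#' @export
total_objective <- function(components, weights = loss_weights()) {
  if (length(components) != 5L || any(!is.finite(components))) {
    stop_with("gf_divergence_error",
              "objective components must be 5 finite scalars")
  }
  components[1] + components[2] + weights$lambda_cycle * components[3] +
    weights$mu_identity * components[4] + weights$gamma_counter * components[5]
}

# -- replay buffer ----------------------------------------------------------
# standard CycleGAN image pool: until full, store and return the new fake;
# afterwards, with probability 1/2 swap the new fake against a random stored
# one and return the old, else return the new.
new_image_pool <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$capacity <- capacity
  e$images <- list()
  e
}

pool_query <- function(pool, img) {
  if (pool$capacity <= 0L) return(img)
  if (length(pool$images) < pool$capacity) {
    pool$images[[length(pool$images) + 1L]] <- img
    return(img)
  }
  if (stats::runif(1) < 0.5) {
    i <- sample.int(length(pool$images), 1L)
    old <- pool$images[[i]]
    pool$images[[i]] <- img
    old
  } else {
    img
  }
}

# -- training ---------------------------------------------------------------

sign_grad <- function(a, b, w) w * sign(a - b) / length(a)

#' Train the counterfactual CycleGAN
#'
#' Alternating optimization of two generators (G: X to Y, F: Y to X) and two
#' PatchGAN discriminators on the train partition, with the frozen classifier
#' in the loop: each iteration updates D_X and D_Y on real images and replay-
#' buffer fakes, then takes one joint Adam step on G and F minimizing the
#' combined objective. For the counterfactual term, generator outputs in
#' \[-1, 1\] are mapped to \[0, 1\] by `(g + 1) / 2` inside the
#' differentiable path before entering the classifier, whose parameters
#' receive no gradient.
#'
#' @param partitions a [split_corpus()] result whose train partition contains
#'   both classes.
#' @param classifier a trained `gf_classifier`, marked with
#'   [freeze_classifier()]; its input size must equal `config$image_size`.
#' @param config a [gan_config()].
#' @param weights a [loss_weights()]; `gamma_counter = 0` trains the plain
#'   CycleGAN ablation (the counterfactual loss is still logged, with zero
#'   weight in the objective).
#' @param verbose print a line every `verbose` iterations (0 = silent).
#' @return an object of class `ganterfactual`: list with generators `G`, `F`,
#'   discriminators `D_X`, `D_Y`, the per-iteration loss `log`, `config`,
#'   `weights` and the frozen `classifier`.
#' @export
train_ganterfactual <- function(partitions, classifier, config = gan_config(),
                                weights = loss_weights(), verbose = 0L) {
  if (!isTRUE(classifier$frozen)) {
    stop_with("gf_contract_error",
              "classifier must be marked frozen (see freeze_classifier())")
  }
  if (classifier$config$input_size != config$image_size) {
    stop_with("gf_config_error",
              "classifier input size %d != gan image size %d",
              classifier$config$input_size, config$image_size)
  }
  labs <- vapply(partitions$train, function(im) im$label, "")
  xs <- partitions$train[labs == "CLASS_X"]
  ys <- partitions$train[labs == "CLASS_Y"]
  if (!length(xs) || !length(ys)) {
    stop_with("gf_parameter_error", "train partition must contain both classes")
  }
  # generator-domain images in [-1, 1]
  to_gan <- function(im) array(2 * im$pixels - 1, c(dim(im$pixels), 1L, 1L))
  xs <- lapply(xs, to_gan)
  ys <- lapply(ys, to_gan)

  G <- build_generator(config, "G")
  F_ <- build_generator(config, "F")
  D_X <- build_discriminator(config, "D_X")
  D_Y <- build_discriminator(config, "D_Y")
  opt_G <- make_adam(config$learning_rate, config$beta1, config$beta2)
  opt_DX <- make_adam(config$learning_rate, config$beta1, config$beta2)
  opt_DY <- make_adam(config$learning_rate, config$beta1, config$beta2)
  pool_X <- new_image_pool(config$pool_size)
  pool_Y <- new_image_pool(config$pool_size)
  form <- config$adversarial_form
  tg <- config$target_vectors
  lam <- weights$lambda_cycle; mu <- weights$mu_identity
  gam <- weights$gamma_counter
  n_iter_epoch <- min(length(xs), length(ys))
  total_iters <- config$epochs * n_iter_epoch
  log <- data.frame(iter = seq_len(total_iters), epoch = NA_integer_,
                    loss_D_X = NA_real_, loss_D_Y = NA_real_,
                    adv_G = NA_real_, adv_F = NA_real_, cycle = NA_real_,
                    identity = NA_real_, counter = NA_real_, total = NA_real_)
  it <- 0L

  with_rng_seed(derive_seed(config$seed, "gan_train"), {
    for (ep in seq_len(config$epochs)) {
      ox <- sample(seq_along(xs))
      oy <- sample(seq_along(ys))
      for (i in seq_len(n_iter_epoch)) {
        it <- it + 1L
        x <- xs[[ox[i]]]
        y <- ys[[oy[i]]]

        # fresh fakes (reused for the generator step: D updates below do not
        # touch generator parameters)
        fwG1 <- net_forward(G$net, x);  fake_y <- fwG1$out
        fwF2 <- net_forward(F_$net, y); fake_x <- fwF2$out

        # --- discriminator updates (replay buffer, D_X then D_Y) ---
        upd_D <- function(D, opt, real, fake) {
          net_zero_grads(D$net)
          fr <- net_forward(D$net, real)
          ff <- net_forward(D$net, fake)
          loss <- adversarial_loss(fr$out, ff$out, "discriminator", form)
          net_backward(D$net, fr$tape,
                       adversarial_grad(fr$out, 1, form) / 2, acc = TRUE)
          net_backward(D$net, ff$tape,
                       adversarial_grad(ff$out, 0, form) / 2, acc = TRUE)
          opt_step(opt, D$net)
          loss
        }
        # log-form discriminator sums (not averages) its two terms
        if (form == "log") {
          upd_D <- function(D, opt, real, fake) {
            net_zero_grads(D$net)
            fr <- net_forward(D$net, real)
            ff <- net_forward(D$net, fake)
            loss <- adversarial_loss(fr$out, ff$out, "discriminator", form)
            net_backward(D$net, fr$tape, adversarial_grad(fr$out, 1, form),
                         acc = TRUE)
            net_backward(D$net, ff$tape, adversarial_grad(ff$out, 0, form),
                         acc = TRUE)
            opt_step(opt, D$net)
            loss
          }
        }
        loss_dx <- upd_D(D_X, opt_DX, x, pool_query(pool_X, fake_x))
        loss_dy <- upd_D(D_Y, opt_DY, y, pool_query(pool_Y, fake_y))

        # --- joint generator step ---
        net_zero_grads(G$net)
        net_zero_grads(F_$net)

        fwF1 <- net_forward(F_$net, fake_y); rec_x <- fwF1$out
        fwG2 <- net_forward(G$net, fake_x);  rec_y <- fwG2$out
        sy <- net_forward(D_Y$net, fake_y)
        sx <- net_forward(D_X$net, fake_x)
        pcy <- net_forward(classifier$net, (fake_y + 1) / 2)
        pcx <- net_forward(classifier$net, (fake_x + 1) / 2)

        adv_g <- adversarial_loss(NULL, sy$out, "generator", form)
        adv_f <- adversarial_loss(NULL, sx$out, "generator", form)
        cyc <- cycle_loss(x, rec_x, y, rec_y)
        cf <- counterfactual_loss(pcy$out[, 1], pcx$out[, 1], tg)

        # gradient flowing into fake_y
        d_fake_y <- net_backward(D_Y$net, sy$tape,
                                 adversarial_grad(sy$out, 1, form), acc = FALSE) +
          net_backward(F_$net, fwF1$tape, sign_grad(rec_x, x, lam), acc = TRUE)
        if (gam > 0) {
          d_fake_y <- d_fake_y + gam * 0.5 *
            net_backward(classifier$net, pcy$tape,
                         matrix(2 * (pcy$out[, 1] - tg[[1]]), 2L, 1L),
                         acc = FALSE)
        }
        # gradient flowing into fake_x
        d_fake_x <- net_backward(D_X$net, sx$tape,
                                 adversarial_grad(sx$out, 1, form), acc = FALSE) +
          net_backward(G$net, fwG2$tape, sign_grad(rec_y, y, lam), acc = TRUE)
        if (gam > 0) {
          d_fake_x <- d_fake_x + gam * 0.5 *
            net_backward(classifier$net, pcx$tape,
                         matrix(2 * (pcx$out[, 1] - tg[[2]]), 2L, 1L),
                         acc = FALSE)
        }

        idt <- 0
        if (mu > 0) {
          fwG3 <- net_forward(G$net, y);  idt_y <- fwG3$out
          fwF4 <- net_forward(F_$net, x); idt_x <- fwF4$out
          idt <- identity_loss(y, idt_y, x, idt_x)
          net_backward(G$net, fwG3$tape, sign_grad(idt_y, y, mu), acc = TRUE)
          net_backward(F_$net, fwF4$tape, sign_grad(idt_x, x, mu), acc = TRUE)
        }

        net_backward(G$net, fwG1$tape, d_fake_y, acc = TRUE)
        net_backward(F_$net, fwF2$tape, d_fake_x, acc = TRUE)
        opt_step(opt_G, G$net)
        opt_step(opt_G, F_$net)

        comps <- c(adv_g, adv_f, cyc, idt, cf)
        tot <- total_objective(comps, weights)
        if (!is.finite(tot)) {
          stop_with("gf_divergence_error",
                    "non-finite total loss at iteration %d", it)
        }
        log[it, ] <- list(it, ep, loss_dx, loss_dy, adv_g, adv_f, cyc, idt,
                          cf, tot)
        if (verbose > 0 && it %% verbose == 0L) {
          message(sprintf(
            "iter %5d (epoch %2d)  D %.3f/%.3f  adv %.3f/%.3f  cyc %.3f  idt %.3f  cf %.3f",
            it, ep, loss_dx, loss_dy, adv_g, adv_f, cyc, idt, cf))
        }
      }
    }
  })

  structure(list(G = G, F = F_, D_X = D_X, D_Y = D_Y, log = log,
                 config = config, weights = weights, classifier = classifier),
            class = "ganterfactual")
}

#' @export
print.ganterfactual <- function(x, ...) {
  cat("counterfactual CycleGAN (", x$config$image_size, "px, ",
      x$config$base_filters, " base filters, ",
      x$config$n_residual_blocks, " residual blocks)\n", sep = "")
  cat(sprintf("weights: lambda = %g, mu = %g, gamma = %g\n",
              x$weights$lambda_cycle, x$weights$mu_identity,
              x$weights$gamma_counter))
  n <- nrow(x$log)
  if (n) {
    cat(sprintf("trained %d iterations; final losses: cycle %.3f, counterfactual %.3f\n",
                n, x$log$cycle[n], x$log$counter[n]))
  }
  invisible(x)
}

#' @export
summary.ganterfactual <- function(object, ...) {
  log <- object$log
  dec <- max(1L, floor(nrow(log) / 10))
  out <- list(
    iterations = nrow(log),
    first_decile = colMeans(log[seq_len(dec), -(1:2)]),
    last_decile = colMeans(log[nrow(log) - dec + seq_len(dec), -(1:2)]),
    weights = object$weights
  )
  class(out) <- "summary.ganterfactual"
  out
}

#' @export
print.summary.ganterfactual <- function(x, ...) {
  cat("iterations:", x$iterations, "\n")
  cat("mean losses, first decile of training:\n")
  print(round(x$first_decile, 4))
  cat("mean losses, last decile of training:\n")
  print(round(x$last_decile, 4))
  invisible(x)
}

#' @export
plot.ganterfactual <- function(x, ...) {
  log <- x$log
  graphics::matplot(log$iter, cbind(log$cycle, log$counter, log$adv_G),
                    type = "l", lty = 1, col = c("black", "firebrick", "gray60"),
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", c("cycle", "counterfactual", "adversarial G"),
                   col = c("black", "firebrick", "gray60"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
predict.ganterfactual <- function(object, newdata, ...) {
  generate_counterfactual(newdata, object$classifier, object$G, object$F)
}

#' Save / load a trained counterfactual CycleGAN
#' @param model a `ganterfactual` object.
#' @param path checkpoint file path.
#' @export
save_ganterfactual <- function(model, path) {
  saveRDS(list(config = model$config, weights = model$weights,
               params = lapply(model[c("G", "F", "D_X", "D_Y")],
                               function(m) net_params(m$net)),
               log = model$log,
               classifier = list(config = model$classifier$config,
                                 params = net_params(model$classifier$net))),
          path)
  invisible(path)
}

#' @rdname save_ganterfactual
#' @export
load_ganterfactual <- function(path) {
  ck <- readRDS(path)
  nets <- list(G = build_generator(ck$config, "G"),
               F = build_generator(ck$config, "F"),
               D_X = build_discriminator(ck$config, "D_X"),
               D_Y = build_discriminator(ck$config, "D_Y"))
  for (nm in names(nets)) net_set_params(nets[[nm]]$net, ck$params[[nm]])
  cl <- build_classifier(ck$classifier$config)
  net_set_params(cl$net, ck$classifier$params)
  cl$trained <- TRUE
  cl <- freeze_classifier(cl)
  structure(c(nets, list(log = ck$log, config = ck$config,
                         weights = ck$weights, classifier = cl)),
            class = "ganterfactual")
}

#' Checksum of a classifier's parameters (frozen-classifier audits)
#' @param classifier a `gf_classifier`.
#' @export
classifier_checksum <- function(classifier) net_checksum(classifier$net)
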