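# Shared, lazily built experiment artifacts. The expensive objects (trained
# classifier, trained GANs) are computed once per test run and memoized here;
# every consumer states the conditions through these helpers so all tests see
# the same study design.
#
# Reduced-scale study conditions used by the test suite (one CPU):
#   corpus: 64-px phantoms, 200 per class, seed 0, split 70/10/20
#   classifier: AlexNet-style toy widths, 30 epochs, lr 0.01
#   counterfactual GAN: base_filters 12, 3 residual blocks, 60 train images
#     per class, 2 epochs (120 iterations), Adam 2e-4
.exp_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.exp_cache[[key]])) .exp_cache[[key]] <- force(expr)
  .exp_cache[[key]]
}

exp_phantom_params <- function() phantom_params(image_size = 64, seed = 0)

exp_partitions <- function() {
  memo("partitions", split_corpus(make_corpus(exp_phantom_params(), 200), seed = 0))
}

exp_classifier <- function() {
  memo("classifier", {
    cfg <- toy_classifier_config(epochs = 30, seed = 0)
    cl <- freeze_classifier(train_classifier(build_classifier(cfg),
                                             exp_partitions()))
    .exp_cache$classifier_checksum_at_creation <- classifier_checksum(cl)
    cl
  })
}

exp_classifier_checksum_at_creation <- function() {
  exp_classifier()
  .exp_cache$classifier_checksum_at_creation
}

exp_gan_config <- function(seed) {
  gan_config(image_size = 64, base_filters = 12, n_residual_blocks = 3,
             epochs = 2, seed = seed)
}

# training subset: first 60 train images per class (deterministic)
exp_gan_partitions <- function() {
  memo("gan_partitions", {
    parts <- exp_partitions()
    labs <- vapply(parts$train, function(im) im$label, "")
    list(train = c(parts$train[labs == "CLASS_X"][1:60],
                   parts$train[labs == "CLASS_Y"][1:60]),
         validation = parts$validation, test = parts$test)
  })
}

exp_gan <- function(seed, gamma) {
  memo(sprintf("gan_s%d_g%g", seed, gamma), {
    train_ganterfactual(exp_gan_partitions(), exp_classifier(),
                        exp_gan_config(seed),
                        loss_weights(gamma_counter = gamma))
  })
}

exp_flip_report <- function(seed, gamma) {
  memo(sprintf("flip_s%d_g%g", seed, gamma), {
    m <- exp_gan(seed, gamma)
    flip_rate_report(exp_partitions()$test, exp_classifier(), m$G, m$F)
  })
}

# tiny corpus + nets for fast structural tests
tiny_partitions <- function() {
  memo("tiny_partitions", split_corpus(make_corpus(exp_phantom_params(), 12), seed = 2))
}

tiny_classifier <- function() {
  memo("tiny_classifier", {
    cfg <- toy_classifier_config(epochs = 1, seed = 3)
    freeze_classifier(train_classifier(build_classifier(cfg), tiny_partitions()))
  })
}

tiny_gan_config <- function(seed = 5, ...) {
  gan_config(image_size = 64, base_filters = 4, n_residual_blocks = 1,
             epochs = 1, seed = seed, ...)
}

tiny_gan_run <- function(gamma = 1) {
  memo(sprintf("tiny_gan_run_g%g", gamma), {
    train_ganterfactual(tiny_partitions(), tiny_classifier(),
                        tiny_gan_config(seed = 5),
                        loss_weights(gamma_counter = gamma))
  })
}
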