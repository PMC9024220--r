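test_that("generator preserves shape and bounds output to [-1, 1]", {
  for (size in c(16L, 32L)) {
    cfg <- gan_config(image_size = size, base_filters = 4,
                      n_residual_blocks = 1, seed = 2)
    G <- build_generator(cfg)
    x <- matrix(runif(size * size, -1, 1), size)
    out <- translate(G, x)
    expect_identical(dim(out), dim(x))
    expect_true(all(out >= -1 & out <= 1))
  }
  expect_error(gan_config(image_size = 30), class = "gf_config_error")
})

test_that("network initialization is deterministic per seed and stream", {
  cfg <- gan_config(image_size = 16, base_filters = 4, n_residual_blocks = 1,
                    seed = 7)
  expect_identical(net_params(build_generator(cfg, "G")$net),
                   net_params(build_generator(cfg, "G")$net))
  expect_false(identical(net_params(build_generator(cfg, "G")$net),
                         net_params(build_generator(cfg, "F")$net)))
})

test_that("discriminator emits a patch grid, not a scalar", {
  cfg <- gan_config(image_size = 64, base_filters = 4, n_residual_blocks = 1,
                    seed = 3)
  D <- build_discriminator(cfg)
  s <- discriminate(D, matrix(runif(64 * 64, -1, 1), 64))
  expect_true(is.matrix(s))
  expect_true(all(dim(s) > 1))
  # fully convolutional: doubling the input doubles each grid dimension
  s2 <- discriminate(D, matrix(runif(128 * 128, -1, 1), 128))
  # three stride-2 stages double the grid, the two stride-1 valid-ish stages
  # add one cell each: g(2s) = 2 g(s) + 2
  expect_equal(dim(s2), dim(s) * 2 + 2)
  expect_error(build_discriminator(gan_config(image_size = 16, base_filters = 4,
                                              n_residual_blocks = 1)),
               class = "gf_config_error")
})

test_that("patch grids are translation-equivariant away from borders", {
  cfg <- gan_config(image_size = 64, base_filters = 4, n_residual_blocks = 1,
                    seed = 9)
  D <- build_discriminator(cfg)
  stride <- 8L   # product of the stride-2 stages
  x1 <- matrix(0, 64, 64); x1[24, 24] <- 1
  x2 <- matrix(0, 64, 64); x2[24 + stride, 24] <- 1
  g1 <- discriminate(D, x1)
  g2 <- discriminate(D, x2)
  # shifting the input by one patch stride shifts the response grid by one
  # cell; approximate only, because instance norm couples every cell to the
  # global feature statistics (and borders feel the zero padding)
  interior <- 3:(nrow(g1) - 3)
  expect_equal(g2[interior + 1, 3], g1[interior, 3], tolerance = 0.01)
})

test_that("log-form discriminators emit probabilities", {
  cfg <- gan_config(image_size = 32, base_filters = 4, n_residual_blocks = 1,
                    adversarial_form = "log", seed = 1)
  D <- build_discriminator(cfg)
  s <- discriminate(D, matrix(runif(32 * 32, -1, 1), 32))
  expect_true(all(s > 0 & s < 1))
})

test_that("the replay pool returns new fakes until full, then swaps", {
  ns <- asNamespace("ganterfactual")
  pool <- ns$new_image_pool(2L)
  a <- matrix(1, 2, 2); b <- matrix(2, 2, 2); c2 <- matrix(3, 2, 2)
  expect_identical(ns$pool_query(pool, a), a)
  expect_identical(ns$pool_query(pool, b), b)
  set.seed(1)
  got <- replicate(50, ns$pool_query(pool, c2), simplify = FALSE)
  vals <- vapply(got, function(m) m[1, 1], 1)
  expect_true(any(vals == 3))          # sometimes the fresh fake
  expect_true(any(vals %in% c(1, 2)))  # sometimes a stored one
})

test_that("counterfactual gradients reach the generator, not the classifier", {
  cl <- tiny_classifier()
  cfg <- tiny_gan_config(seed = 11)
  G <- build_generator(cfg)
  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1, 1))
  net_zero_grads(G$net)
  net_zero_grads(cl$net)
  fwG <- net_forward(G$net, x)
  fwC <- net_forward(cl$net, (fwG$out + 1) / 2)
  dprob <- matrix(2 * (fwC$out[, 1] - c(0, 1)), 2, 1)
  dh <- net_backward(cl$net, fwC$tape, dprob, acc = FALSE)
  net_backward(G$net, fwG$tape, 0.5 * dh, acc = TRUE)
  expect_equal(net_grad_abs_sum(cl$net), 0)
  expect_gt(net_grad_abs_sum(G$net), 0)
})
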