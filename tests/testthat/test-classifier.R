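test_that("softmax outputs are valid probabilities for any input", {
  cl <- build_classifier(toy_classifier_config(seed = 1))
  img <- matrix(runif(64 * 64), 64)
  p <- predict_probabilities(cl, img)
  expect_named(p, c("p_X", "p_Y"))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("builds are deterministic in config seed", {
  a <- build_classifier(toy_classifier_config(seed = 4))
  b <- build_classifier(toy_classifier_config(seed = 4))
  c2 <- build_classifier(toy_classifier_config(seed = 5))
  expect_identical(net_params(a$net), net_params(b$net))
  expect_false(identical(net_params(a$net), net_params(c2$net)))
})

test_that("doubling input size changes only the first dense stage fan-in", {
  count_by_layer <- function(size) {
    cl <- build_classifier(toy_classifier_config(input_size = size))
    vapply(param_layers(cl$net),
           function(ly) sum(vapply(ly$params, length, 1L)), 1L)
  }
  c64 <- count_by_layer(64)
  c128 <- count_by_layer(128)
  expect_length(c64, 8)          # 5 conv + 3 dense
  expect_identical(c64[-6], c128[-6])
  expect_gt(c128[6], c64[6])     # first dense stage fan-in grows
})

test_that("incompatible input sizes raise configuration errors", {
  expect_error(build_classifier(toy_classifier_config(input_size = 16)),
               class = "gf_config_error")
  cl <- build_classifier(toy_classifier_config(input_size = 64))
  expect_error(predict_probabilities(cl, matrix(0.5, 32, 32)),
               class = "gf_shape_error")
})

test_that("batch and single-image predictions agree and ties go to CLASS_X", {
  cl <- build_classifier(toy_classifier_config(seed = 6))
  imgs <- lapply(1:3, function(i) matrix(runif(64 * 64), 64))
  pb <- predict_probabilities(cl, imgs)
  for (i in 1:3) {
    expect_equal(unname(predict_probabilities(cl, imgs[[i]])), unname(pb[i, ]),
                 tolerance = 1e-5)
  }
  # zero out the head: logits equal => p_X = p_Y = 0.5 => predict CLASS_X
  head_layer <- param_layers(cl$net)[[8]]
  head_layer$params$W[] <- 0
  head_layer$params$b[] <- 0
  expect_equal(unname(predict_probabilities(cl, imgs[[1]])), c(0.5, 0.5))
  expect_equal(predict_class(cl, imgs[[1]]), "CLASS_X")
})

test_that("metrics match hand-computed F-beta arithmetic", {
  conf <- function(tp, fp, fn, tn) {
    matrix(c(tn, fn, fp, tp), 2, 2,
           dimnames = list(truth = c("CLASS_X", "CLASS_Y"),
                           predicted = c("CLASS_X", "CLASS_Y")))
  }
  mfc <- asNamespace("ganterfactual")$metrics_from_confusion
  m1 <- mfc(conf(tp = 8, fp = 2, fn = 2, tn = 8))
  expect_equal(m1$precision, 0.8)
  expect_equal(m1$recall, 0.8)
  expect_equal(m1$f1, 0.8)
  expect_equal(m1$f2, 0.8)
  expect_equal(m1$accuracy, 0.8)
  m2 <- mfc(conf(tp = 6, fp = 1, fn = 4, tn = 9))
  expect_equal(m2$precision, 6 / 7)
  expect_equal(m2$recall, 0.6)
  expect_equal(m2$f1, 2 * (6 / 7) * 0.6 / (6 / 7 + 0.6))
  expect_equal(m2$f2, 5 * (6 / 7) * 0.6 / (4 * 6 / 7 + 0.6))
  expect_equal(round(m2$f1, 3), 0.706)
  expect_equal(round(m2$f2, 3), 0.638)
})

test_that("F2 increases with recall at fixed precision", {
  fb <- asNamespace("ganterfactual")$fbeta
  rs <- seq(0.1, 1, by = 0.1)
  f2s <- vapply(rs, function(r) fb(0.7, r, 2), 1)
  expect_true(all(diff(f2s) > 0))
})

test_that("training bookkeeping: history length, zero-lr no-op, checkpoints", {
  parts <- tiny_partitions()
  cfg <- toy_classifier_config(epochs = 2, seed = 9)
  cl <- train_classifier(build_classifier(cfg), parts, cfg)
  expect_equal(nrow(cl$history), 2)
  expect_true(all(is.finite(cl$history$train_loss)))

  cfg0 <- toy_classifier_config(epochs = 1, seed = 9)
  cfg0$learning_rate <- 0
  cl0 <- build_classifier(cfg0)
  before <- net_params(cl0$net)
  cl0 <- train_classifier(cl0, parts, cfg0)
  expect_identical(net_params(cl0$net), before)

  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(cl, f)
  cl2 <- load_classifier(f)
  img <- parts$test[[1]]
  expect_equal(predict_probabilities(cl2, img), predict_probabilities(cl, img))
})

test_that("perfect predictions yield perfect metrics", {
  cl <- exp_classifier()
  parts <- exp_partitions()
  m <- evaluate_classifier(cl, parts$test)
  expect_equal(sum(m$confusion), length(parts$test))
  all_right <- m$confusion["CLASS_X", "CLASS_Y"] == 0 &&
    m$confusion["CLASS_Y", "CLASS_X"] == 0
  if (all_right) {
    expect_equal(m$accuracy, 1)
    expect_equal(m$f1, 1)
    expect_equal(m$f2, 1)
  } else {
    succeed("classifier not perfect on this corpus; exactness covered above")
  }
})
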