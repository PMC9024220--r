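test_that("identity generators leave predictions untouched", {
  cl <- tiny_classifier()
  idg <- identity_generator(64)
  img <- tiny_partitions()$test[[1]]
  r <- generate_counterfactual(img, cl, idg, idg)
  expect_equal(r$counterfactual_prediction, r$original_prediction,
               tolerance = 1e-9)
  expect_false(r$flipped)
  expect_equal(r$counterfactual, img$pixels, tolerance = 1e-12)
})

test_that("routing follows the predicted class, not the label", {
  cl <- tiny_classifier()
  idg <- identity_generator(64)
  # raw unlabeled matrix input works; routing derives from the prediction
  raw <- tiny_partitions()$test[[2]]$pixels
  r <- generate_counterfactual(raw, cl, idg, idg)
  pred_x <- r$original_prediction[["p_X"]] >= r$original_prediction[["p_Y"]]
  expect_equal(r$routed_generator, if (pred_x) "G" else "F")
  expect_error(generate_counterfactual(matrix(0.1, 2, 3), cl, idg, idg),
               class = "gf_shape_error")
})

test_that("interpolation is exact at the endpoints and midpoint", {
  a <- matrix(runif(64), 8)
  b <- matrix(runif(64), 8)
  expect_identical(interpolate_images(a, b, 0), a)
  expect_identical(interpolate_images(a, b, 1), b)
  expect_equal(interpolate_images(matrix(0.2, 1, 1), matrix(0.6, 1, 1), 0.5),
               matrix(0.4, 1, 1))
  expect_error(interpolate_images(a, b, 1.5), class = "gf_parameter_error")
  expect_error(interpolate_images(a, matrix(0, 2, 2), 0.5),
               class = "gf_shape_error")
})

test_that("flip-rate report conserves counts and matches a direct recount", {
  cl <- tiny_classifier()
  model <- tiny_gan_run()
  test_set <- c(tiny_partitions()$test, tiny_partitions()$validation)
  rep <- flip_rate_report(test_set, cl, model$G, model$F)

  truth <- vapply(test_set, function(im) im$label, "")
  expect_equal(sum(rep$matrix_normal), sum(truth == "CLASS_X"))
  expect_equal(sum(rep$matrix_pneumonia), sum(truth == "CLASS_Y"))
  expect_identical(rep$matrix_total, rep$matrix_normal + rep$matrix_pneumonia)
  n_x <- sum(truth == "CLASS_X"); n_y <- sum(truth == "CLASS_Y")
  expect_equal(rep$accuracy_total,
               (n_x * rep$accuracy_normal + n_y * rep$accuracy_pneumonia) /
                 (n_x + n_y))

  # brute-force recount: re-invoke classifier and generators per image
  flips <- vapply(test_set, function(im) {
    p0 <- predict_probabilities(cl, im$pixels)
    gen <- if (p0[["p_X"]] >= p0[["p_Y"]]) model$G else model$F
    cf <- pmin(pmax((translate(gen, 2 * im$pixels - 1) + 1) / 2, 0), 1)
    p1 <- predict_probabilities(cl, cf)
    (p0[["p_Y"]] > p0[["p_X"]]) != (p1[["p_Y"]] > p1[["p_X"]])
  }, TRUE)
  expect_equal(rep$accuracy_total, mean(flips))
  expect_equal(rep$accuracy_normal, mean(flips[truth == "CLASS_X"]))
  expect_equal(rep$accuracy_pneumonia, mean(flips[truth == "CLASS_Y"]))

  # ordering invariance
  perm <- sample(seq_along(test_set))
  rep2 <- flip_rate_report(test_set[perm], cl, model$G, model$F)
  expect_identical(rep2$matrix_total, rep$matrix_total)
  expect_equal(rep2$accuracy_total, rep$accuracy_total)
})

test_that("identity generators produce a diagonal report with zero accuracy", {
  cl <- tiny_classifier()
  idg <- identity_generator(64)
  test_set <- tiny_partitions()$test
  rep <- flip_rate_report(test_set, cl, idg, idg)
  expect_equal(rep$accuracy_total, 0)
  expect_equal(rep$matrix_total[1, 2] + rep$matrix_total[2, 1], 0)
  expect_error(flip_rate_report(test_set[vapply(test_set, function(im)
    im$label, "") == "CLASS_X"], cl, idg, idg),
    class = "gf_evaluation_error")
})

test_that("explanation export writes frames, difference map and sidecar", {
  cl <- tiny_classifier()
  idg <- identity_generator(64)
  img <- tiny_partitions()$test[[1]]
  r <- generate_counterfactual(img, cl, idg, idg)
  out <- withr::local_tempdir()
  export_explanation(r, n_frames = 2, out = out)
  f1 <- png::readPNG(file.path(out, "frame_001.png"))
  f2 <- png::readPNG(file.path(out, "frame_002.png"))
  orig <- png::readPNG(file.path(out, "original.png"))
  cf <- png::readPNG(file.path(out, "counterfactual.png"))
  expect_identical(f1, orig)
  expect_identical(f2, cf)
  # identical original/counterfactual => uniform mid-gray difference map
  d <- png::readPNG(file.path(out, "difference.png"))
  expect_true(all(abs(d - 0.5) <= 1 / 255))
  side <- jsonlite::read_json(file.path(out, "explanation.json"))
  expect_equal(side$original_prediction$p_X, r$original_prediction[["p_X"]],
               tolerance = 1e-9)
  expect_false(side$flipped)
  expect_error(export_explanation(r, n_frames = 1, out = out),
               class = "gf_parameter_error")
})
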