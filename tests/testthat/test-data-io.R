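test_that("written corpora round-trip through the PNG loader", {
  p <- phantom_params(image_size = 32, seed = 9)
  corpus <- make_corpus(p, 3)
  root <- withr::local_tempdir()
  write_corpus(corpus, root)
  loaded <- load_image_directory(root, 32)
  expect_length(loaded, 6)
  by_id <- setNames(loaded, vapply(loaded, function(im) im$id, ""))
  for (im in corpus) {
    expect_equal(by_id[[im$id]]$label, im$label)
    expect_lt(max(abs(by_id[[im$id]]$pixels - im$pixels)), 1 / 255 + 1e-9)
  }
})

test_that("RGB input collapses to one channel and resizing yields squares", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "a"))
  dir.create(file.path(root, "b"))
  rgb <- array(runif(24 * 24 * 3), c(24, 24, 3))
  png::writePNG(rgb, file.path(root, "a", "rgb.png"))
  png::writePNG(matrix(runif(24 * 24), 24), file.path(root, "b", "gray.png"))
  loaded <- load_image_directory(root, 16)
  expect_true(all(vapply(loaded, function(im) all(dim(im$pixels) == c(16, 16)), TRUE)))
  expect_equal(loaded[[1]]$label, "CLASS_X")   # folder "a" sorts first
  expect_equal(loaded[[2]]$label, "CLASS_Y")
})

test_that("degenerate directory layouts are rejected with layout errors", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "only_one"))
  png::writePNG(matrix(0.5, 8, 8), file.path(root, "only_one", "x.png"))
  expect_error(load_image_directory(root, 8), class = "gf_layout_error")
  dir.create(file.path(root, "empty_class"))
  expect_error(load_image_directory(root, 8), class = "gf_layout_error")
})

test_that("stratified splitting hits exact floor-based counts", {
  corpus <- make_corpus(phantom_params(image_size = 16, seed = 2), 50)
  parts <- split_corpus(corpus, c(0.7, 0.1, 0.2), seed = 1)
  expect_length(parts$train, 70)
  expect_length(parts$validation, 10)
  expect_length(parts$test, 20)
  for (part in list(parts$train, parts$validation, parts$test)) {
    labs <- table(vapply(part, function(im) im$label, ""))
    expect_equal(unname(labs["CLASS_X"]), unname(labs["CLASS_Y"]))
  }
})

test_that("splits are deterministic, disjoint and exhaustive", {
  corpus <- make_corpus(phantom_params(image_size = 16, seed = 3), 10)
  a <- split_corpus(corpus, seed = 7)
  b <- split_corpus(corpus, seed = 7)
  ids <- function(part) sort(vapply(part, function(im) im$id, ""))
  for (p in c("train", "validation", "test")) expect_identical(ids(a[[p]]), ids(b[[p]]))
  all_ids <- c(ids(a$train), ids(a$validation), ids(a$test))
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, vapply(corpus, function(im) im$id, ""))
})

test_that("per-class partition proportions deviate by at most one image", {
  corpus <- make_corpus(phantom_params(image_size = 16, seed = 5), 17)
  parts <- split_corpus(corpus, c(0.6, 0.2, 0.2), seed = 3)
  for (lab in c("CLASS_X", "CLASS_Y")) {
    for (p in c("train", "validation", "test")) {
      n <- sum(vapply(parts[[p]], function(im) im$label, "") == lab)
      want <- 17 * parts$fractions[[match(p, c("train", "validation", "test"))]]
      expect_lte(abs(n - want), 1)
    }
  }
})

test_that("too-small classes and bad fractions are size/parameter errors", {
  corpus <- make_corpus(phantom_params(image_size = 16, seed = 6), 2)
  expect_error(split_corpus(corpus, seed = 1), class = "gf_size_error")
  corpus10 <- make_corpus(phantom_params(image_size = 16, seed = 6), 5)
  expect_error(split_corpus(corpus10, c(0.5, 0.5, 0.5), seed = 1),
               class = "gf_parameter_error")
})

test_that("partition manifests and corpus counts are written faithfully", {
  corpus <- make_corpus(phantom_params(image_size = 16, seed = 8), 10)
  parts <- split_corpus(corpus, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_partition_manifest(parts, f)
  man <- read.csv(f)
  expect_equal(nrow(man), 20)
  expect_setequal(unique(man$partition), c("train", "validation", "test"))

  root <- withr::local_tempdir()
  write_corpus(corpus, root)
  counts <- corpus_counts(root)
  expect_equal(unname(counts[["CLASS_X"]]), 10L)
  expect_equal(unname(counts[["total"]]), 20L)
})
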