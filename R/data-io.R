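#' Load a two-class image directory
#'
#' Reads a directory containing exactly two class subfolders of PNG images
#' (the layout [write_corpus()] emits, and the layout a prepared chest-x-ray
#' corpus uses with one folder per class). Images are converted to a single
#' channel (luminance average for RGB), bilinearly resized to
#' `image_size x image_size`, and scaled to \[0, 1\]. The subfolder that
#' sorts first becomes class `CLASS_X`, the other `CLASS_Y`; with a corpus
#' prepared from the RSNA pneumonia data, name the folders so that "Normal"
#' sorts first.
#'
#' @param path directory with exactly two class subfolders.
#' @param image_size target side length in pixels.
#' @return a list of `labeled_image` objects.
#' @export
load_image_directory <- function(path, image_size) {
  if (!dir.exists(path)) stop_with("gf_io_error", "directory '%s' not found", path)
  subs <- sort(list.dirs(path, recursive = FALSE))
  if (length(subs) != 2L) {
    stop_with("gf_layout_error",
              "expected exactly 2 class subfolders in '%s', found %d",
              path, length(subs))
  }
  labels <- c("CLASS_X", "CLASS_Y")
  out <- list()
  for (k in 1:2) {
    files <- sort(list.files(subs[k], pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) {
      stop_with("gf_layout_error", "class folder '%s' contains no PNG images",
                subs[k])
    }
    for (f in files) {
      px <- tryCatch(png::readPNG(f), error = function(e) {
        stop_with("gf_io_error", "failed to read image '%s': %s", f,
                  conditionMessage(e))
      })
      if (length(dim(px)) == 3L) px <- rowMeans(px[, , 1:3, drop = FALSE], dims = 2L)
      if (nrow(px) != image_size || ncol(px) != image_size) {
        px <- resize_bilinear(px, image_size)
      }
      out[[length(out) + 1L]] <- structure(
        list(pixels = clip01(px), label = labels[k],
             id = tools::file_path_sans_ext(basename(f))),
        class = "labeled_image")
    }
  }
  out
}

# bilinear resize of a single-channel matrix via EBImage
resize_bilinear <- function(px, image_size) {
  out <- EBImage::resize(EBImage::Image(px), w = image_size, h = image_size)
  matrix(EBImage::imageData(out), image_size, image_size)
}

#' Stratified train/validation/test split
#'
#' Splits a labeled corpus class by class: within each class the images are
#' shuffled by `seed` and allocated with floor-based counts, remainders going
#' to the training partition, so per-class proportions deviate from the
#' requested fractions by at most one image.
#'
#' @param corpus a list of `labeled_image` objects.
#' @param fractions positive numeric triple `(train, validation, test)`
#'   summing to 1; default `c(0.7, 0.1, 0.2)`.
#' @param seed integer seed for the shuffles.
#' @return an object of class `corpus_partitions` with elements `train`,
#'   `validation`, `test`, `fractions`, `seed`.
#' @export
split_corpus <- function(corpus, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_with("gf_parameter_error",
              "fractions must be three positive numbers summing to 1")
  }
  labels <- vapply(corpus, function(im) im$label, "")
  ids <- vapply(corpus, function(im) im$id, "")
  if (anyDuplicated(ids)) stop_with("gf_parameter_error", "corpus ids must be unique")
  parts <- list(train = list(), validation = list(), test = list())
  for (lab in sort(unique(labels))) {
    idx <- which(labels == lab)
    n <- length(idx)
    if (n < 3L) {
      stop_with("gf_size_error",
                "class '%s' has %d images, fewer than the 3 partitions", lab, n)
    }
    idx <- with_rng_seed(derive_seed(seed, paste0("split_", lab)), sample(idx))
    n_va <- floor(n * fractions[2])
    n_te <- floor(n * fractions[3])
    n_tr <- n - n_va - n_te   # floor(train) + both remainders
    take <- list(train = idx[seq_len(n_tr)],
                 validation = idx[n_tr + seq_len(n_va)],
                 test = idx[n_tr + n_va + seq_len(n_te)])
    for (p in names(parts)) parts[[p]] <- c(parts[[p]], corpus[take[[p]]])
  }
  structure(list(train = parts$train, validation = parts$validation,
                 test = parts$test, fractions = fractions,
                 seed = as.integer(seed)),
            class = "corpus_partitions")
}

#' @export
print.corpus_partitions <- function(x, ...) {
  for (p in c("train", "validation", "test")) {
    tab <- table(vapply(x[[p]], function(im) im$label, ""))
    cat(sprintf("%-10s %4d images (%s)\n", p, length(x[[p]]),
                paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Write an `id,label,partition` manifest CSV for a split
#'
#' @param partitions a [split_corpus()] result.
#' @param file output CSV path.
#' @export
write_partition_manifest <- function(partitions, file) {
  rows <- do.call(rbind, lapply(c("train", "validation", "test"), function(p) {
    data.frame(id = vapply(partitions[[p]], function(im) im$id, ""),
               label = vapply(partitions[[p]], function(im) im$label, ""),
               partition = rep(p, length(partitions[[p]])))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Audit the class counts of a prepared two-class corpus directory
#'
#' Counts images per class subfolder. For a corpus prepared from the RSNA
#' pneumonia challenge data (keeping only the "Normal" and "Lung Opacity"
#' classes and removing duplicate patients), the published preparation yields
#' 8,851 normal and 6,012 opacity images, 14,863 in total; the exact
#' deduplication rule is not part of this package, so those totals are
#' documented expectations for an externally prepared directory, not
#' something this function enforces.
#'
#' @param path directory with two class subfolders.
#' @return named integer vector: per-class counts plus `total`.
#' @export
corpus_counts <- function(path) {
  subs <- sort(list.dirs(path, recursive = FALSE))
  if (length(subs) != 2L) {
    stop_with("gf_layout_error", "expected exactly 2 class subfolders in '%s'", path)
  }
  n <- vapply(subs, function(d) length(list.files(d, pattern = "\\.png$",
                                                  ignore.case = TRUE)), 1L)
  out <- c(n, sum(n))
  names(out) <- c(basename(subs), "total")
  out
}
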