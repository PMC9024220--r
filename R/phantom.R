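#' Parameters for the synthetic lung-phantom generator
#'
#' The phantom generator produces two-class grayscale images whose only class
#' difference is smooth textural opacity inside a lung-shaped mask: class
#' `CLASS_X` plays the role of a normal frontal chest radiograph, class
#' `CLASS_Y` the role of one showing lung opacities (the radiographic
#' correlate of pneumonia). Geometry (background, two elliptical lung fields,
#' rib-like banding) is identical across classes; only the opacity texture
#' differs, so a classifier trained on a phantom corpus must rely on texture,
#' not position.
#'
#' @param image_size pixels per side of the square image (>= 16, default 64).
#' @param opacity_amplitude additive intensity of each opacity blob, in (0, 1]
#'   (default 0.35). Zero is allowed and produces images identical to
#'   `CLASS_X` ones, which is useful for null controls.
#' @param n_blobs number of opacity blobs per diseased image (default 3).
#' @param blob_sigma Gaussian spread of each blob in pixels
#'   (default `image_size / 8`).
#' @param noise_sd standard deviation of per-pixel Gaussian noise added last
#'   (default 0.03).
#' @param seed integer seed; every image's RNG stream is derived from
#'   `(seed, id)` so corpora are order-independent.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 64L, opacity_amplitude = 0.35,
                           n_blobs = 3L, blob_sigma = image_size / 8,
                           noise_sd = 0.03, seed = 1L) {
  if (image_size < 16) {
    stop_with("gf_parameter_error", "image_size must be >= 16, got %s", image_size)
  }
  if (opacity_amplitude < 0 || opacity_amplitude > 1) {
    stop_with("gf_parameter_error", "opacity_amplitude must lie in [0, 1]")
  }
  if (n_blobs < 1) stop_with("gf_parameter_error", "n_blobs must be >= 1")
  if (noise_sd < 0) stop_with("gf_parameter_error", "noise_sd must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 opacity_amplitude = opacity_amplitude,
                 n_blobs = as.integer(n_blobs),
                 blob_sigma = blob_sigma,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# deterministic lung-field geometry shared by both classes
phantom_geometry <- function(image_size) {
  s <- image_size
  xs <- (seq_len(s) - 0.5) / s
  gx <- matrix(xs, s, s, byrow = TRUE)   # column coordinate
  gy <- matrix(xs, s, s)                 # row coordinate
  lung <- (((gx - 0.30) / 0.16)^2 + ((gy - 0.52) / 0.30)^2 <= 1) |
          (((gx - 0.70) / 0.16)^2 + ((gy - 0.52) / 0.30)^2 <= 1)
  base <- matrix(0.75, s, s)
  base[lung] <- base[lung] - 0.38
  ribs <- 0.05 * sin(2 * pi * gy * 8)    # rib-like periodic banding
  list(base = base + ribs, mask = lung, gx = gx, gy = gy)
}

#' Generate a single phantom image
#'
#' @param params a [phantom_params()] object.
#' @param label `"CLASS_X"` (normal) or `"CLASS_Y"` (opacity).
#' @param seed integer seed for this image's RNG stream. Images generated with
#'   the same seed share geometry and pixel noise exactly, so an X/Y pair at
#'   one seed differs only by the opacity blobs.
#' @param components if `TRUE`, attach the noise-free image and the lung mask
#'   as attributes `"clean"` and `"mask"` (diagnostics).
#' @return a `labeled_image`: list with `pixels` (square matrix in \[0, 1\]),
#'   `label` and `id`.
#' @export
generate_phantom <- function(params, label = c("CLASS_X", "CLASS_Y"),
                             seed = params$seed, components = FALSE) {
  if (!inherits(params, "phantom_params")) {
    stop_with("gf_parameter_error", "params must be a phantom_params object")
  }
  label <- match.arg(label)
  s <- params$image_size
  geo <- phantom_geometry(s)
  img <- geo$base

  if (label == "CLASS_Y" && params$opacity_amplitude > 0) {
    blob <- with_rng_seed(derive_seed(seed, "blobs"), {
      field <- matrix(0, s, s)
      inside <- which(geo$mask, arr.ind = TRUE)
      for (b in seq_len(params$n_blobs)) {
        ctr <- inside[sample.int(nrow(inside), 1L), ]
        cy <- (ctr[1] - 0.5) / s
        cx <- (ctr[2] - 0.5) / s
        sg <- params$blob_sigma / s * stats::runif(1, 0.7, 1.3)
        field <- field + params$opacity_amplitude *
          exp(-(((geo$gx - cx)^2 + (geo$gy - cy)^2) / (2 * sg^2)))
      }
      field * geo$mask
    })
    img <- img + blob
  }

  if (params$noise_sd > 0) {
    img <- img + with_rng_seed(derive_seed(seed, "noise"),
                               matrix(stats::rnorm(s * s, 0, params$noise_sd), s, s))
  }
  img <- clip01(img)
  out <- structure(list(pixels = img, label = label,
                        id = sprintf("%s_seed%d", label, seed)),
                   class = "labeled_image")
  if (components) {
    attr(out, "mask") <- geo$mask
    attr(out, "clean") <- clip01(geo$base)
  }
  out
}

#' Generate a balanced two-class phantom corpus
#'
#' @param params a [phantom_params()] object.
#' @param n_per_class images per class (>= 1).
#' @return a list of `2 * n_per_class` `labeled_image` objects (class
#'   `phantom_corpus`), with unique ids, reproducible from `params$seed`.
#' @export
make_corpus <- function(params, n_per_class) {
  if (n_per_class < 1) stop_with("gf_parameter_error", "n_per_class must be >= 1")
  out <- vector("list", 2L * n_per_class)
  k <- 0L
  for (label in c("CLASS_X", "CLASS_Y")) {
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%04d", label, i)
      img <- generate_phantom(params, label, seed = derive_seed(params$seed, id))
      img$id <- id
      k <- k + 1L
      out[[k]] <- img
    }
  }
  structure(out, class = c("phantom_corpus", "list"), params = params)
}

#' Write a corpus as an 8-bit grayscale PNG directory tree
#'
#' Emits `root/CLASS_X/*.png` and `root/CLASS_Y/*.png`, the layout
#' [load_image_directory()] reads.
#'
#' @param corpus a list of `labeled_image` objects.
#' @param root output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_corpus <- function(corpus, root) {
  files <- character(length(corpus))
  for (i in seq_along(corpus)) {
    im <- corpus[[i]]
    dir <- file.path(root, im$label)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files[i] <- file.path(dir, paste0(im$id, ".png"))
    png::writePNG(im$pixels, files[i])
  }
  invisible(files)
}

#' @export
print.phantom_corpus <- function(x, ...) {
  tab <- table(vapply(x, function(im) im$label, ""))
  cat("phantom corpus:", length(x), "images (",
      paste(sprintf("%s = %d", names(tab), tab), collapse = ", "), ")\n")
  cat("image size:", attr(x, "params")$image_size, "px\n")
  invisible(x)
}
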