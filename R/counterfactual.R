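#' Generate a counterfactual explanation for one image
#'
#' The image is first classified; the generator is then chosen by the
#' classifier's own prediction (G for predicted `CLASS_X`, F for predicted
#' `CLASS_Y`), never by the ground-truth label, so the explanation answers
#' "what would this image have to look like for the classifier to decide
#' otherwise". The translated image is mapped back to \[0, 1\] and
#' re-classified; `flipped` records whether the hard prediction changed.
#'
#' @param image a `labeled_image` or a pixel matrix in \[0, 1\].
#' @param classifier a trained `gf_classifier`.
#' @param G,F the two generators (X to Y and Y to X).
#' @return an object of class `counterfactual_result` with fields `original`,
#'   `original_prediction`, `routed_generator`, `counterfactual`,
#'   `counterfactual_prediction`, `flipped`.
#' @export
generate_counterfactual <- function(image, classifier, G, F) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  if (!is.matrix(px) || nrow(px) != ncol(px)) {
    stop_with("gf_shape_error", "image must be a square pixel matrix")
  }
  p0 <- predict_probabilities(classifier, px)
  pred0 <- if (p0[["p_Y"]] > p0[["p_X"]]) "CLASS_Y" else "CLASS_X"
  gen <- if (pred0 == "CLASS_X") G else F
  out <- translate(gen, 2 * px - 1)
  cf <- clip01((out + 1) / 2)
  p1 <- predict_probabilities(classifier, cf)
  pred1 <- if (p1[["p_Y"]] > p1[["p_X"]]) "CLASS_Y" else "CLASS_X"
  structure(list(original = px, original_prediction = p0,
                 routed_generator = if (pred0 == "CLASS_X") "G" else "F",
                 counterfactual = cf, counterfactual_prediction = p1,
                 flipped = pred0 != pred1),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  cat(sprintf("original prediction:      p_X = %.4f, p_Y = %.4f\n",
              x$original_prediction[["p_X"]], x$original_prediction[["p_Y"]]))
  cat("routed generator:        ", x$routed_generator, "\n")
  cat(sprintf("counterfactual prediction: p_X = %.4f, p_Y = %.4f\n",
              x$counterfactual_prediction[["p_X"]],
              x$counterfactual_prediction[["p_Y"]]))
  cat("prediction flipped:      ", x$flipped, "\n")
  invisible(x)
}

#' Linear interpolation between an image and its counterfactual
#'
#' Elementwise `(1 - alpha) * original + alpha * counterfactual`; the
#' inference-time analogue of a slider blending the original radiograph into
#' its counterfactual.
#'
#' @param original,counterfactual images of matching shape.
#' @param alpha mixing weight in \[0, 1\].
#' @return the blended image.
#' @export
interpolate_images <- function(original, counterfactual, alpha) {
  if (!identical(dim(original), dim(counterfactual))) {
    stop_with("gf_shape_error", "images differ in shape")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop_with("gf_parameter_error", "alpha must be a scalar in [0, 1]")
  }
  (1 - alpha) * original + alpha * counterfactual
}

#' Flip-rate confusion matrices over a labeled test set
#'
#' Runs [generate_counterfactual()] on every image, then bins the results by
#' ground-truth label: `matrix_normal` (over `CLASS_X` images) and
#' `matrix_pneumonia` (over `CLASS_Y` images) count predicted classes before
#' translation (rows) against after translation (columns); `matrix_total` is
#' their sum. The flip accuracy of a subset is the fraction of
#' counterfactuals that changed the classifier's prediction. Routing uses
#' the predicted label while binning uses the true label, so misclassified
#' inputs contribute to their true class's matrix but are routed by what the
#' classifier believed.
#'
#' @param test non-empty list of `labeled_image`s containing both classes.
#' @param classifier a trained `gf_classifier`.
#' @param G,F the two generators.
#' @return an object of class `flip_rate_report`.
#' @export
flip_rate_report <- function(test, classifier, G, F) {
  if (!length(test)) stop_with("gf_parameter_error", "test set is empty")
  truth <- vapply(test, function(im) im$label, "")
  for (lab in c("CLASS_X", "CLASS_Y")) {
    if (!any(truth == lab)) {
      stop_with("gf_evaluation_error", "test set contains no '%s' images", lab)
    }
  }
  lv <- c("CLASS_X", "CLASS_Y")
  empty <- matrix(0L, 2, 2, dimnames = list(before = lv, after = lv))
  mats <- list(CLASS_X = empty, CLASS_Y = empty)
  flips <- list(CLASS_X = logical(0), CLASS_Y = logical(0))
  for (i in seq_along(test)) {
    r <- generate_counterfactual(test[[i]], classifier, G, F)
    pre <- if (r$routed_generator == "G") "CLASS_X" else "CLASS_Y"
    post <- if (r$counterfactual_prediction[["p_Y"]] >
                r$counterfactual_prediction[["p_X"]]) "CLASS_Y" else "CLASS_X"
    lab <- truth[i]
    mats[[lab]][pre, post] <- mats[[lab]][pre, post] + 1L
    flips[[lab]] <- c(flips[[lab]], r$flipped)
  }
  acc_x <- mean(flips$CLASS_X)
  acc_y <- mean(flips$CLASS_Y)
  n_x <- length(flips$CLASS_X)
  n_y <- length(flips$CLASS_Y)
  structure(list(matrix_normal = mats$CLASS_X,
                 matrix_pneumonia = mats$CLASS_Y,
                 matrix_total = mats$CLASS_X + mats$CLASS_Y,
                 accuracy_normal = acc_x, accuracy_pneumonia = acc_y,
                 accuracy_total = (n_x * acc_x + n_y * acc_y) / (n_x + n_y)),
            class = "flip_rate_report")
}

#' @export
print.flip_rate_report <- function(x, ...) {
  cat(sprintf("flip accuracy: total %.2f%%  normal %.2f%%  pneumonia %.2f%%\n",
              100 * x$accuracy_total, 100 * x$accuracy_normal,
              100 * x$accuracy_pneumonia))
  cat("\nnormal (CLASS_X) images:\n"); print(x$matrix_normal)
  cat("\npneumonia (CLASS_Y) images:\n"); print(x$matrix_pneumonia)
  cat("\nall images:\n"); print(x$matrix_total)
  invisible(x)
}

#' Export an explanation as PNG frames plus a JSON sidecar
#'
#' Writes the original, the counterfactual, `n_frames` linear interpolation
#' frames between them, and a signed pixel-difference map rescaled so zero
#' difference is mid-gray and the largest absolute difference reaches the
#' display extremes.
#'
#' @param result a `counterfactual_result`.
#' @param n_frames number of interpolation frames (>= 2; default 11, i.e.
#'   alpha steps of 0.1).
#' @param out output directory (created if missing).
#' @return invisibly, the sidecar path.
#' @export
export_explanation <- function(result, n_frames = 11L, out) {
  if (n_frames < 2L) stop_with("gf_parameter_error", "n_frames must be >= 2")
  if (!dir.exists(out)) {
    ok <- dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_with("gf_io_error", "cannot create directory '%s'", out)
  }
  png::writePNG(result$original, file.path(out, "original.png"))
  png::writePNG(result$counterfactual, file.path(out, "counterfactual.png"))
  alphas <- seq(0, 1, length.out = n_frames)
  for (i in seq_along(alphas)) {
    frame <- interpolate_images(result$original, result$counterfactual,
                                alphas[i])
    png::writePNG(clip01(frame), file.path(out, sprintf("frame_%03d.png", i)))
  }
  d <- result$counterfactual - result$original
  m <- max(abs(d))
  diffmap <- if (m > 0) d / (2 * m) + 0.5 else d + 0.5
  png::writePNG(diffmap, file.path(out, "difference.png"))
  sidecar <- file.path(out, "explanation.json")
  jsonlite::write_json(
    list(original_prediction = as.list(result$original_prediction),
         counterfactual_prediction = as.list(result$counterfactual_prediction),
         routed_generator = result$routed_generator,
         flipped = result$flipped, n_frames = n_frames),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
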