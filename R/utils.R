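# Seed plumbing and small shared helpers.

# One global seed fans out to named per-purpose streams so that, e.g., the
# image drawn for id "CLASS_Y_0007" does not depend on how many images were
# generated before it.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * (31L^(seq_along(utf8ToInt(as.character(tag))) %% 7L)))
  val <- (as.numeric(seed) * 48271 + h * 16807) %% 2147483647
  as.integer(val)
}

# evaluate expr under a given RNG seed, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

stop_with <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# convert assorted image inputs to an (H, W, 1, N) array in [0, 1]
as_image_batch <- function(x) {
  if (inherits(x, "labeled_image")) x <- x$pixels
  if (is.list(x)) {
    mats <- lapply(x, function(im) if (inherits(im, "labeled_image")) im$pixels else im)
    d <- dim(mats[[1]])
    out <- array(0, c(d[1], d[2], 1, length(mats)))
    for (i in seq_along(mats)) out[, , 1, i] <- mats[[i]]
    return(out)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1, 1)))
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stop_with("gf_shape_error", "cannot interpret input of class '%s' as image batch",
            paste(class(x), collapse = "/"))
}
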