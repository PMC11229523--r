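# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "fruitmorph_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

assert_color_image <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort(sprintf("`%s` must be an H x W x 3 array", arg), "invalid_image")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    abort(sprintf("`%s` channel values must lie in [0, 255]", arg), "invalid_image")
  invisible(img)
}

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img))
    abort(sprintf("`%s` must be an H x W matrix", arg), "invalid_image")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    abort(sprintf("`%s` intensities must lie in [0, 255]", arg), "invalid_image")
  invisible(img)
}

assert_binary_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask))
    abort(sprintf("`%s` must be an H x W matrix", arg), "invalid_mask")
  if (anyNA(mask) || !all(mask %in% c(0, 1)))
    abort(sprintf("`%s` values must be exactly 0 or 1", arg), "invalid_mask")
  invisible(mask)
}

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow(x), ncol(x))
  m
}

# Luminance (ITU-R BT.601 weights) of a color image, still on the 0-255 scale.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}
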