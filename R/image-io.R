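#' Read an 8-bit color photograph
#'
#' Reads a PNG, TIFF or JPEG file into the plain array representation used
#' throughout fruitmorph: an `H x W x 3` numeric array with channel values on
#' the 0-255 scale (row 1 is the top image row).  Grayscale files are
#' replicated across the three channels and any alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An `H x W x 3` numeric array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path), "io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort("the 'tiff' package is required to read TIFF files", "io_error")
      tiff::readTIFF(path)
    },
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort("the 'jpeg' package is required to read JPEG files", "io_error")
      jpeg::readJPEG(path)
    },
    abort(sprintf("unsupported image format: .%s", ext), "io_error")
  )
  if (is.matrix(raw)) raw <- array(raw, c(dim(raw), 1L))
  nc <- dim(raw)[3]
  img <- if (nc >= 3L) raw[, , 1:3, drop = FALSE]
         else array(raw[, , 1L], c(dim(raw)[1:2], 3L))
  img <- img * 255
  assert_color_image(img)
}

#' Write a color image as PNG
#'
#' @param img `H x W x 3` array in `[0, 255]`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_color_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read and write binary masks as PNG (0/255)
#'
#' Masks are stored as 8-bit grayscale PNGs with background 0 and foreground
#' 255; on reading, any pixel above 127 is taken as foreground.
#'
#' @param mask Binary 0/1 matrix.
#' @param path `.png` path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a 0/1 integer matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("mask file not found: %s", path), "io_error")
  raw <- png::readPNG(path)
  if (!is.matrix(raw)) raw <- raw[, , 1]
  as_mask(raw > 0.5)
}

#' Run-length CSV serialization of a binary mask
#'
#' A text alternative to PNG masks: one CSV row per horizontal run of
#' foreground pixels (`row`, `start` column, `length`), with the mask height
#' and width carried in a header row (`row = 0`).
#'
#' @param mask Binary 0/1 matrix.
#' @param path Output `.csv` path.
#' @return `write_mask_rle()` returns `path` invisibly; `read_mask_rle()`
#'   returns the reconstructed 0/1 integer matrix.
#' @export
write_mask_rle <- function(mask, path) {
  assert_binary_mask(mask)
  rows <- integer(0); starts <- integer(0); lens <- integer(0)
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    keep <- r$values == 1
    if (any(keep)) {
      rows <- c(rows, rep(i, sum(keep)))
      starts <- c(starts, (ends - r$lengths + 1L)[keep])
      lens <- c(lens, r$lengths[keep])
    }
  }
  df <- rbind(
    data.frame(row = 0L, start = nrow(mask), length = ncol(mask)),
    data.frame(row = rows, start = starts, length = lens)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_rle
#' @export
read_mask_rle <- function(path) {
  df <- utils::read.csv(path)
  hdr <- df[df$row == 0L, ]
  if (nrow(hdr) != 1L) abort("run-length CSV lacks its dimension header row", "io_error")
  mask <- matrix(0L, hdr$start, hdr$length)
  runs <- df[df$row > 0L, ]
  for (k in seq_len(nrow(runs)))
    mask[runs$row[k], runs$start[k] + seq_len(runs$length[k]) - 1L] <- 1L
  mask
}
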