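#' Single-channel fluorescence image
#'
#' A `channel_image` wraps one stitched fluorescence channel as a 2-D
#' intensity matrix together with its physical pixel size, channel name and
#' bit depth.  Pixel values are raw detector counts (a.u.); position in
#' micrometres is the 0-based pixel index times `pixel_size`, so the pixel
#' at row 1, column 1 sits at (0, 0) um and the x axis runs along columns.
#'
#' @param pixels Numeric matrix of non-negative intensities (rows = y,
#'   columns = x).
#' @param pixel_size Physical size of one pixel in um/px.
#' @param channel Channel name, e.g. `"nuclear"` or `"gfp"`.
#' @param bit_depth Integer bit depth of the acquisition (default 16);
#'   values must lie in `[0, 2^bit_depth - 1]`.
#'
#' @return An object of class `channel_image`.
#' @export
#' @examples
#' img <- channel_image(matrix(100, 32, 32), pixel_size = 1, channel = "dapi")
#' dim(img$pixels)
channel_image <- function(pixels, pixel_size, channel, bit_depth = 16L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (um/px).")
  }
  maxval <- 2^bit_depth - 1
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > maxval) {
    abort(sprintf("pixel values must lie in [0, %d] for bit depth %d",
                  as.integer(maxval), as.integer(bit_depth)))
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel = as.character(channel), bit_depth = as.integer(bit_depth)),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image '%s'> %d x %d px @ %g um/px (%d-bit)\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              x$bit_depth))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

#' Read a channel image from a grayscale TIFF
#'
#' Reads one 16-bit (or 8-bit) grayscale TIFF as raw integer counts; no
#' rescaling is applied, so values round-trip bit-exactly through
#' [write_channel_tiff()].
#'
#' @param path Path to a single-plane grayscale TIFF.
#' @inheritParams channel_image
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path, pixel_size, channel,
                              bit_depth = 16L) {
  if (!file.exists(path)) abort(paste0("TIFF not found: ", path))
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) abort(paste0("expected grayscale TIFF: ", path))
    px <- px[, , 1L]
  }
  channel_image(px * 1.0, pixel_size = pixel_size, channel = channel,
                bit_depth = bit_depth)
}

#' Write a channel image to a grayscale TIFF
#'
#' Values are rounded to integers and written at the image's bit depth;
#' re-reading with [read_channel_tiff()] reproduces them bit-exactly.
#'
#' @param image A [channel_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  stopifnot(inherits(image, "channel_image"))
  maxval <- 2^image$bit_depth - 1
  px <- pmin(pmax(round(image$pixels), 0), maxval)
  ok <- tryCatch(
    tiff::writeTIFF(px / maxval, path,
                    bits.per.sample = as.integer(image$bit_depth)),
    error = function(e) abort(paste0("failed to write TIFF ", path, ": ",
                                     conditionMessage(e)))
  )
  invisible(path)
}
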