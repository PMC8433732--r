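#' Construct a raw RGB image object
#'
#' Wraps an H x W x 3 numeric array of 8-bit channel values (R, G, B order)
#' together with capture metadata. Values must lie in \[0, 255\] unless
#' `allow_headroom = TRUE`, which admits sensor-linear synthetic rasters that
#' exceed the 8-bit range before calibration (see the methods vignette).
#'
#' @param pixels numeric H x W x 3 array, channels in R, G, B order.
#' @param sample_id character scalar identifying the sample.
#' @param capture_date optional `Date` (or coercible string).
#' @param allow_headroom logical; permit values outside \[0, 255\].
#' @return An object of class `raw_image`.
#' @export
raw_image <- function(pixels, sample_id = "sample", capture_date = NULL,
                      allow_headroom = FALSE) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have positive height and width")
  if (!allow_headroom && (min(pixels) < 0 || max(pixels) > 255))
    stop("channel values must lie in [0, 255]")
  structure(
    list(pixels = pixels, sample_id = as.character(sample_id),
         capture_date = if (!is.null(capture_date)) as.Date(capture_date)),
    class = "raw_image")
}

#' @export
print.raw_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raw_image> %s: %d x %d px, range [%.1f, %.1f]\n",
              x$sample_id, d[1], d[2], min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.raw_image <- function(x) dim(x$pixels)

# channel accessors used throughout: 2-d matrices
img_channel <- function(img, i) {
  px <- if (inherits(img, "raw_image") || inherits(img, "corrected_image"))
    img$pixels else img
  px[, , i]
}

#' Read an 8-bit PNG as a raw image
#'
#' @param path PNG file path.
#' @inheritParams raw_image
#' @return A [raw_image()].
#' @export
read_image <- function(path, sample_id = sub("\\.png$", "", basename(path)),
                       capture_date = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  else a <- array(a[, , 1L], c(dim(a)[1:2], 3L))
  raw_image(a * 255, sample_id = sample_id, capture_date = capture_date)
}

#' Write an image (raw or corrected) to an 8-bit PNG
#'
#' Values are clipped to \[0, 255\] and quantized on write only; in-memory
#' corrected rasters stay real-valued.
#'
#' @param img a `raw_image` or `corrected_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (is.list(img)) img$pixels else img
  png::writePNG(pmin(pmax(px, 0), 255) / 255, path)
  invisible(path)
}

#' Write a boolean mask as a single-channel PNG (255 = retained)
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a single-channel PNG mask written by [write_mask()]
#' @param path PNG path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0.5
}

clip255 <- function(x) pmin(pmax(x, 0), 255)
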