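#' Measure calibration-patch statistics
#'
#' Computes the per-channel arithmetic mean over each of the white, black and
#' gray patch regions of a board photograph.
#'
#' @param image a [raw_image()] (or an H x W x 3 array).
#' @param regions named list `white`, `black`, `gray`, each a 2-column
#'   (row, col) index matrix of pixels inside that patch.
#' @return A `calibration_patches` list: `white_mean`, `black_mean`,
#'   `gray_mean` (length-3 RGB), and the regions used.
#' @export
measure_patches <- function(image, regions) {
  px <- if (is.list(image)) image$pixels else image
  d <- dim(px)
  need <- c("white", "black", "gray")
  if (!all(need %in% names(regions))) stop("regions must name white, black, gray")
  means <- lapply(regions[need], function(idx) {
    idx <- as.matrix(idx)
    if (nrow(idx) == 0L) stop("patch-location failure: empty patch region")
    if (any(idx[, 1] < 1 | idx[, 1] > d[1] | idx[, 2] < 1 | idx[, 2] > d[2]))
      stop("patch-location failure: region outside image bounds")
    vapply(1:3, function(ch) mean(px[cbind(idx, ch)]), numeric(1))
  })
  structure(list(white_mean = means$white, black_mean = means$black,
                 gray_mean = means$gray, regions = regions[need]),
            class = "calibration_patches")
}

#' Contrast correction by white/black histogram stretch
#'
#' Per channel, maps the black-patch mean to 0 and the white-patch mean to
#' 255: `Ic = 255 (I - Ibl) / (Iw - Ibl)`, clipped to \[0, 255\].
#'
#' @param image a [raw_image()] or numeric array.
#' @param patches a `calibration_patches` object from [measure_patches()].
#' @return A `corrected_image` list with real-valued `pixels`.
#' @export
contrast_correct <- function(image, patches) {
  px <- if (is.list(image)) image$pixels else image
  iw <- patches$white_mean; ibl <- patches$black_mean
  if (any(iw <= ibl))
    stop("calibration failure: white patch not brighter than black patch")
  out <- px
  for (ch in 1:3)
    out[, , ch] <- clip255(255 * (px[, , ch] - ibl[ch]) / (iw[ch] - ibl[ch]))
  structure(list(pixels = out, gamma_used = 1,
                 sample_id = if (is.list(image)) image$sample_id else NA),
            class = "corrected_image")
}

#' Solve the gamma that maps the gray patch to 119
#'
#' The 18%-reflectance gray card is (119, 119, 119) in RGB. Given the gray
#' patch's observed value `Ig` (after contrast correction), returns the gamma
#' for which `255 (Ig/255)^gamma = 119`.
#'
#' @param gray_value observed gray-patch value, in (0, 255).
#' @return positive gamma.
#' @export
solve_gamma <- function(gray_value) {
  if (gray_value <= 0 || gray_value >= 255)
    stop("degenerate gray patch: no gamma solution for Ig in {0, 255}")
  log(119 / 255) / log(gray_value / 255)
}

#' Apply gamma correction
#'
#' `Igm = 255 (Ic / 255)^gamma` per channel; monotone, with 0 and 255 fixed.
#'
#' @param image a `corrected_image` (or array of values in \[0, 255\]).
#' @param gamma positive exponent.
#' @return A `corrected_image` with `gamma_used` recorded.
#' @export
gamma_correct <- function(image, gamma) {
  if (gamma <= 0) stop("invalid parameter: gamma must be positive")
  px <- if (is.list(image)) image$pixels else image
  out <- 255 * (pmax(px, 0) / 255)^gamma
  structure(list(pixels = out, gamma_used = gamma,
                 sample_id = if (is.list(image)) image$sample_id else NA),
            class = "corrected_image")
}

#' Per-pixel channel spread used for halation flagging
#'
#' The population standard deviation of a pixel's three channel values:
#' `sigma = sqrt(((R-Ave)^2 + (G-Ave)^2 + (B-Ave)^2) / 3)`. Specular glare
#' (halation) is nearly achromatic, so low sigma flags it.
#'
#' @param r,g,b numeric vectors (or an image when `g`, `b` are missing).
#' @return numeric vector (or matrix for an image input) of sigma values.
#' @export
halation_sigma <- function(r, g = NULL, b = NULL) {
  if (is.null(g)) {
    px <- if (is.list(r)) r$pixels else r
    r0 <- px[, , 1]; g0 <- px[, , 2]; b0 <- px[, , 3]
  } else { r0 <- r; g0 <- g; b0 <- b }
  ave <- (r0 + g0 + b0) / 3
  sqrt(((r0 - ave)^2 + (g0 - ave)^2 + (b0 - ave)^2) / 3)
}

#' Halation retention mask
#'
#' Pixels are retained iff their channel sigma is at least `threshold`
#' (default 35); flagged pixels are excluded from all downstream index
#' means. The raster geometry is preserved: this is a mask, not a deletion.
#'
#' @param image a `corrected_image` (or array).
#' @param threshold non-negative sigma cut, default 35.
#' @return A `halation_mask` list: logical `retained`, `sigma_threshold`.
#' @export
halation_mask <- function(image, threshold = 35) {
  if (threshold < 0) stop("threshold must be non-negative")
  sig <- halation_sigma(image)
  structure(list(retained = sig >= threshold, sigma_threshold = threshold),
            class = "halation_mask")
}

#' Full color calibration of a board photograph
#'
#' Locates the calibration patches (from detected anchors and the board
#' layout, unless explicit `regions` are given), applies the white/black
#' contrast stretch, solves gamma from the stretched gray patch's luminance
#' (one gamma for all three channels), applies gamma correction, and flags
#' halation on the corrected image.
#'
#' @inheritParams measure_patches
#' @param layout a [board_layout()].
#' @param anchors optional pre-detected [detect_anchors()] result.
#' @param regions optional explicit patch regions (overrides layout lookup).
#' @param sigma_threshold halation sigma cut, default 35.
#' @return A `calibrated_board` list: `corrected` (corrected_image),
#'   `patches`, `gamma`, `halation`, `anchors`, `transform`, and a `report`
#'   list (gamma, patch means, halation fraction).
#' @export
calibrate_image <- function(image, layout = board_layout(), anchors = NULL,
                            regions = NULL, sigma_threshold = 35) {
  tr <- NULL
  if (is.null(regions)) {
    if (is.null(anchors)) anchors <- detect_anchors(image)
    tr <- fit_transform(layout$marker_centers, anchors$centers_px[, c(2, 1)])
    d <- dim(image$pixels)
    regions <- lapply(layout$patches, function(rect)
      region_from_rect(tr, rect, d[1:2], shrink = 0.6))
    names(regions) <- names(layout$patches)
  }
  patches <- measure_patches(image, regions)
  ic <- contrast_correct(image, patches)
  # gray-patch luminance after the stretch drives a single gamma
  idx <- as.matrix(patches$regions$gray)
  gray_rgb <- vapply(1:3, function(ch) mean(ic$pixels[cbind(idx, ch)]),
                     numeric(1))
  ig <- sum(gray_rgb * c(0.299, 0.587, 0.114))
  gamma <- solve_gamma(ig)
  igm <- gamma_correct(ic, gamma)
  igm$sample_id <- if (is.list(image)) image$sample_id else NA
  hal <- halation_mask(igm, sigma_threshold)
  structure(list(
    corrected = igm, patches = patches, gamma = gamma, halation = hal,
    anchors = anchors, transform = tr,
    report = list(gamma = gamma,
                  white_mean = patches$white_mean,
                  black_mean = patches$black_mean,
                  gray_mean = patches$gray_mean,
                  halation_fraction = mean(!hal$retained))),
    class = "calibrated_board")
}
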