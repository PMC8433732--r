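#' Detect the four corner fiducial markers
#'
#' Finds bright square blobs (the white marker backings) on the dark board,
#' keeps candidates whose interior contains the dark module pattern, assigns
#' one to each image corner, and decodes the payloads from the module grid
#' mapped through the anchor-fitted affine transform. Works for board
#' rotations up to about 10 degrees.
#'
#' @param image a [raw_image()].
#' @param layout a [board_layout()] giving marker geometry.
#' @return A `qr_anchors` list: `centers_px` (4 x 2 row/col matrix in order
#'   tl, tr, bl, br), `payloads` (character length 4, `NA` where a payload
#'   failed its checksum), `sample_code`.
#' @export
detect_anchors <- function(image, layout = board_layout()) {
  px <- if (is.list(image)) image$pixels else image
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  d <- dim(gray)
  # bright threshold relative to the image's own bright end (robust to the
  # unclipped gain/offset/gamma distortions of field lighting)
  thr <- 0.5 * (stats::quantile(gray, 0.999) + stats::median(gray))
  bright <- gray > thr
  # the black ring splits a marker into several bright components; filling
  # enclosed holes makes each marker one solid square whose centroid is
  # rotation-invariant
  filled <- EBImage::fillHull(EBImage::Image(bright * 1))
  labm <- EBImage::imageData(EBImage::bwlabel(filled))
  nlab <- max(labm)
  if (nlab < 1) stop("anchor-detection failure: found 0 markers")
  idx <- which(labm > 0, arr.ind = TRUE)
  labv <- labm[idx]
  cand <- list()
  for (l in seq_len(nlab)) {
    pts <- idx[labv == l, , drop = FALSE]
    if (nrow(pts) < 100) next
    rr <- range(pts[, 1]); cc <- range(pts[, 2])
    h <- diff(rr) + 1; w <- diff(cc) + 1
    if (h / w > 1.45 || w / h > 1.45) next      # not square
    # a square rotated up to ~10 deg fills >= ~0.75 of its bbox
    if (nrow(pts) / (h * w) < 0.6) next         # not solid after filling
    # markers carry dark modules inside; uniform bright patches do not
    fill_orig <- sum(bright[rr[1]:rr[2], cc[1]:cc[2]]) / (h * w)
    if (fill_orig < 0.25 || fill_orig > 0.65) next
    cand[[length(cand) + 1]] <- list(
      center = c(mean(pts[, 1]), mean(pts[, 2])), size = (h + w) / 2)
  }
  if (length(cand) < 4)
    stop(sprintf("anchor-detection failure: found %d markers", length(cand)))
  centers <- do.call(rbind, lapply(cand, `[[`, "center"))
  corners <- rbind(c(1, 1), c(1, d[2]), c(d[1], 1), c(d[1], d[2]))
  pick <- integer(4)
  for (k in 1:4) {
    dist <- sqrt((centers[, 1] - corners[k, 1])^2 +
                 (centers[, 2] - corners[k, 2])^2)
    pick[k] <- which.min(dist)
  }
  if (length(unique(pick)) < 4)
    stop("anchor-detection failure: markers do not occupy four corners")
  centers_px <- centers[pick, , drop = FALSE]           # tl, tr, bl, br
  rownames(centers_px) <- c("tl", "tr", "bl", "br")
  # affine fit mm -> (col,row) from the four centers, then decode payloads
  tr <- fit_transform(layout$marker_centers, centers_px[, c(2, 1)])
  m <- layout$marker_module_mm
  payloads <- character(4)
  for (k in 1:4) {
    cen <- layout$marker_centers[k, ]
    off <- (seq_len(MARKER_MODULES) - (MARKER_MODULES + 1) / 2) * m
    grid_mm <- cbind(rep(cen[1] + off, each = MARKER_MODULES),
                     rep(cen[2] + off, times = MARKER_MODULES))
    pxy <- mm_to_px(tr, grid_mm)
    rows <- pmin(pmax(round(pxy[, 2]), 1), d[1])
    cols <- pmin(pmax(round(pxy[, 1]), 1), d[2])
    vals <- gray[cbind(rows, cols)]
    cut <- (min(vals) + max(vals)) / 2
    # vals iterate y (module row) fastest: column-major into the pattern
    pat <- matrix(as.integer(vals < cut), MARKER_MODULES, MARKER_MODULES)
    dec <- decode_marker(pat)
    payloads[k] <- if (is.null(dec)) NA_character_ else dec
  }
  codes <- sub("^[0-9]{8}-", "", payloads[!is.na(payloads)])
  structure(list(centers_px = centers_px, payloads = payloads,
                 sample_code = if (length(codes)) codes[1] else NA_character_,
                 transform = tr),
            class = "qr_anchors")
}

#' Crop the region of interest anchored on the corner markers
#'
#' Maps the layout's fixed ROI window (board millimeters) through the
#' anchor-fitted affine transform and resamples it (nearest neighbor) to an
#' axis-aligned raster in board coordinates. The same index map can be
#' applied to any companion raster (e.g., ground-truth masks or the halation
#' mask) with [crop_apply()].
#'
#' @param image a [raw_image()] or `corrected_image`.
#' @param anchors a [detect_anchors()] result (`NULL` with an identity
#'   layout returns the input raster unchanged).
#' @param layout a [board_layout()].
#' @return An `roi_raster` list: `pixels` (h x w x 3), `index` (h x w matrix
#'   of linear source-pixel indices), `window` (the mm window).
#' @export
crop_roi <- function(image, anchors = NULL, layout = board_layout()) {
  px <- if (is.list(image)) image$pixels else image
  d <- dim(px)
  if (isTRUE(layout$identity)) {
    return(structure(list(pixels = px,
                          index = matrix(seq_len(d[1] * d[2]), d[1], d[2]),
                          window = c(0, 0, d[2], d[1])),
                     class = "roi_raster"))
  }
  if (is.null(anchors)) stop("anchors required for a non-identity layout")
  tr <- fit_transform(layout$marker_centers, anchors$centers_px[, c(2, 1)])
  s <- transform_scale(tr)
  w_mm <- layout$roi[3]; h_mm <- layout$roi[4]
  out_w <- max(1L, round(w_mm * s)); out_h <- max(1L, round(h_mm * s))
  xs <- layout$roi[1] + (seq_len(out_w) - 0.5) / s
  ys <- layout$roi[2] + (seq_len(out_h) - 0.5) / s
  mm <- cbind(rep(xs, each = out_h), rep(ys, times = out_w))
  pxy <- mm_to_px(tr, mm)
  rows <- round(pxy[, 2]); cols <- round(pxy[, 1])
  if (any(rows < 1 | rows > d[1] | cols < 1 | cols > d[2]))
    stop("cropping failure: ROI window exceeds image bounds")
  lin <- matrix((cols - 1) * d[1] + rows, out_h, out_w)
  out <- array(0, c(out_h, out_w, 3))
  npx <- d[1] * d[2]
  for (ch in 1:3) out[, , ch] <- px[(ch - 1) * npx + lin]
  structure(list(pixels = out, index = lin,
                 window = layout$roi), class = "roi_raster")
}

#' Resample a companion raster through an ROI crop's index map
#'
#' @param roi an `roi_raster` from [crop_roi()].
#' @param x a matrix (mask) or H x W x 3 array aligned with the source image.
#' @return The cropped matrix or array.
#' @export
crop_apply <- function(roi, x) {
  if (is.matrix(x)) {
    out <- x[roi$index]
    dim(out) <- dim(roi$index)
    return(out)
  }
  npx <- dim(x)[1] * dim(x)[2]
  out <- array(0, c(dim(roi$index), 3))
  for (ch in 1:3) out[, , ch] <- x[(ch - 1) * npx + roi$index]
  out
}

#' Default background-removal thresholds
#'
#' `exg_cut` 150 (rubber band), `hue_card_cut` 60 degrees (card remnants),
#' `gray_cut` 150 (shadow / bright card), `stem_hue_cut` in \[25, 35\]
#' (panicle stem; tuned per sample by grain color), `halation_cut` 35.
#'
#' @param stem_hue_cut stem hue threshold, degrees in \[25, 35\].
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(stem_hue_cut = 35) {
  if (stem_hue_cut < 25 || stem_hue_cut > 35)
    stop("stem_hue_cut must lie in [25, 35]")
  list(exg_cut = 150, hue_card_cut = 60, gray_cut = 150,
       stem_hue_cut = stem_hue_cut, halation_cut = 35)
}

#' Isolate grain pixels with the sequential threshold cascade
#'
#' Halation-flagged pixels are excluded first, then four stages run in
#' order: (1) excess green `ExG > exg_cut` removes the rubber band;
#' (2) hue `H1 > hue_card_cut` removes card remnants; (3) grayscale
#' `Gray > gray_cut` removes shadow and bright card; (4) hue
#' `H1 < stem_hue_cut` removes the stem. Remaining pixels are the grain.
#'
#' @param roi an `roi_raster`, `corrected_image`, or H x W x 3 array.
#' @param thresholds a [default_thresholds()] list.
#' @param halation optional logical matrix (TRUE = retained) aligned with
#'   the ROI, typically `crop_apply(roi, calib$halation$retained)`.
#' @return A `grain_mask` list: logical `retained`, integer `stage_counts`
#'   (halation, band, card, shadow, stem), `n_roi`.
#' @export
remove_background <- function(roi, thresholds = default_thresholds(),
                              halation = NULL) {
  px <- if (is.list(roi)) roi$pixels else roi
  d <- dim(px)[1:2]
  r <- matrix(px[, , 1], d[1], d[2])
  g <- matrix(px[, , 2], d[1], d[2])
  b <- matrix(px[, , 3], d[1], d[2])
  alive <- matrix(TRUE, d[1], d[2])
  counts <- c(halation = 0L, band = 0L, card = 0L, shadow = 0L, stem = 0L)
  if (!is.null(halation)) {
    counts["halation"] <- sum(alive & !halation)
    alive <- alive & halation
  }
  exg <- 2 * g - r - b
  hue <- hue_deg(r, g, b)
  gray <- 0.299 * r + 0.587 * g + 0.114 * b
  stage <- function(alive, cond, nm) {
    hit <- alive & cond
    counts[nm] <<- sum(hit)
    alive & !hit
  }
  alive <- stage(alive, exg > thresholds$exg_cut, "band")
  alive <- stage(alive, hue > thresholds$hue_card_cut, "card")
  alive <- stage(alive, gray > thresholds$gray_cut, "shadow")
  alive <- stage(alive, hue < thresholds$stem_hue_cut, "stem")
  if (!any(alive))
    warning("no grain found: empty mask after background removal")
  structure(list(retained = alive, stage_counts = counts,
                 n_roi = prod(d)), class = "grain_mask")
}
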