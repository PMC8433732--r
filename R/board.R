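#' Default correction-board layout
#'
#' Geometry of the 30 cm x 10 cm correction board, in board millimeters with
#' the origin at the board's upper-left corner (x right, y down). The board
#' carries four corner fiducial markers, three calibration patches (white,
#' black, 18% gray) along the left edge, and a central grain zone that the
#' region of interest (ROI) window covers while excluding markers and
#' patches.
#'
#' @param board_mm numeric length-2, board width and height in mm.
#' @param marker_module_mm side of one marker module in mm.
#' @param roi numeric length-4 `c(x0, y0, w, h)` ROI window in mm.
#' @return A `board_layout` list: marker centers, patch rectangles, ROI.
#' @export
board_layout <- function(board_mm = c(300, 100), marker_module_mm = 1.75,
                         roi = c(60, 27, 234, 46)) {
  half <- marker_module_mm * MARKER_MODULES / 2
  m <- half + 3.5  # marker center inset from board edge
  structure(list(
    board_mm = board_mm,
    marker_module_mm = marker_module_mm,
    # order: top-left, top-right, bottom-left, bottom-right
    marker_centers = rbind(
      tl = c(m, m),
      tr = c(board_mm[1] - m, m),
      bl = c(m, board_mm[2] - m),
      br = c(board_mm[1] - m, board_mm[2] - m)),
    # patch rectangles c(x0, y0, x1, y1), mm
    patches = list(
      white = c(36, 8, 50, 22),
      black = c(36, 43, 50, 57),
      gray  = c(36, 78, 50, 92)),
    roi = roi,
    identity = FALSE), class = "board_layout")
}

#' Identity layout: the ROI window is the whole image
#'
#' Used when an image is already cropped; [crop_roi()] returns its input.
#' @return A `board_layout` with the identity flag set.
#' @export
identity_layout <- function() {
  l <- board_layout()
  l$identity <- TRUE
  l
}

#' Read / write a board layout as YAML
#' @param path YAML file path.
#' @return `read_layout`: a `board_layout`; `write_layout`: `path` invisibly.
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  l <- board_layout(board_mm = as.numeric(y$board_mm),
                    marker_module_mm = y$marker_module_mm,
                    roi = as.numeric(y$roi))
  if (!is.null(y$patches))
    l$patches <- lapply(y$patches, as.numeric)
  l
}

#' @rdname read_layout
#' @param layout a `board_layout`.
#' @export
write_layout <- function(layout, path) {
  yaml::write_yaml(list(board_mm = layout$board_mm,
                        marker_module_mm = layout$marker_module_mm,
                        roi = layout$roi, patches = layout$patches), path)
  invisible(path)
}

## ---- affine board-mm <-> pixel transforms -------------------------------

# forward transform: mm (x, y) -> pixel (col, row)
# represented as list(A = 2x2, t = length-2)
make_transform <- function(px_per_mm, rotation_deg, origin_px) {
  th <- rotation_deg * pi / 180
  A <- px_per_mm * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  list(A = A, t = origin_px)
}

mm_to_px <- function(tr, xy) {
  # xy: n x 2 matrix of mm coords; returns n x 2 (col, row)
  sweep(as.matrix(xy) %*% t(tr$A), 2, tr$t, "+")
}

px_to_mm <- function(tr, cr) {
  Ainv <- solve(tr$A)
  sweep(as.matrix(cr), 2, tr$t, "-") %*% t(Ainv)
}

# least-squares affine fit mm -> px from point correspondences (n >= 3)
fit_transform <- function(mm, px) {
  X <- cbind(as.matrix(mm), 1)
  beta <- qr.solve(X, as.matrix(px))  # 3 x 2
  list(A = t(beta[1:2, , drop = FALSE]), t = as.numeric(beta[3, ]))
}

transform_scale <- function(tr) sqrt(abs(det(tr$A)))

# pixel (row, col) index matrix covering a mm rectangle, optionally shrunk
# toward its center (shrink < 1 guards against localization error)
region_from_rect <- function(tr, rect, dim_hw, shrink = 1) {
  cx <- (rect[1] + rect[3]) / 2; cy <- (rect[2] + rect[4]) / 2
  hw <- (rect[3] - rect[1]) / 2 * shrink
  hh <- (rect[4] - rect[2]) / 2 * shrink
  corners <- mm_to_px(tr, rbind(c(cx - hw, cy - hh), c(cx + hw, cy - hh),
                                c(cx - hw, cy + hh), c(cx + hw, cy + hh)))
  cols <- range(corners[, 1]); rows <- range(corners[, 2])
  rr <- max(1, ceiling(rows[1])):min(dim_hw[1], floor(rows[2]))
  cc <- max(1, ceiling(cols[1])):min(dim_hw[2], floor(cols[2]))
  if (!length(rr) || !length(cc)) return(matrix(0L, 0, 2))
  idx <- as.matrix(expand.grid(row = rr, col = cc))
  # keep pixels whose mm position is inside the shrunk rectangle (handles
  # rotation, where the bounding box overshoots)
  mm <- px_to_mm(tr, idx[, c(2, 1)])
  keep <- abs(mm[, 1] - cx) <= hw & abs(mm[, 2] - cy) <= hh
  idx[keep, , drop = FALSE]
}

## ---- fiducial marker codec ----------------------------------------------

# Marker geometry (in modules): 1-module white quiet ring, 1-module black
# ring, 8 x 8 payload grid. The white backing square spans the full 12
# modules so the marker is detectable as a bright blob on the dark board.
MARKER_MODULES <- 12L

# payload: date as yyyymmdd integer (27 bits), sample id (16 bits),
# checksum (8 bits), 13 fixed sync bits
MARKER_SYNC <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L, 1L, 1L)

int_to_bits <- function(x, nbits) {
  b <- integer(nbits)
  for (i in seq_len(nbits)) { b[i] <- x %% 2; x <- x %/% 2 }
  b
}
bits_to_int <- function(b) sum(b * 2^(seq_along(b) - 1))

payload_checksum <- function(date_int, id_int) {
  (date_int %% 251 + (id_int * 31) %% 251) %% 251
}

#' Encode a marker payload into its module pattern
#'
#' The payload text has the form `"YYYYMMDD-ID"` (sampling date and sample
#' code). Returns the full 12 x 12 module matrix (1 = black module).
#'
#' @param payload character scalar `"YYYYMMDD-ID"`.
#' @return integer 12 x 12 matrix of 0/1 modules.
#' @export
encode_marker <- function(payload) {
  parts <- strsplit(payload, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !grepl("^[0-9]{8}$", parts[1]))
    stop("payload must have the form 'YYYYMMDD-ID'")
  date_int <- as.integer(parts[1])
  id_int <- suppressWarnings(as.integer(parts[2]))
  if (is.na(id_int) || id_int < 0 || id_int > 65535)
    stop("sample id must be an integer in 0..65535")
  bits <- c(int_to_bits(date_int, 27), int_to_bits(id_int, 16),
            int_to_bits(payload_checksum(date_int, id_int), 8), MARKER_SYNC)
  grid <- matrix(bits, 8, 8, byrow = TRUE)
  pat <- matrix(0L, MARKER_MODULES, MARKER_MODULES)
  pat[2:11, 2:11] <- 1L            # black ring
  pat[3:10, 3:10] <- grid          # payload replaces ring interior
  pat
}

#' Decode a marker module pattern back to its payload
#'
#' @param pattern numeric 12 x 12 matrix (values near 1 = black).
#' @return The payload string, or `NULL` if the ring, sync bits or checksum
#'   do not validate.
#' @export
decode_marker <- function(pattern) {
  pat <- round(pattern)
  ring <- c(pat[2, 2:11], pat[11, 2:11], pat[3:10, 2], pat[3:10, 11])
  quiet <- c(pat[1, ], pat[12, ], pat[2:11, 1], pat[2:11, 12])
  if (any(ring != 1L) || any(quiet != 0L)) return(NULL)
  bits <- as.integer(t(pat[3:10, 3:10]))
  date_int <- bits_to_int(bits[1:27])
  id_int <- bits_to_int(bits[28:43])
  cs <- bits_to_int(bits[44:51])
  sync <- bits[52:64]
  if (!all(sync == MARKER_SYNC)) return(NULL)
  if (cs != payload_checksum(date_int, id_int)) return(NULL)
  sprintf("%08d-%d", date_int, id_int)
}
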