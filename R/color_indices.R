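#' Names of the 18 color indices, in canonical column order
#' @export
CI_NAMES <- c("R", "G", "B", "H1", "S1", "V1", "H2", "L2", "S2",
              "Lstar", "astar", "bstar", "Y", "Cr", "Cb",
              "NDI", "GI", "RGRI")

#' Grayscale luminance
#'
#' `Gray = 0.299 R + 0.587 G + 0.114 B` on 0-255 channels. This is the same
#' function as the YCbCr luma `Y`; both call this one routine.
#'
#' @param r,g,b numeric vectors of channel values in \[0, 255\].
#' @return numeric vector.
#' @export
ci_gray <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b

#' Excess green index
#'
#' `ExG = 2G - R - B`, in \[-510, 510\] for 8-bit channels.
#' @inheritParams ci_gray
#' @return numeric vector.
#' @export
ci_exg <- function(r, g, b) 2 * g - r - b

# hue in degrees [0, 360) by the four-branch max/min formula; x = y -> 0
hue_deg <- function(r, g, b) {
  x <- pmax(r, g, b); y <- pmin(r, g, b)
  span <- x - y
  h <- numeric(length(x))
  dim(h) <- dim(x)
  eq <- span == 0
  span[eq] <- 1  # avoid 0/0; overwritten below
  hr <- 60 * (g - b) / span
  hr <- ifelse(g >= b, hr, hr + 360)
  hg <- 60 * (b - r) / span + 120
  hb <- 60 * (r - g) / span + 240
  h <- ifelse(x == r, hr, ifelse(x == g, hg, hb))
  h[eq] <- 0
  h
}

#' RGB to HSV (hue in degrees, value on the channel scale)
#'
#' `x = max(R,G,B)`, `y = min(R,G,B)`; `H1` by the four-branch hue formula
#' (0 when x = y), `S1 = (x - y)/x` (0 when x = 0), `V1 = x`.
#'
#' @inheritParams ci_gray
#' @return list with `H1` (degrees), `S1` in \[0, 1\], `V1`.
#' @export
ci_hsv <- function(r, g, b) {
  x <- pmax(r, g, b); y <- pmin(r, g, b)
  list(H1 = hue_deg(r, g, b),
       S1 = ifelse(x == 0, 0, (x - y) / x),
       V1 = x)
}

#' RGB to HLS on \[0, 1\]-scaled channels
#'
#' `H2 = H1`; `L2 = (x + y)/2`; `S2 = (x-y)/(x+y)` for lightness up to 0.5
#' and `(x-y)/(2-(x+y))` above. Inputs are divided by 255 internally.
#'
#' @inheritParams ci_gray
#' @return list with `H2` (degrees), `L2`, `S2` (dimensionless).
#' @export
ci_hls <- function(r, g, b) {
  u <- r / 255; v <- g / 255; w <- b / 255
  x <- pmax(u, v, w); y <- pmin(u, v, w)
  l <- (x + y) / 2
  s <- ifelse(l == 0 | x == y, 0,
              ifelse(l <= 0.5, (x - y) / (x + y), (x - y) / (2 - (x + y))))
  list(H2 = hue_deg(r, g, b), L2 = l, S2 = s)
}

#' RGB to the survey's CIELAB-style coordinates
#'
#' Uses the printed linear transform on \[0, 1\]-scaled channels
#' (`X = 0.607R + 0.174G + 0.200B`, `Y = 0.299R + 0.587G + 0.114B`,
#' `Z = 0.066G + 1.116B`, with no white-point division) and the usual
#' `k = 0.008856` cube-root/linear split. `lab_standard = TRUE` switches to
#' the conventional sRGB D65 transform for comparison.
#'
#' @inheritParams ci_gray
#' @param lab_standard use the standard D65 XYZ transform instead of the
#'   printed one.
#' @return list with `Lstar`, `astar`, `bstar`.
#' @export
ci_lab <- function(r, g, b, lab_standard = FALSE) {
  u <- r / 255; v <- g / 255; w <- b / 255
  k <- 0.008856
  if (lab_standard) {
    X <- (0.4124 * u + 0.3576 * v + 0.1805 * w) / 0.95047
    Y <- 0.2126 * u + 0.7152 * v + 0.0722 * w
    Z <- (0.0193 * u + 0.1192 * v + 0.9505 * w) / 1.08883
  } else {
    X <- 0.607 * u + 0.174 * v + 0.200 * w
    Y <- 0.299 * u + 0.587 * v + 0.114 * w
    Z <- 0.066 * v + 1.116 * w
  }
  f <- function(t) ifelse(t > k, t^(1 / 3), 7.787 * t + 0.1379)
  list(Lstar = ifelse(Y > k, 116 * Y^(1 / 3) - 16, 903.3 * Y),
       astar = 500 * (f(X) - f(Y)),
       bstar = 200 * (f(Y) - f(Z)))
}

#' RGB to YCbCr (0-255 channels)
#'
#' `Y` is the grayscale luminance ([ci_gray()]); `Cr = (R - Y) 0.713 + 128`,
#' `Cb = (B - Y) 0.564 + 128`, both clipped to \[0, 255\].
#'
#' @inheritParams ci_gray
#' @return list with `Y`, `Cr`, `Cb`.
#' @export
ci_ycbcr <- function(r, g, b) {
  y <- ci_gray(r, g, b)
  list(Y = y,
       Cr = clip255((r - y) * 0.713 + 128),
       Cb = clip255((b - y) * 0.564 + 128))
}

#' Red/green ratio indices
#'
#' `NDI = (G - R)/(G + R)`, `GI = G/R`, `RGRI = R/G`. Pixels with an
#' undefined denominator yield `NaN` and are excluded (and counted) when
#' averaging in [sample_ci_vector()].
#'
#' @param r,g numeric vectors of the red and green channels.
#' @return list with `NDI`, `GI`, `RGRI` (with `NaN` where undefined).
#' @export
ci_ratios <- function(r, g) {
  list(NDI = ifelse(g + r == 0, NaN, (g - r) / (g + r)),
       GI = ifelse(r == 0, NaN, g / r),
       RGRI = ifelse(g == 0, NaN, r / g))
}

#' Compute all 18 color indices per pixel
#'
#' @param r,g,b numeric vectors of channel values in \[0, 255\] (HLS and
#'   Lab scale internally).
#' @param lab_standard passed to [ci_lab()].
#' @return numeric matrix, one row per pixel, columns [CI_NAMES].
#' @export
pixel_indices <- function(r, g, b, lab_standard = FALSE) {
  hsv <- ci_hsv(r, g, b)
  hls <- ci_hls(r, g, b)
  lab <- ci_lab(r, g, b, lab_standard)
  ycc <- ci_ycbcr(r, g, b)
  rat <- ci_ratios(r, g)
  out <- cbind(R = as.numeric(r), G = as.numeric(g), B = as.numeric(b),
               H1 = as.numeric(hsv$H1), S1 = as.numeric(hsv$S1),
               V1 = as.numeric(hsv$V1),
               H2 = as.numeric(hls$H2), L2 = as.numeric(hls$L2),
               S2 = as.numeric(hls$S2),
               Lstar = as.numeric(lab$Lstar), astar = as.numeric(lab$astar),
               bstar = as.numeric(lab$bstar),
               Y = as.numeric(ycc$Y), Cr = as.numeric(ycc$Cr),
               Cb = as.numeric(ycc$Cb),
               NDI = as.numeric(rat$NDI), GI = as.numeric(rat$GI),
               RGRI = as.numeric(rat$RGRI))
  out
}

#' Aggregate the 18 color indices over the retained grain pixels
#'
#' Each index is computed per pixel over `grain_mask & halation-retained`
#' pixels and arithmetically averaged (hue in plain degrees; grain hues sit
#' far from the 0/360 wrap). Ratio indices exclude their undefined pixels
#' per index; the exclusion counts are attached.
#'
#' @param roi an `roi_raster`, `corrected_image`, or H x W x 3 array.
#' @param grain_mask logical matrix or `grain_mask` object (TRUE = grain).
#' @param halation optional logical matrix (TRUE = retained).
#' @param lab_standard passed to [ci_lab()].
#' @return Named numeric vector over [CI_NAMES] with attributes `n_pixels`
#'   and `n_excluded` (per ratio index).
#' @export
sample_ci_vector <- function(roi, grain_mask = NULL, halation = NULL,
                             lab_standard = FALSE) {
  px <- if (is.list(roi)) roi$pixels else roi
  keep <- matrix(TRUE, dim(px)[1], dim(px)[2])
  if (!is.null(grain_mask)) {
    gm <- if (is.list(grain_mask)) grain_mask$retained else grain_mask
    keep <- keep & gm
  }
  if (!is.null(halation)) {
    hm <- if (is.list(halation)) halation$retained else halation
    keep <- keep & hm
  }
  if (!any(keep)) stop("invalid sample: zero retained pixels")
  r <- px[, , 1][keep]; g <- px[, , 2][keep]; b <- px[, , 3][keep]
  m <- pixel_indices(r, g, b, lab_standard)
  out <- colMeans(m, na.rm = TRUE)
  excl <- colSums(is.na(m[, c("NDI", "GI", "RGRI"), drop = FALSE]))
  attr(out, "n_pixels") <- length(r)
  attr(out, "n_excluded") <- excl
  out
}
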