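#' Wet-basis grain moisture content from wet and dry weights
#'
#' `GMC = 100 (Wwet - Wdry) / Wwet` percent.
#'
#' @param w_wet wet weight, grams (> 0).
#' @param w_dry dry weight, grams (0 <= w_dry <= w_wet).
#' @return GMC percent (vectorized).
#' @export
wet_basis_gmc <- function(w_wet, w_dry) {
  if (any(w_wet <= 0)) stop("invalid sample: w_wet must be positive")
  if (any(w_dry < 0 | w_dry > w_wet))
    stop("invalid sample: need 0 <= w_dry <= w_wet")
  100 * (w_wet - w_dry) / w_wet
}

#' Filter samples to the valid GMC range
#'
#' Keeps samples with GMC in the closed interval \[13, 60\] percent (the
#' physiologically valid range for rice grain); the exclusion count is
#' attached as an attribute.
#'
#' @param samples data frame with a `gmc_wb` column, or a numeric vector.
#' @param range closed validity interval, percent.
#' @return filtered input with attribute `n_excluded`.
#' @export
filter_valid <- function(samples, range = c(13, 60)) {
  g <- if (is.data.frame(samples)) samples$gmc_wb else samples
  keep <- g >= range[1] & g <= range[2]
  out <- if (is.data.frame(samples)) samples[keep, , drop = FALSE]
         else samples[keep]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

# Truncated shifted log-normal parameters, moment-matched by numerical
# integration to the field moments: panicle mode mean 29.32, sd 6.98,
# skewness 1.81 on [13.86, 57.43]; area mode mean 27.15, sd 4.29,
# skewness 0.57 on [20.06, 37.67].
GMC_POP <- list(
  panicle = list(theta = 23.264089, mu = 1.316167, sigma = 1.479916,
                 lo = 13.86, hi = 57.43),
  area = list(theta = 19.440523, mu = 2.094058, sigma = 0.809886,
              lo = 20.06, hi = 37.67))

#' Draw a GMC population
#'
#' Shifted log-normal draws truncated (by rejection) to the mode's support.
#' `panicle` mode emulates the right-tailed single-panicle distribution;
#' `area` mode the milder one-square-meter area means.
#'
#' @param n number of draws.
#' @param mode `"panicle"` or `"area"`.
#' @param seed integer seed (reproducible).
#' @return numeric GMC percent values.
#' @export
sample_gmc_population <- function(n, mode = c("panicle", "area"), seed = 1) {
  mode <- match.arg(mode)
  p <- GMC_POP[[mode]]
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    x <- p$theta + rlnorm(max(2L * n, 100L), p$mu, p$sigma)
    out <- c(out, x[x >= p$lo & x <= p$hi])
  }
  out[seq_len(n)]
}

#' Map GMC to a grain (spikelet) color
#'
#' Hue tracks moisture linearly, `H = 35 + 30 (GMC - 14) / 46` degrees
#' clipped to \[35, 65\] (wet grain is greener, dry grain yellower-red),
#' with Gaussian hue jitter per spikelet. Chroma and the minimum channel
#' are drawn from fixed grain-plausible ranges that keep `Gray <= 145` and
#' `ExG <= 100` and channel sigma comfortably above the halation cut.
#'
#' @param gmc GMC percent in \[13, 60\].
#' @param jitter_sd hue jitter standard deviation, degrees (per spikelet).
#' @param n number of spikelet colors to draw.
#' @param hue_clip clip range for the jittered hue, degrees.
#' @return data.frame with columns `h` (degrees), `c` (chroma, 0-255),
#'   `y` (minimum channel, 0-255) and the implied `r`, `g`, `b`.
#' @export
gmc_to_grain_color <- function(gmc, jitter_sd = 1.5, n = 1,
                               hue_clip = c(35, 65)) {
  h0 <- 35 + 30 * (gmc - 14) / 46
  h0 <- pmin(pmax(h0, 35), 65)
  h <- pmin(pmax(h0 + rnorm(n, 0, jitter_sd), hue_clip[1]), hue_clip[2])
  # chroma >= 85 keeps per-pixel channel sigma (~0.41 c) above the
  # halation cut after calibration; the upper bounds keep ExG <= 100 and
  # Gray <= 145 with margin against the cascade cuts
  cc <- runif(n, 85, 105)
  y <- runif(n, 25, 40)
  rgb <- hue_chroma_rgb(h, cc, y)
  data.frame(h = h, c = cc, y = y, r = rgb$r, g = rgb$g, b = rgb$b)
}

# hue (degrees, in [0,120]) + chroma + min-channel -> RGB
hue_chroma_rgb <- function(h, cc, y) {
  x <- y + cc
  r <- ifelse(h < 60, x, y + (120 - h) / 60 * cc)
  g <- ifelse(h < 60, y + h / 60 * cc, x)
  list(r = r, g = g, b = y)
}

# patch values the boards are printed with
PATCH_WHITE <- 245
PATCH_BLACK <- 18

# the canonical form every calibrated image is brought to: black patch to 0,
# white to 255, then the gamma that sends the gray card to 119
canonical_correction <- function(v) {
  stretched <- 255 * (pmax(v - PATCH_BLACK, 0) / (PATCH_WHITE - PATCH_BLACK))
  g0 <- log(119 / 255) /
    log((119 - PATCH_BLACK) / (PATCH_WHITE - PATCH_BLACK))
  pmin(255 * (stretched / 255)^g0, 255)
}

## ---- board scenes -------------------------------------------------------

#' Describe a synthetic single-panicle board scene
#'
#' Geometry is in board millimeters on a [board_layout()]. The scene
#' carries its own ground truth: true GMC, patch RGB values, marker
#' payloads, per-class regions, and the lighting distortion applied at
#' render time (gain and offset after a gamma warp, in sensor-linear
#' floating point, so a later calibration can invert it).
#'
#' @param sample_id integer sample code (encoded in the marker payloads).
#' @param gmc true GMC percent (drawn from the panicle population when
#'   missing).
#' @param capture_date `Date` for the marker payloads.
#' @param seed integer seed for colors and placement.
#' @param distortion `c(gain, offset, gamma)` lighting distortion.
#' @param rotation_deg board rotation in the image, degrees (<= 10).
#' @param px_per_mm rendering scale.
#' @param layout a [board_layout()].
#' @param n_spikelets number of grain ellipses.
#' @param hue_jitter_sd per-spikelet hue jitter, degrees.
#' @param grain_hue_clip hue clip range for grain, degrees; the default
#'   \[38.5, 57\] keeps at least three noise standard deviations inside
#'   the cascade cuts (35 and 60).
#' @return A `panicle_scene` list.
#' @export
panicle_scene <- function(sample_id = 1L, gmc = NULL,
                          capture_date = as.Date("2019-10-14"), seed = 1,
                          distortion = c(gain = 1, offset = 0, gamma = 1),
                          rotation_deg = 0, px_per_mm = 2,
                          layout = board_layout(), n_spikelets = 40,
                          hue_jitter_sd = 1.5,
                          grain_hue_clip = c(38.5, 57)) {
  set.seed(seed)
  if (is.null(gmc)) gmc <- sample_gmc_population(1, "panicle", seed)
  payload <- sprintf("%s-%d", format(capture_date, "%Y%m%d"), sample_id)
  # panicle axis across the grain zone, with a gentle bow
  roi <- layout$roi
  x0 <- roi[1] + 15; x1 <- roi[1] + roi[3] - 24
  ymid <- roi[2] + roi[4] / 2
  tpar <- seq(0, 1, length.out = n_spikelets)
  axis_x <- x0 + tpar * (x1 - x0)
  axis_y <- ymid - 6 + 8 * sin(pi * tpar) + rnorm(n_spikelets, 0, 1.2)
  cols <- gmc_to_grain_color(gmc, hue_jitter_sd, n_spikelets,
                             hue_clip = grain_hue_clip)
  grains <- data.frame(
    cx = axis_x + rnorm(n_spikelets, 0, 1.5),
    cy = axis_y + runif(n_spikelets, -5, 5),
    a = runif(n_spikelets, 3.6, 5.2), b = runif(n_spikelets, 1.8, 2.6),
    ang = atan2(rep(diff(range(axis_y)), n_spikelets),
                rep(x1 - x0, n_spikelets)) + rnorm(n_spikelets, 0, 0.5),
    r = cols$r, g = cols$g, b_ch = cols$b)
  # class hues sit >= 3 noise-sd from every cascade cut (35, 60) so the
  # documented >= 99% recall / rejection margins hold under pixel noise
  # and the gamma warp
  stem_cols <- hue_chroma_rgb(runif(1, 26, 30.5), runif(1, 85, 100),
                              runif(1, 20, 35))
  structure(list(
    sample_id = sample_id, gmc = gmc, payload = payload,
    capture_date = capture_date, layout = layout,
    px_per_mm = px_per_mm, rotation_deg = rotation_deg,
    distortion = distortion, seed = seed,
    patch_rgb = list(white = c(245, 245, 245), black = c(18, 18, 18),
                     gray = c(119, 119, 119)),
    grains = grains,
    stem = list(from = c(x0 - 6, ymid + 9), to = c(x1 + 6, ymid + 4),
                width = 2, rgb = c(stem_cols$r, stem_cols$g, stem_cols$b)),
    band = list(rect = c(x0 - 12, ymid - 7, x0 - 4, ymid + 7),
                rgb = c(60, 200, 40)),
    card = list(rect = c(x1 + 8, roi[2] + 3, x1 + 26, roi[2] + 13),
                rgb = c(110, 150, 55)),
    shadow = list(center = c((x0 + x1) / 2, ymid + 14), axes = c(55, 4.5),
                  rgb = c(230, 185, 130)),
    board_rgb = c(28, 28, 32), noise_sd = 1.2),
    class = "panicle_scene")
}

#' Render a scene to a raster with ground-truth masks
#'
#' Paints the board, calibration patches, corner markers and the panicle
#' props in board coordinates, applies per-pixel Gaussian color noise, then
#' the scene's lighting distortion (gamma warp followed by gain and offset,
#' unclipped sensor-linear floats). Returns the image together with
#' per-class ground-truth masks so calibration recovery and segmentation
#' accuracy are computable with no external data.
#'
#' @param scene a [panicle_scene()].
#' @return list: `image` ([raw_image()], headroom allowed), `masks` (named
#'   logical matrices: grain, stem, band, card, shadow, board), `truth`
#'   (gmc, patch RGB, payloads, distortion).
#' @export
render_scene <- function(scene) {
  set.seed(scene$seed + 7L)
  lay <- scene$layout
  s <- scene$px_per_mm
  th <- scene$rotation_deg * pi / 180
  bw <- lay$board_mm[1]; bh <- lay$board_mm[2]
  corners <- rbind(c(0, 0), c(bw, 0), c(0, bh), c(bw, bh))
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pc <- corners %*% t(rot) * s
  margin <- 8
  tx <- margin - min(pc[, 1]); ty <- margin - min(pc[, 2])
  tr <- make_transform(s, scene$rotation_deg, c(tx, ty))
  W <- ceiling(max(pc[, 1]) + tx + margin)
  H <- ceiling(max(pc[, 2]) + ty + margin)
  # mm coordinates of every pixel center
  cr <- cbind(rep(seq_len(W), each = H), rep(seq_len(H), times = W))
  mm <- px_to_mm(tr, cr)
  X <- matrix(mm[, 1], H, W); Ym <- matrix(mm[, 2], H, W)
  img <- array(12, c(H, W, 3))  # dark backdrop outside the board
  paint <- function(mask, rgb) {
    for (ch in 1:3) {
      pl <- img[, , ch]; pl[mask] <- rgb[ch]; img[, , ch] <<- pl
    }
  }
  on_board <- X >= 0 & X <= bw & Ym >= 0 & Ym <= bh
  paint(on_board, scene$board_rgb)
  rect_mask <- function(rect)
    X >= rect[1] & X <= rect[3] & Ym >= rect[2] & Ym <= rect[4]
  for (nm in names(lay$patches))
    paint(rect_mask(lay$patches[[nm]]), scene$patch_rgb[[nm]])
  # corner markers: white backing then black modules
  mmod <- lay$marker_module_mm
  half <- mmod * MARKER_MODULES / 2
  pat <- encode_marker(scene$payload)
  for (k in 1:4) {
    cen <- lay$marker_centers[k, ]
    back <- X >= cen[1] - half & X <= cen[1] + half &
            Ym >= cen[2] - half & Ym <= cen[2] + half
    paint(back, c(240, 240, 240))
    i_mod <- floor((Ym - (cen[2] - half)) / mmod) + 1
    j_mod <- floor((X - (cen[1] - half)) / mmod) + 1
    inside <- back & i_mod >= 1 & i_mod <= MARKER_MODULES &
              j_mod >= 1 & j_mod <= MARKER_MODULES
    dark <- inside
    dark[inside] <- pat[cbind(i_mod[inside], j_mod[inside])] == 1L
    paint(dark, c(15, 15, 15))
  }
  # props, bottom-to-top: shadow, card, band, stem, grain
  masks <- list()
  ell <- scene$shadow
  dx <- X - ell$center[1]; dy <- Ym - ell$center[2]
  masks$shadow <- (dx / ell$axes[1])^2 + (dy / ell$axes[2])^2 <= 1
  paint(masks$shadow, ell$rgb)
  masks$card <- rect_mask(scene$card$rect)
  paint(masks$card, scene$card$rgb)
  masks$band <- rect_mask(scene$band$rect)
  paint(masks$band, scene$band$rgb)
  st <- scene$stem
  u <- st$to - st$from; len <- sqrt(sum(u^2)); u <- u / len
  px_ <- X - st$from[1]; py_ <- Ym - st$from[2]
  along <- px_ * u[1] + py_ * u[2]
  perp <- abs(-px_ * u[2] + py_ * u[1])
  masks$stem <- along >= 0 & along <= len & perp <= st$width / 2
  paint(masks$stem, st$rgb)
  masks$grain <- matrix(FALSE, H, W)
  for (q in seq_len(nrow(scene$grains))) {
    gr <- scene$grains[q, ]
    ca <- cos(gr$ang); sa <- sin(gr$ang)
    dx <- X - gr$cx; dy <- Ym - gr$cy
    du <- dx * ca + dy * sa; dv <- -dx * sa + dy * ca
    em <- (du / gr$a)^2 + (dv / gr$b)^2 <= 1
    masks$grain <- masks$grain | em
    paint(em, c(gr$r, gr$g, gr$b_ch))
  }
  # occlusion order: grain on top of everything
  masks$stem <- masks$stem & !masks$grain
  masks$band <- masks$band & !masks$grain & !masks$stem
  masks$card <- masks$card & !masks$grain & !masks$stem & !masks$band
  masks$shadow <- masks$shadow & !masks$grain & !masks$stem &
                  !masks$band & !masks$card
  masks$board <- on_board & !Reduce(`|`, masks)
  # pixel noise, then the lighting distortion (unclipped sensor floats)
  img <- img + array(rnorm(length(img), 0, scene$noise_sd), dim(img))
  img <- pmax(img, 0)
  a <- scene$distortion[1]; b0 <- scene$distortion[2]
  g0 <- scene$distortion[3]
  img <- a * 255 * (img / 255)^g0 + b0
  list(image = raw_image(img, sample_id = as.character(scene$sample_id),
                         capture_date = scene$capture_date,
                         allow_headroom = TRUE),
       masks = masks,
       truth = list(gmc = scene$gmc, patch_rgb = scene$patch_rgb,
                    payload = scene$payload,
                    distortion = scene$distortion))
}

#' Simulate a per-sample color-index feature table
#'
#' Draws GMC values from the panicle population, renders each sample's
#' spikelet colors (hue tracking GMC with per-spikelet jitter, plus
#' per-pixel channel noise), and averages the 18 color indices over the
#' grain pixels — the feature-extraction output of the image pipeline
#' without the rendering and segmentation stages, which are exercised
#' separately.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param hue_jitter_sd per-spikelet hue jitter, degrees.
#' @param n_spikelets spikelets per panicle.
#' @param px_per_spikelet grain pixels per spikelet.
#' @param rgb_noise_sd per-pixel channel noise.
#' @param calibrated map pixel colors through the canonical calibration
#'   (black patch to 0, white to 255, gray card to 119) so the features
#'   live in the same space the image pipeline emits; `FALSE` keeps raw
#'   board colors, where the hue-GMC map is exactly linear.
#' @return data.frame: `sample_id`, `n_pixels`, the 18 [CI_NAMES] columns,
#'   `gmc_wb`.
#' @export
simulate_ci_dataset <- function(n = 500, seed = 1, hue_jitter_sd = 1.5,
                                n_spikelets = 40, px_per_spikelet = 30,
                                rgb_noise_sd = 2, calibrated = TRUE) {
  gmc <- sample_gmc_population(n, "panicle", seed)
  set.seed(seed + 1L)
  rows <- vector("list", n)
  # per-sample residual brightness (chroma and pedestal) variation:
  # field photographs of different panicles retain sample-level lighting
  # differences after calibration, which is what spreads the feature
  # correlation structure over a brightness axis and a hue axis
  c_base <- runif(n, 88, 102)
  y_base <- runif(n, 28, 37)
  for (k in seq_len(n)) {
    cols <- gmc_to_grain_color(gmc[k], hue_jitter_sd, n_spikelets)
    cols_c <- pmin(pmax(c_base[k] + runif(n_spikelets, -8, 8), 85), 105)
    cols_y <- pmin(pmax(y_base[k] + runif(n_spikelets, -5, 5), 25), 40)
    rgb <- hue_chroma_rgb(cols$h, cols_c, cols_y)
    cols$r <- rgb$r; cols$g <- rgb$g; cols$b <- rgb$b
    r <- rep(cols$r, each = px_per_spikelet) +
      rnorm(n_spikelets * px_per_spikelet, 0, rgb_noise_sd)
    g <- rep(cols$g, each = px_per_spikelet) +
      rnorm(n_spikelets * px_per_spikelet, 0, rgb_noise_sd)
    b <- rep(cols$b, each = px_per_spikelet) +
      rnorm(n_spikelets * px_per_spikelet, 0, rgb_noise_sd)
    if (calibrated) {
      r <- canonical_correction(r); g <- canonical_correction(g)
      b <- canonical_correction(b)
    }
    ci <- colMeans(pixel_indices(clip255(r), clip255(g), clip255(b)),
                   na.rm = TRUE)
    rows[[k]] <- c(n_pixels = length(r), ci, gmc_wb = gmc[k])
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(sample_id = sprintf("S%04d", seq_len(n)), out)
}

#' Simulate a multiday area-mean GMC series
#'
#' `mean_gmc(d) = a2 ln(start_gd + d) + b2 + N(0, noise_sd)`, clipped to
#' (0, 1); dates advance daily from `start_date`.
#'
#' @param days number of daily entries (>= 2).
#' @param start_gd growth day of the first entry.
#' @param coeffs `c(a2, b2)`; printed defaults (-0.514, 2.58).
#' @param noise_sd Gaussian noise on the fraction scale.
#' @param seed integer seed.
#' @param start_date first calendar date.
#' @return A [multiday_series()].
#' @export
simulate_multiday <- function(days = 17, start_gd = 79,
                              coeffs = c(-0.514, 2.58), noise_sd = 0,
                              seed = 1,
                              start_date = as.Date("2019-10-07")) {
  if (days < 2) stop("need days >= 2")
  set.seed(seed)
  d <- seq_len(days) - 1
  g <- coeffs[1] * log(start_gd + d) + coeffs[2] + rnorm(days, 0, noise_sd)
  g <- pmin(pmax(g, 1e-6), 1 - 1e-6)
  if (any(coeffs[1] * log(start_gd + d) + coeffs[2] <= 0))
    stop("invalid parameters: non-positive GMC on the deterministic curve")
  multiday_series(date = start_date + d, growth_day = start_gd + d,
                  mean_gmc = g)
}

#' Build a GMC sample table from weights
#'
#' @param sample_id identifiers.
#' @param w_wet,w_dry weights in grams.
#' @param survey_date optional dates.
#' @return data.frame with the wet-basis GMC attached.
#' @export
gmc_samples <- function(sample_id, w_wet, w_dry, survey_date = NULL) {
  out <- data.frame(sample_id = as.character(sample_id),
                    w_wet = w_wet, w_dry = w_dry,
                    gmc_wb = wet_basis_gmc(w_wet, w_dry))
  if (!is.null(survey_date)) out$survey_date <- as.Date(survey_date)
  out
}
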