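# shared fixtures: random pixel batches, an independent HLS reference, and
# small rendered board scenes

# n random 8-bit-range pixels (continuous), plus the awkward corners
rand_pixels <- function(n, seed = 1) {
  set.seed(seed)
  r <- c(runif(n, 0, 255), 0, 255, 0, 255, 128, 119)
  g <- c(runif(n, 0, 255), 0, 255, 255, 0, 128, 119)
  b <- c(runif(n, 0, 255), 0, 0, 255, 255, 128, 119)
  list(r = r, g = g, b = b)
}

# independent HLS saturation: S = C / (1 - |2L - 1|) on [0,1] channels,
# algebraically distinct from the package's two-branch form
hls_reference <- function(r, g, b) {
  u <- r / 255; v <- g / 255; w <- b / 255
  x <- pmax(u, v, w); y <- pmin(u, v, w)
  L <- (x + y) / 2
  denom <- 1 - abs(2 * L - 1)
  S <- ifelse(x == y | denom == 0, 0, (x - y) / denom)
  list(L = L, S = S)
}

# a small rendered scene with its calibrated + segmented products
scene_products <- function(seed, gmc, rotation_deg = 0,
                           distortion = c(1, 0, 1), ...) {
  sc <- panicle_scene(sample_id = seed, gmc = gmc, seed = seed,
                      rotation_deg = rotation_deg,
                      distortion = distortion, ...)
  rend <- render_scene(sc)
  cal <- calibrate_image(rend$image)
  roi <- crop_roi(cal$corrected, cal$anchors)
  hal <- crop_apply(roi, cal$halation$retained)
  gm <- remove_background(roi, halation = hal)
  list(scene = sc, rend = rend, cal = cal, roi = roi, hal = hal, gm = gm)
}
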