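test_that("patch means are per-channel arithmetic means with bounds checks", {
  px <- array(0, c(4, 4, 3))
  px[1:2, 1:2, ] <- 250
  px[3:4, 1:2, 1] <- c(200, 100, 200, 100)  # red column pairs
  img <- raw_image(px)
  reg <- list(white = as.matrix(expand.grid(1:2, 1:2)),
              black = as.matrix(expand.grid(3:4, 3:4)),
              gray = rbind(c(3, 1), c(4, 1)))
  p <- measure_patches(img, reg)
  expect_equal(p$white_mean, c(250, 250, 250))
  expect_equal(p$gray_mean, c(150, 0, 0))  # mean of 200 and 100 red
  # 3x3 gray with one zero outlier among eight 119s
  px2 <- array(119, c(3, 3, 3)); px2[2, 2, ] <- 0
  p2 <- measure_patches(raw_image(px2),
                        list(white = rbind(c(1, 1)), black = rbind(c(1, 2)),
                             gray = as.matrix(expand.grid(1:3, 1:3))))
  expect_equal(p2$gray_mean, rep(8 * 119 / 9, 3), tolerance = 1e-12)
  expect_equal(p2$gray_mean[1], 105.78, tolerance = 1e-4)
  expect_error(measure_patches(img, modifyList(reg, list(gray = rbind(c(9, 1))))),
               "out")
  expect_error(measure_patches(img, modifyList(reg, list(gray = reg$gray[0, ]))),
               "empty")
})

test_that("contrast stretch is affine, maps black to 0 and white to 255", {
  patches <- structure(list(white_mean = rep(245, 3), black_mean = rep(10, 3),
                            regions = NULL), class = "calibration_patches")
  px <- array(rep(c(10, 245, 128), each = 1), c(1, 3, 3))
  for (ch in 2:3) px[, , ch] <- px[, , 1]
  out <- contrast_correct(px, patches)
  expect_equal(out$pixels[1, 1, 1], 0)
  expect_equal(out$pixels[1, 2, 1], 255)
  expect_equal(out$pixels[1, 3, 1], 255 * 118 / 235, tolerance = 1e-12)
  expect_equal(out$pixels[1, 3, 1], 128.04, tolerance = 1e-2)
  # affine per channel: equal spacing preserved up to a scale
  bad <- patches; bad$black_mean <- rep(250, 3)
  expect_error(contrast_correct(px, bad), "calibration failure")
})

test_that("gamma solve hits the gray target and inverts brightness errors", {
  expect_equal(solve_gamma(119), 1.0)
  # brute-force check: solve (Ig/255)^g = 119/255 by bisection
  brute <- function(ig) {
    f <- function(g) 255 * (ig / 255)^g - 119
    uniroot(f, c(0.01, 20), tol = 1e-12)$root
  }
  expect_equal(solve_gamma(150), brute(150), tolerance = 1e-9)
  expect_equal(solve_gamma(150), 1.4363, tolerance = 1e-4)
  expect_equal(solve_gamma(80), brute(80), tolerance = 1e-9)
  expect_equal(solve_gamma(80), 0.6575, tolerance = 1e-4)
  expect_lt(solve_gamma(80), 1)  # darker-than-target patch brightens
  expect_error(solve_gamma(0), "degenerate")
  expect_error(solve_gamma(255), "degenerate")
})

test_that("gamma correction is monotone with 0 and 255 fixed", {
  px <- array(c(0, 128, 255), c(1, 3, 3))
  for (ch in 2:3) px[, , ch] <- px[, , 1]
  id <- gamma_correct(px, 1)
  expect_equal(id$pixels, px)
  sq <- gamma_correct(px, 2)
  expect_equal(sq$pixels[1, 1, 1], 0)
  expect_equal(sq$pixels[1, 3, 1], 255)
  expect_equal(sq$pixels[1, 2, 1], 255 * (128 / 255)^2, tolerance = 1e-12)
  expect_equal(sq$pixels[1, 2, 1], 64.25, tolerance = 1e-2)
  expect_error(gamma_correct(px, 0), "invalid")
  v <- seq(0, 255, by = 5)
  for (g in c(0.5, 1.7)) {
    out <- gamma_correct(array(v, c(1, length(v), 3)), g)$pixels[1, , 1]
    expect_true(all(diff(out) > 0))
  }
})

test_that("halation sigma matches a brute-force population sd", {
  expect_equal(halation_sigma(255, 255, 255), 0)
  expect_equal(halation_sigma(100, 150, 200), sqrt(5000 / 3),
               tolerance = 1e-12)
  expect_equal(halation_sigma(120, 130, 140), sqrt(200 / 3),
               tolerance = 1e-12)
  p <- rand_pixels(1e4, seed = 3)
  brute <- vapply(seq_along(p$r), function(i) {
    v <- c(p$r[i], p$g[i], p$b[i])
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  expect_equal(halation_sigma(p$r, p$g, p$b), brute, tolerance = 1e-9)
})

test_that("halation mask retains exactly the high-sigma pixels", {
  gray_img <- array(100, c(2, 2, 3))
  expect_equal(sum(halation_mask(gray_img)$retained), 0)
  chrom <- array(rep(c(100, 150, 200), each = 4), c(2, 2, 3))
  expect_true(all(halation_mask(chrom)$retained))       # sigma 40.8 >= 35
  expect_true(all(halation_mask(gray_img, threshold = 0)$retained))
})

test_that("full calibration restores a distorted board to its canonical form", {
  # gray patch back to 119 +- 1 and grain pixels within 3 units RMS of the
  # clean-corrected reference, over seeded random gain/offset/gamma
  set.seed(421)
  for (k in 1:6) {
    dist <- c(runif(1, 0.7, 1.3), runif(1, -30, 30), runif(1, 0.7, 1.4))
    clean <- scene_products(30 + k, gmc = runif(1, 18, 45))
    distorted <- clean$scene
    distorted$distortion <- dist
    rd <- render_scene(distorted)
    cald <- calibrate_image(rd$image)
    idx <- as.matrix(cald$patches$regions$gray)
    gray_val <- mean((cald$corrected$pixels[cbind(idx, 1)] +
                      cald$corrected$pixels[cbind(idx, 2)] +
                      cald$corrected$pixels[cbind(idx, 3)]) / 3)
    expect_lt(abs(gray_val - 119), 1)
    gm <- clean$rend$masks$grain
    dif <- vapply(1:3, function(ch)
      sqrt(mean((cald$corrected$pixels[, , ch][gm] -
                 clean$cal$corrected$pixels[, , ch][gm])^2)), numeric(1))
    expect_lt(sqrt(mean(dif^2)), 3)
  }
})
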