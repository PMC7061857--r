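test_that("pixel-to-absorbance follows the log ratio with the dark-pixel clip", {
  expect_identical(pixel_to_absorbance(255), 0)
  expect_equal(pixel_to_absorbance(26), log10(255 / 26), tolerance = 1e-12)
  expect_equal(pixel_to_absorbance(0), log10(255), tolerance = 1e-12)
  expect_error(pixel_to_absorbance(-1), "0, 255")
  expect_error(pixel_to_absorbance(256), "0, 255")
  a <- pixel_to_absorbance(1:255)
  expect_true(all(diff(a) < 0))
})

test_that("absorbance rendering and pixel recovery invert each other", {
  A <- seq(0, 1.2, by = 0.05)
  pv <- absorbance_to_pixel(A)
  back <- pixel_to_absorbance(pv)
  ## error bounded by half a grey level at the local pixel value
  expect_true(all(abs(back - A) <= log10(pv + 0.5) - log10(pv - 0.5)))
})

test_that("spectrum hue: flat transmittance is achromatic, band hues land in the purple/yellow ranges", {
  wl <- seq(380, 780, 1)
  flat <- spectrum_to_hue(absorbance_spectrum(wl, rep(0, length(wl))))
  expect_true(flat$achromatic)
  expect_lt(flat$saturation, 0.01)

  band <- function(c0) make_spectrum(list(c(c0, 30, 1.0)), grid = wl)
  h550 <- spectrum_to_hue(band(550))
  expect_false(h550$achromatic)
  expect_gt(h550$hue, 280); expect_lt(h550$hue, 340)
  h440 <- spectrum_to_hue(band(440))
  expect_gt(h440$hue, 40); expect_lt(h440$hue, 100)

  expect_error(spectrum_to_hue(absorbance_spectrum(400:700, rep(0, 301))),
               "380-780")
})

test_that("hue is invariant to uniform transmittance rescaling", {
  wl <- seq(380, 780, 1)
  s1 <- make_spectrum(list(c(550, 30, 1.0)), grid = wl)
  ## multiplying T by c in (0,1] adds a flat absorbance offset
  for (offset in c(0.2, 0.5, 1.0)) {
    s2 <- absorbance_spectrum(wl, s1$absorbance + offset)
    h1 <- spectrum_to_hue(s1); h2 <- spectrum_to_hue(s2)
    expect_lt(abs(h1$hue - h2$hue), 2)
    expect_lt(h2$value, h1$value)
  }
})

test_that("region hue handles pure colours, circularity and grey points", {
  img <- array(0L, c(20, 20, 3))
  img[, , 1] <- 255L; img[, , 3] <- 255L # magenta
  rh <- region_hue(img, data.frame(x = 10, y = 10))
  expect_equal(rh$points$hue, 300)
  cm <- circular_mean_hue(c(10, 350))
  expect_lt(min(abs(c(cm, cm - 360))), 1e-9) # 0 and 360 are the same angle
  grey <- array(128L, c(20, 20, 3))
  rg <- region_hue(grey, data.frame(x = 10, y = 10))
  expect_true(rg$achromatic)
})

test_that("stain vectors are unit length with non-negative components", {
  for (h in c(0, 60, 310, 330)) {
    v <- stain_vector(h)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
  }
})

test_that("colour deconvolution recovers a known two-stain mixture", {
  set.seed(5)
  p <- stain_vector(310)
  q0 <- stain_vector(60)
  ## make the second stain exactly orthogonal to the primary in OD space so
  ## the data-driven complement matches the encoding
  q <- q0 - sum(q0 * p) * p
  q <- q / sqrt(sum(q^2))
  h <- 40; w <- 40
  d1 <- matrix(runif(h * w, 0, 0.8), h)
  d2 <- matrix(runif(h * w, 0, 0.5), h)
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- round(255 * 10^(-(d1 * p[ch] + d2 * q[ch])))
  dec <- color_deconvolve(img, p)
  expect_equal(sum(dec$complementary_vector * p), 0, tolerance = 1e-6)
  keep <- d1 > 0.1 & d2 > 0.1
  expect_lt(median(abs(dec$primary_density - d1)[keep] / d1[keep]), 0.02)
  expect_lt(median(abs(dec$complementary_density - d2)[keep] / d2[keep]), 0.02)

  ## remixing the densities reconstructs the OD image
  od <- log10(255 / pmax(img, 1))
  M <- cbind(p, dec$complementary_vector)
  rec <- array(0, dim(od))
  for (ch in 1:3)
    rec[, , ch] <- dec$primary_density * M[ch, 1] + dec$complementary_density * M[ch, 2]
  expect_lt(sqrt(mean((rec - od)^2)) / sqrt(mean(od^2)), 0.01)
})

test_that("single-stain images yield near-zero complementary density, collinear primaries diagnose", {
  set.seed(6)
  p <- stain_vector(310)
  h <- 30; w <- 30
  d1 <- matrix(runif(h * w, 0.2, 0.9), h)
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- round(255 * 10^(-d1 * p[ch]))
  expect_warning(dec <- color_deconvolve(img, p), "collinear")
  expect_lt(max(abs(dec$complementary_density)), 0.05)
  expect_error(color_deconvolve(img, p, fallback = FALSE), "collinear")
})
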