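# normalization, fusion, CNR, kernel search, dose-kernel fitting

roi_at <- function(cx, cy, r) data.frame(name = "roi", cx_mm = cx,
                                         cy_mm = cy, r_mm = r,
                                         tissue = NA)

test_that("pair normalization pins the ROI means to 0 and 1", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64, 5, 0.1), 64, 64)
  lo <- roi_at(-10, 0, 5); hi <- roi_at(10, 0, 5)
  n <- 64; px <- 1
  img[roi_mask(hi, n, px)] <- img[roi_mask(hi, n, px)] + 3
  out <- normalize_pair(img, lo, hi, pixel_mm = px)
  expect_equal(mean(out[roi_mask(lo, n, px)]), 0, tolerance = 1e-12)
  expect_equal(mean(out[roi_mask(hi, n, px)]), 1, tolerance = 1e-12)
  # already normalized: identity
  out2 <- normalize_pair(out, lo, hi, pixel_mm = px)
  expect_equal(out2, out, tolerance = 1e-12)
  # inverted contrast: negative gain still lands on 0/1
  inv <- normalize_pair(-img, lo, hi, pixel_mm = px)
  expect_equal(mean(inv[roi_mask(hi, n, px)]), 1, tolerance = 1e-12)
  expect_error(normalize_pair(matrix(1, 64, 64), lo, hi, pixel_mm = 1),
               "equal")
})

test_that("fusion partitions frequencies exactly", {
  set.seed(2)
  a <- matrix(rnorm(64 * 64), 64, 64)
  d <- matrix(rnorm(64 * 64), 64, 64)
  # sigma 0: identity on the attenuation channel
  expect_equal(fuse(a, d, 0), a)
  # complementarity: fusing an image with itself returns it for any sigma
  for (s in c(0.7, 2, 8)) expect_equal(fuse(a, a, s), a, tolerance = 1e-9)
  # very large sigma: low-pass tends to the mean, fused -> dpc + offset
  f <- fuse(a, d, 1e4)
  expect_equal(f, d - mean(d) + mean(a), tolerance = 1e-6)
  # smooth-region means follow the attenuation channel
  a2 <- a + 2; d2 <- d + 7
  f2 <- fuse(a2, d2, 3)
  expect_equal(mean(f2), mean(a2), tolerance = 0.05)
})

test_that("CNR follows its definition", {
  img <- matrix(0, 60, 60)
  A <- roi_at(-15, 0, 6); B <- roi_at(15, 0, 6)
  mA <- roi_mask(A, 60, 1); mB <- roi_mask(B, 60, 1)
  # deterministic +-0.2 checkerboard noise: sd exactly 0.2
  img[mA] <- 1 + 0.2 * rep_len(c(-1, 1), sum(mA))
  img[mB] <- 0 + 0.2 * rep_len(c(-1, 1), sum(mB))
  v <- stats::var(img[mA])
  expect_equal(cnr(img, A, B, pixel_mm = 1), 1 / sqrt(v), tolerance = 1e-3)
  expect_equal(cnr(img, A, A, pixel_mm = 1), 0)
  expect_error(cnr(img, roi_at(0, 0, 2), B, pixel_mm = 1), "25 pixels")
})

test_that("blurring raises the CNR of a noisy two-level image", {
  set.seed(3)
  img <- matrix(rnorm(100 * 100, 0, 1), 100, 100)
  img[, 51:100] <- img[, 51:100] + 1
  A <- roi_at(-20, -20, 10); B <- roi_at(-20, 20, 10)
  c0 <- cnr(img, A, B, pixel_mm = 1)
  c1 <- cnr(gaussian_blur(img, 2), A, B, pixel_mm = 1)
  expect_gt(c1, c0)
})

test_that("kernel search matches the white-noise closed form", {
  # CNR(sigma) = 2 sigma sqrt(pi) * dm / sd for white noise of unit sd:
  # target 5 with dm = 1 gives sigma* = 5/(2 sqrt(pi))
  set.seed(4)
  img <- matrix(rnorm(160 * 160), 160, 160)
  img[, 81:160] <- img[, 81:160] + 1
  A <- roi_at(-40, -40, 24); B <- roi_at(-40, 40, 24)
  got <- kernel_for_cnr(img, A, B, target = 5, pixel_mm = 1)
  pred <- 5 / (2 * sqrt(pi)) * 2 * sqrt(2 * log(2))
  expect_lt(abs(got / pred - 1), 0.1)
  # already above target: zero kernel
  expect_equal(kernel_for_cnr(img * 1e3 + outer(rep(0, 160), rep(0, 160)),
                              A, B, target = 1e-6, pixel_mm = 1), 0)
  # unreachable target: absent
  expect_true(is.na(kernel_for_cnr(img, A, B, target = 1e5,
                                   pixel_mm = 1)))
})

test_that("dose-kernel fits interpolate and cross analytically", {
  f <- dose_kernel_fit(c(10, 30), c(2, 1))
  expect_equal(f$slope, -0.05)
  expect_equal(f$intercept, 2.5)
  expect_equal(predict_kernel(f, 20), 1.5)
  g <- dose_kernel_fit(c(10, 30), c(1.2, 1.0))
  expect_equal(crossing_dose(f, g), (1.3 - 2.5) / (-0.05 + 0.01))
  expect_error(dose_kernel_fit(10, 1), "2")
})

test_that("fused noise power is bounded by the better channel per band", {
  set.seed(5)
  n <- 128
  white <- function() matrix(rnorm(n * n), n, n)
  shape <- function(img, gain) {
    # radially shape white noise in the Fourier domain
    fx <- c(0:(n / 2), -(n / 2 - 1):-1) / n
    fr <- sqrt(outer(fx^2, fx^2, `+`))
    Re(stats::fft(stats::fft(img) * gain(fr), inverse = TRUE)) / (n * n)
  }
  att_noise <- shape(white(), function(f) f / 0.5)        # ramp-like NPS
  dpc_noise <- shape(white(), function(f) pmin(0.05 / pmax(f, 0.01), 1.5))
  fused <- fuse(att_noise, dpc_noise, sigma_px = 2)
  nf <- radial_nps(fused); na <- radial_nps(att_noise)
  nd <- radial_nps(dpc_noise)
  lo <- nf$freq < 0.08; hi <- nf$freq > 0.3
  # low band follows attenuation (quieter there), high band follows phase
  expect_lt(sum(nf$power[lo]), sum(nd$power[lo]))
  expect_lt(sum(nf$power[hi]), sum(na$power[hi]))
})
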