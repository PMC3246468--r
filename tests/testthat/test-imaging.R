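test_that("the FFT bandpass keeps in-band structure and damps the rest", {
  # uniform image passes through unchanged (mean re-added after filtering)
  u <- matrix(7, 64, 64)
  expect_equal(fft_bandpass(u, 8, 128)$data, u, tolerance = 1e-10)
  expect_error(fft_bandpass(u, 10, 5), "invalid band")

  n <- 256
  grating <- function(period) {
    base <- matrix(100, n, 16)
    base + 20 * sin(2 * pi * outer(seq_len(n), rep(1, 16)) / period)
  }
  amp <- function(m) (max(m) - min(m)) / 2
  # period well inside the band: amplitude preserved within 5 %
  inband <- fft_bandpass(grating(32), 8, 128)$data
  expect_equal(amp(inband), 20, tolerance = 0.05)
  # periods outside the band: attenuated by at least 80 %
  toobig <- fft_bandpass(grating(256), 8, 32)$data
  expect_lt(amp(toobig), 0.2 * 20)
  toosmall <- fft_bandpass(grating(4), 8, 128)$data
  expect_lt(amp(toosmall), 0.2 * 20)
})

test_that("the bandpass is deterministic and near-idempotent", {
  set.seed(3)
  img <- matrix(runif(64 * 48, 50, 150), 64, 48)
  once <- fft_bandpass(img, 4, 32)$data
  expect_identical(once, fft_bandpass(img, 4, 32)$data)
  twice <- fft_bandpass(once, 4, 32)$data
  expect_equal(twice, once, tolerance = 0.05)
})

test_that("ROI profiles are per-row means across the membrane direction", {
  m <- matrix(5, 40, 30)
  prof <- roi_profile(m, roi_band(1:40, 1:30))
  expect_equal(prof$intensity, rep(5, 40))

  m2 <- m; m2[25, ] <- 0  # one dark row crossing the ROI
  prof2 <- roi_profile(m2, roi_band(1:40, 5:20))
  expect_equal(which.min(prof2$intensity), 25)

  set.seed(19)
  m3 <- matrix(runif(40 * 30), 40, 30)
  roi <- roi_band(5:30, 4:27)
  prof3 <- roi_profile(m3, roi)
  brute <- vapply(5:30, function(r) mean(m3[r, 4:27]), 1)
  expect_equal(prof3$intensity, brute)
  expect_error(roi_profile(m3, roi_band(30:50, 1:10)), "bounds")
})

test_that("planted triple troughs are counted and located to sub-pixel accuracy", {
  x <- seq_len(100)
  prof <- 100 - 30 * (exp(-(x - 20)^2 / 8) + exp(-(x - 50)^2 / 8) +
                        exp(-(x - 80)^2 / 8))
  call <- detect_membranes(prof)
  expect_identical(call$count, 3L)
  expect_equal(call$positions_px, c(20, 50, 80), tolerance = 0.5)
  expect_equal(call$spacing_unit, "px")
  expect_equal(call$spacings, c(30, 30), tolerance = 1)

  flat <- detect_membranes(rep(4, 50))
  expect_identical(flat$count, 0L)
})

test_that("membrane detection is invariant to affine intensity changes", {
  gen <- generate_membrane_image(n_lines = 3, noise_sd = 10, seed = 23)
  prof <- roi_profile(gen$image, roi_band(1:120, 1:80))
  base <- detect_membranes(prof)
  scaled <- detect_membranes(3.7 * prof$intensity + 40)
  expect_identical(base$count, scaled$count)
  expect_equal(base$positions_px, scaled$positions_px, tolerance = 1e-9)
})

test_that("calibrated spacings convert planted geometry to nanometres", {
  gen <- generate_membrane_image(n_lines = 2, line_spacing = 20,
                                 noise_sd = 0, pixel_size = 2.5, seed = 1)
  prof <- roi_profile(gen$image, roi_band(1:120, 1:80))
  call <- detect_membranes(prof)
  expect_identical(call$count, 2L)
  expect_equal(call$spacing_unit, "nm")
  expect_equal(call$mean_spacing, 20 * 2.5, tolerance = 0.5 * 2.5)
  expect_equal(call$positions_px, gen$manifest$line_centres_px,
               tolerance = 0.5)
})

test_that("layer classification maps counts to membrane organisations", {
  mk <- function(k) structure(list(count = k), class = "membrane_call")
  expect_equal(classify_membrane_system(mk(2L)), "two_layer")
  expect_equal(classify_membrane_system(mk(3L)), "three_layer")
  expect_equal(classify_membrane_system(mk(5L)), "other")
  expect_equal(classify_membrane_system(mk(0L)), "other")
})

test_that("contact-point compatibility separates the reference spacings", {
  expect_true(contact_point_compatible(14.8))   # mitochondrial scale
  expect_false(contact_point_compatible(37.3))  # symbiosomal scale
  expect_false(contact_point_compatible(41.4))
  expect_true(contact_point_compatible(20))     # boundary convention: <=
})

test_that("noisy planted geometries are recovered at SNR 5", {
  correct <- 0
  for (s in 1:30) {
    n_lines <- if (s %% 2 == 0) 2 else 3
    gen <- generate_membrane_image(n_lines = n_lines, line_spacing = 25,
                                   line_depth = 100, noise_sd = 20,
                                   blur_sigma = 1, seed = 7000 + s)
    prof <- roi_profile(gen$image, roi_band(1:120, 1:80))
    call <- detect_membranes(prof)
    if (call$count == n_lines) correct <- correct + 1
  }
  expect_gte(correct, 29)
})

test_that("image files round-trip through PNG and TIFF", {
  gen <- generate_membrane_image(seed = 5, noise_sd = 5)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gray_image(gen$image, path)
    back <- read_gray_image(path, pixel_size = 2)
    expect_identical(dim(back$data), dim(gen$image$data))
    expect_equal(back$pixel_size, 2)
    # structure is preserved: same trough count after rescaling
    call <- detect_membranes(roi_profile(back, roi_band(1:120, 1:80)))
    expect_identical(call$count, 3L)
  }
})

test_that("ratiometric analysis of identical images is exactly uniform", {
  img <- matrix(runif(32 * 32, 50, 150), 32, 32)
  res <- ratiometric_image(img, img)
  expect_true(all(res$ratio == 1))
  expect_equal(res$cv, 0)
  expect_equal(nrow(res$contrast_regions), 0)
  expect_error(ratiometric_image(img, -img, offset = 0), "positive")
})

test_that("a planted ratio-shifted region is detected, a uniform pair is not", {
  planted <- generate_ratiometric_pair(
    contrast_region = list(rows = 30:50, cols = 40:60, ratio_shift = 1.5),
    seed = 11)
  res <- ratiometric_image(planted$img_a, planted$img_b, offset = 1, k = 3)
  expect_gte(nrow(res$contrast_regions), 1)
  # the biggest region overlaps the planted mask almost entirely
  big <- res$contrast_regions[which.max(res$contrast_regions$area), ]
  overlap <- mean(planted$manifest$planted_mask[big$pixels[[1]]])
  expect_gte(overlap, 0.95)

  uniform <- generate_ratiometric_pair(seed = 12)
  res0 <- ratiometric_image(uniform$img_a, uniform$img_b, offset = 1, k = 3)
  expect_equal(nrow(res0$contrast_regions), 0)
  expect_lt(res0$cv, 0.1)
})

test_that("weight and offset scale the ratio as documented", {
  a <- matrix(10, 4, 4); b <- matrix(4, 4, 4)
  res <- ratiometric_image(a, b, offset = 1, weight = 2)
  expect_true(all(res$ratio == 2 * 10 / 5))
})
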