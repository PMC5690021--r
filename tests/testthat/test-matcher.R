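test_that("sigma scales linearly with the window size", {
  expect_equal(compute_sigma(384, 0.4), 153.6)  # the default N = 480 * 0.8
  expect_equal(compute_sigma(100, 1.0), 100)
  expect_equal(compute_sigma(1, 0.5), 0.5)
  expect_error(compute_sigma(0, 0.4))
  expect_error(compute_sigma(10, 0))
})

test_that("the Gaussian weight has its closed-form values and symmetry", {
  ic <- c(40, 60)
  # displaced pixel on the isocenter: weight 1
  expect_equal(gaussian_weight(c(38, 60), c(2, 0), ic, sigma = 10), 1)
  # one-sigma displacement: exp(-1/2)
  expect_equal(gaussian_weight(c(30, 60), c(0, 0), ic, sigma = 10),
               exp(-0.5))
  # radial symmetry: swapping the x- and y-offsets preserves the weight
  expect_equal(gaussian_weight(c(37, 56), c(0, 0), ic, sigma = 7),
               gaussian_weight(c(36, 57), c(0, 0), ic, sigma = 7))
  expect_error(gaussian_weight(c(1, 1), c(0, 0), ic, sigma = 0),
               class = "couchmatch_input_error")
})

test_that("weighted ZNCC hits the exact values of perfect (anti)correlation", {
  img <- blob_image(24)
  cfg <- match_config(s = NULL, sn = 1, M = 4, weight = "uniform")
  expect_equal(weighted_zncc(img, img, c(0, 0), config = cfg), 1)
  neg <- max(img) + min(img) - img   # mean-reflected negation
  expect_equal(weighted_zncc(neg, img, c(0, 0), config = cfg), -1)
})

test_that("weighted ZNCC equals the literal term-by-term transcription", {
  set.seed(5)
  dr <- matrix(runif(64, 0, 65535), 8, 8)
  drr <- matrix(runif(64, 0, 65535), 8, 8)
  ic <- c(4.5, 4.5)
  sigma <- compute_sigma(8, 0.4)
  cfg <- match_config(s = NULL, sn = 1, s_sigma = 0.4, M = 3,
                      min_valid_px = 4)
  for (d in list(c(0, 0), c(1, -2), c(-2, 3), c(0.5, -1.25))) {
    expect_equal(weighted_zncc(dr, drr, d, config = cfg),
                 zncc_oracle(dr, drr, d, ic, sigma, min_valid = 4),
                 tolerance = 1e-10, info = paste(d, collapse = ","))
  }
  # and with a collimator mask excluding a band
  valid <- matrix(TRUE, 8, 8); valid[, 1:2] <- FALSE
  expect_equal(weighted_zncc(dr, drr, c(1, 1), valid, cfg),
               zncc_oracle(dr, drr, c(1, 1), ic, sigma, valid, 4),
               tolerance = 1e-10)
})

test_that("correlation is invariant to gain, and to offset under uniform weight", {
  img <- blob_image(32, seed = 9)
  shifted <- img[, c(3:32, 32, 32)]  # crude content shift for texture
  cfg <- match_config(s = NULL, sn = 1, s_sigma = 0.4, M = 3)
  cfg_u <- match_config(s = NULL, sn = 1, M = 3, weight = "uniform")
  for (d in list(c(0, 0), c(2, -1))) {
    r0 <- weighted_zncc(shifted, img, d, config = cfg)
    expect_lt(abs(weighted_zncc(shifted, 3.7 * img, d, config = cfg) - r0),
              1e-9)
    r0u <- weighted_zncc(shifted, img, d, config = cfg_u)
    expect_lt(abs(weighted_zncc(shifted, img + 4321, d, config = cfg_u) - r0u),
              1e-9)
    expect_lt(abs(weighted_zncc(shifted + 999, 2 * img + 123, d,
                                config = cfg_u) - r0u), 1e-9)
  }
})

test_that("zero-variance patches yield the undefined-correlation sentinel", {
  flat <- matrix(100, 16, 16)
  img <- blob_image(16)
  cfg <- match_config(s = NULL, sn = 1, M = 2, weight = "uniform")
  expect_true(is.na(weighted_zncc(flat, img, c(0, 0), config = cfg)))
  expect_true(is.na(weighted_zncc(img, flat, c(0, 0), config = cfg)))
  # all candidates undefined -> explicit error from the surface
  expect_error(correlation_surface(flat, flat, config = cfg),
               class = "couchmatch_match_error")
})

test_that("the correlation surface peaks at the applied integer shift", {
  img <- blob_image(48, seed = 3)
  cfg <- match_config(s = NULL, sn = 0.6, M = 6)
  surf <- correlation_surface(img, img, config = cfg)
  expect_true(all(abs(surf$R) <= 1, na.rm = TRUE))
  pk <- which(surf$R == max(surf$R, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(surf$dx[pk[1, 2]]), 0)
  expect_equal(unname(surf$dy[pk[1, 1]]), 0)

  # content shifted by an integer (+3, -2): peak moves there
  sh <- shift_image(img, 3, -2)
  surf2 <- correlation_surface(sh, img, config = cfg)
  pk2 <- which(surf2$R == max(surf2$R, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(surf2$dx[pk2[1, 2]]), -3)
  expect_equal(unname(surf2$dy[pk2[1, 1]]), 2)
})

test_that("best_match recovers identity and fractional shifts to subpixel", {
  img <- blob_image(48, seed = 21)
  cfg <- match_config(s = NULL, sn = 0.6, M = 6, subpixel_step_px = 0.05)
  d0 <- best_match(img, img, config = cfg)
  expect_equal(d0$dx_px, 0)
  expect_equal(d0$dy_px, 0)
  expect_equal(d0$peak_correlation, 1, tolerance = 1e-12)

  # fractional (+1.5, -0.5) shift, bilinear-resampled, no noise
  sh <- shift_image(img, 1.5, -0.5)
  d1 <- best_match(sh, img, config = cfg)
  expect_lt(abs(-d1$dx_px - 1.5), 0.1)
  expect_lt(abs(-d1$dy_px - (-0.5)), 0.1)

  # refinement never loses to the integer grid
  surf <- correlation_surface(sh, img, config = cfg)
  expect_gte(d1$peak_correlation, max(surf$R, na.rm = TRUE) - 1e-9)
})

test_that("best_match agrees with exhaustive fractional-grid maximization", {
  img <- blob_image(32, seed = 14)
  sh <- shift_image(img, 1.75, -1.25)
  step <- 0.25
  cfg <- match_config(s = NULL, sn = 1, s_sigma = 0.4, M = 3,
                      subpixel_step_px = step)
  got <- best_match(sh, img, config = cfg)
  ic <- c((32 + 1) / 2, (32 + 1) / 2)
  oracle <- brute_best_match(sh, img, M = 3, step = step, ic = ic,
                             sigma = compute_sigma(32, 0.4))
  expect_lte(abs(got$dx_px - oracle$dx), step + 1e-9)
  expect_lte(abs(got$dy_px - oracle$dy), step + 1e-9)
  expect_equal(got$peak_correlation,
               zncc_oracle(sh, img, c(got$dx_px, got$dy_px), ic,
                           compute_sigma(32, 0.4)),
               tolerance = 1e-9)
})

test_that("matching is shift-consistent and flags border peaks", {
  img <- blob_image(48, seed = 30)
  cfg <- match_config(s = NULL, sn = 0.5, M = 6, subpixel_step_px = 0.05)
  sh <- shift_image(img, 2, 3)
  fwd <- best_match(sh, img, config = cfg)
  bwd <- best_match(img, sh, config = cfg)
  expect_lte(abs(fwd$dx_px + bwd$dx_px), 2 * cfg$subpixel_step_px)
  expect_lte(abs(fwd$dy_px + bwd$dy_px), 2 * cfg$subpixel_step_px)
  expect_false(fwd$border_peak)

  # a shift beyond the search radius pins the peak to the border
  far <- shift_image(img, 10, 0)
  dfar <- best_match(far, img, config = cfg)
  expect_true(dfar$border_peak)
})

test_that("matching is bit-reproducible", {
  img <- blob_image(32, seed = 2)
  sh <- shift_image(img, 1.5, 0.5)
  cfg <- match_config(s = NULL, sn = 0.8, M = 4)
  a <- best_match(sh, img, config = cfg)
  b <- best_match(sh, img, config = cfg)
  expect_identical(a, b)
})
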