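test_that("overlay detection flags exactly the palette-colored pixels", {
  S <- 16
  gray <- matrix(20000, S, S)
  rgb <- array(gray, c(S, S, 3))
  img <- radiograph(rgb, "frontal")
  pal <- default_overlay_palette()

  # pure-gray image: nothing matches a saturated palette
  expect_false(any(detect_overlay_mask(img, pal, tolerance = 500)))

  # one pixel set to an exact palette color, tolerance 0
  rgb[5, 7, ] <- pal["mark", ]
  img2 <- radiograph(rgb, "frontal")
  mk <- detect_overlay_mask(img2, pal, tolerance = 0)
  expect_equal(sum(mk), 1)
  expect_true(mk[5, 7])

  # grayscale input cannot be color-matched
  expect_error(detect_overlay_mask(radiograph(gray, "frontal"), pal),
               class = "couchmatch_input_error")
  expect_error(detect_overlay_mask(img2, matrix(numeric(0), 0, 3)),
               class = "couchmatch_input_error")
})

test_that("overlay detection recovers the generator's ground-truth overlay set", {
  spec <- tiny_spec()
  drr <- render_drr(spec, "frontal")
  rd <- render_dr(drr, c(1, 0, -1), spec)
  mk <- detect_overlay_mask(rd$image, default_overlay_palette(),
                            tolerance = 500)
  expect_identical(mk, rd$truth$overlay_mask)
})

test_that("inpainting fills from non-overlay 8-neighbors and nothing else", {
  # constant image stays constant under any (partial) overlay
  m <- matrix(7, 9, 9)
  ov <- matrix(FALSE, 9, 9); ov[3:5, 4:6] <- TRUE
  expect_equal(inpaint_overlay(m, ov), matrix(7, 9, 9))

  # empty overlay: identity
  r <- matrix(runif(81, 0, 65535), 9, 9)
  expect_identical(inpaint_overlay(r, matrix(FALSE, 9, 9)), r)

  # single pixel on a ramp: mean of its 8 neighbors, computed by hand
  ramp <- outer(1:9, 1:9, function(y, x) 100 * x + 3 * y)
  ov1 <- matrix(FALSE, 9, 9); ov1[5, 5] <- TRUE
  got <- inpaint_overlay(ramp, ov1)
  nbrs <- ramp[4:6, 4:6][-5]
  expect_equal(got[5, 5], mean(nbrs))
  # locality: all other pixels bit-exact
  idx55 <- (5 - 1) * 9 + 5
  expect_identical(got[-idx55], ramp[-idx55])

  # idempotence once the mask is consumed
  expect_identical(inpaint_overlay(got, matrix(FALSE, 9, 9)), got)

  # full-cover mask is rejected
  expect_error(inpaint_overlay(r, matrix(TRUE, 9, 9)),
               class = "couchmatch_input_error")
})

test_that("thick overlays resolve by onion peeling", {
  ramp <- outer(1:15, 1:15, function(y, x) 50 * x + 20 * y)
  ov <- matrix(FALSE, 15, 15); ov[5:11, 5:11] <- TRUE  # 7x7: core has no
  got <- inpaint_overlay(ramp, ov)                     # unmasked neighbor
  expect_true(all(is.finite(got)))
  expect_identical(got[!ov], ramp[!ov])
  # filled values stay within the hull of the surrounding intensities
  expect_true(all(got[ov] >= min(ramp[!ov]) & got[ov] <= max(ramp[!ov])))
})

test_that("Sobel magnitude matches the hand-computed 3x3 response", {
  expect_equal(sobel_magnitude(matrix(5, 8, 8)), matrix(0, 8, 8))

  # vertical step of height h: |gx| = 4h on the two columns flanking the step
  h <- 1000
  step <- cbind(matrix(0, 6, 3), matrix(h, 6, 3))
  sm <- sobel_magnitude(step)
  expect_equal(sm[, 3], rep(4 * h, 6))
  expect_equal(sm[, 4], rep(4 * h, 6))
  expect_equal(sm[, c(1, 2, 5, 6)], matrix(0, 6, 4))

  # transposition symmetry
  img <- blob_image(24)
  expect_equal(sobel_magnitude(t(img)), t(sobel_magnitude(img)))

  expect_error(sobel_magnitude(matrix(1, 2, 2)),
               class = "couchmatch_input_error")
})

test_that("collimator mask scans inward to the first supra-threshold edge", {
  # no gradients anywhere: nothing blocked
  expect_false(any(detect_collimator_mask(matrix(0, 10, 10) + 1, mt = 10)))

  # dark band over the left 12 columns ending in a sharp step: every row
  # masks the columns left of the step
  S <- 24
  img <- matrix(20000, S, S); img[, 1:12] <- 0
  cm <- detect_collimator_mask(sobel_magnitude(img), mt = 30000)
  expect_true(all(cm[, 1:10]))
  expect_false(any(cm[, 12:13]))      # the edge columns themselves stay open

  # high-contrast rectangular frame: the frame interior stays usable and the
  # bands beyond each edge are blocked by the row/column scans; the outer
  # corners, reached by neither scan, stay open under union semantics
  fr <- matrix(0, S, S); fr[6:19, 5:20] <- 20000
  cmf <- detect_collimator_mask(sobel_magnitude(fr), mt = 30000)
  expect_false(any(cmf[7:18, 6:19]))     # interior fully usable
  expect_true(all(cmf[8:17, 1:3]))       # left band
  expect_true(all(cmf[8:17, 22:24]))     # right band
  expect_true(all(cmf[1:4, 7:18]))       # top band
  expect_true(all(cmf[21:24, 7:18]))     # bottom band
  expect_false(cmf[1, 1])                # corner: no scan reaches it
})

test_that("blocked set grows with the threshold while edges still qualify", {
  S <- 32
  img <- matrix(0, S, S)       # weak outer step at col 8|9, strong inner
  img[, 9:S] <- 10000          # step at col 12|13: raising the threshold
  img[, 13:S] <- 40000         # disqualifies the weak edge first
  edges <- sobel_magnitude(img)
  thresholds <- c(20000, 60000, 100000)
  masks <- lapply(thresholds, function(mt) detect_collimator_mask(edges, mt))
  for (i in seq_len(length(masks) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))  # superset
  }
})

test_that("preprocessing recovers the generator's usable region to ~1 px", {
  spec <- tiny_spec()
  drr <- render_drr(spec, "frontal")
  rd <- render_dr(drr, c(0.5, 0, 0.5), spec)
  pre <- preprocess_captured(rd$image, tiny_cfg())
  truth_blocked <- rd$truth$blocked_mask

  disagreement <- xor(pre$collimator_mask, truth_blocked)
  # any disagreement must sit within 1 px of the true field edge, or in the
  # corner blocks that no row/column scan can reach (and that lie outside
  # the isocenter-centered calculation window anyway)
  S <- spec$size_px
  cp <- spec$collimation_px
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  near_edge <- abs(x - cp["left"]) <= 1 | abs(x - (S - cp["right"] + 1)) <= 1 |
               abs(y - cp["top"]) <= 1 | abs(y - (S - cp["bottom"] + 1)) <= 1
  in_x_band <- x <= cp["left"] | x > S - cp["right"]
  in_y_band <- y <= cp["top"] | y > S - cp["bottom"]
  corner <- in_x_band & in_y_band
  expect_true(all((near_edge | corner)[disagreement]))
  # and the overlay annotations were all found and removed
  expect_identical(pre$overlay_mask, rd$truth$overlay_mask)
})
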