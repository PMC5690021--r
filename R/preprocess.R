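#' @noRd
.px_matrix <- function(image, what = "image") {
  if (is_radiograph(image)) {
    if (image$channels != 1L) {
      abort(paste0(what, " must be single-channel"),
            class = "couchmatch_input_error")
    }
    image$pixels
  } else if (is.matrix(image) && is.numeric(image)) {
    image
  } else {
    abort(paste0(what, " must be a radiograph or numeric matrix"),
          class = "couchmatch_input_error")
  }
}

# rewrap a pixel matrix in the geometry of a source radiograph (if any)
#' @noRd
.rewrap <- function(px, like) {
  if (is_radiograph(like)) {
    radiograph(px, view = like$view,
               pixel_spacing_mm = like$pixel_spacing_mm,
               isocenter_px = like$isocenter_px)
  } else {
    px
  }
}

#' Detect rendered overlay annotations by palette color
#'
#' Captured positioning images carry colored decorations (target-volume
#' contour, axes, grid ticks, pointing marks) drawn over the grayscale
#' radiograph.  A pixel is flagged when each of its RGB channels lies within
#' `tolerance` of some palette entry.
#'
#' @param image A 3-channel `radiograph` (or h x w x 3 array) on the 16-bit
#'   scale.
#' @param palette Numeric matrix with one RGB row per overlay color (16-bit
#'   scale), or a list of length-3 vectors.
#' @param tolerance Per-channel tolerance (scalar or length 3), same scale.
#' @return Logical matrix, `TRUE` at annotation pixels.
#' @export
detect_overlay_mask <- function(image, palette, tolerance = 0) {
  px <- if (is_radiograph(image)) image$pixels else image
  if (!(is.array(px) && length(dim(px)) == 3 && dim(px)[3] == 3)) {
    abort("overlay detection needs a color (3-channel) image",
          class = "couchmatch_input_error")
  }
  if (is.list(palette)) palette <- do.call(rbind, palette)
  if (is.null(dim(palette))) palette <- matrix(palette, nrow = 1)
  if (nrow(palette) < 1) {
    abort("`palette` must contain at least one color",
          class = "couchmatch_input_error")
  }
  tolerance <- rep_len(tolerance, 3)
  d <- dim(px)[1:2]
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(palette))) {
    hit <- abs(px[, , 1] - palette[i, 1]) <= tolerance[1] &
           abs(px[, , 2] - palette[i, 2]) <= tolerance[2] &
           abs(px[, , 3] - palette[i, 3]) <= tolerance[3]
    mask <- mask | hit
  }
  mask
}

#' Inpaint overlay pixels from their 8-neighborhoods
#'
#' Each flagged pixel is replaced by the mean of its non-flagged 8-neighbors;
#' pixels whose whole neighborhood is flagged are filled on later passes from
#' the already-filled values (onion peel), so arbitrarily thick annotations
#' resolve deterministically.  Non-flagged pixels are never touched.
#'
#' @param image Single-channel `radiograph` or numeric matrix.
#' @param overlay Logical matrix of the same shape flagging pixels to fill.
#' @return Same type as `image`, with overlay pixels filled.
#' @export
inpaint_overlay <- function(image, overlay) {
  px <- .px_matrix(image)
  if (!identical(dim(overlay), dim(px))) {
    abort("overlay mask shape does not match image",
          class = "couchmatch_input_error")
  }
  if (all(overlay)) {
    abort("overlay mask covers the whole image; nothing to interpolate from",
          class = "couchmatch_input_error")
  }
  h <- nrow(px); w <- ncol(px)
  while (any(overlay)) {
    keep <- !overlay
    vals <- .neighbor_sum(px * keep, h, w)
    cnt  <- .neighbor_sum(keep * 1, h, w)
    fill <- overlay & cnt > 0
    px[fill] <- vals[fill] / cnt[fill]
    overlay[fill] <- FALSE
  }
  .rewrap(px, image)
}

# sum of the 8 neighbors of every pixel (zero beyond the border)
#' @noRd
.neighbor_sum <- function(m, h, w) {
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  p[1:h,       1:w      ] + p[1:h,       2:(w + 1)] + p[1:h,       3:(w + 2)] +
  p[2:(h + 1), 1:w      ] +                           p[2:(h + 1), 3:(w + 2)] +
  p[3:(h + 2), 1:w      ] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
}

#' Sobel gradient magnitude
#'
#' Euclidean magnitude of the horizontal and vertical 3x3 Sobel responses,
#' with edge-replication borders.  Used to locate the sharp radiation
#' field edge left by the collimators.
#'
#' @param image Single-channel `radiograph` or numeric matrix, at least 3x3.
#' @return Numeric matrix of gradient magnitudes, same shape.
#' @export
sobel_magnitude <- function(image) {
  m <- .px_matrix(image)
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) {
    abort("image smaller than 3x3 cannot be edge-filtered",
          class = "couchmatch_input_error")
  }
  p <- m[c(1, 1:h, h), c(1, 1:w, w)]  # edge replication
  nw <- p[1:h, 1:w];       n  <- p[1:h, 2:(w + 1)];       ne <- p[1:h, 3:(w + 2)]
  wst <- p[2:(h + 1), 1:w];                               est <- p[2:(h + 1), 3:(w + 2)]
  sw <- p[3:(h + 2), 1:w]; s  <- p[3:(h + 2), 2:(w + 1)]; se <- p[3:(h + 2), 3:(w + 2)]
  gx <- (ne + 2 * est + se) - (nw + 2 * wst + sw)
  gy <- (sw + 2 * s + se) - (nw + 2 * n + ne)
  sqrt(gx^2 + gy^2)
}

#' Mask the collimator-blocked border region
#'
#' Scans each row inward from the left and right, and each column inward from
#' the top and bottom, for the first Sobel magnitude exceeding `mt` (the
#' radiation field edge); pixels outside that first edge point are marked
#' blocked.  The final mask is the union of the row-wise and column-wise
#' blocked sets.  Rows or columns with no supra-threshold edge contribute no
#' blocked pixels (an open side of the field).
#'
#' @param edges Gradient-magnitude matrix from [sobel_magnitude()].
#' @param mt Positive masking threshold on the 16-bit intensity scale
#'   (default 30000).
#' @return Logical matrix, `TRUE` at blocked pixels.
#' @export
detect_collimator_mask <- function(edges, mt = 30000) {
  stopifnot(is.matrix(edges), is.numeric(mt), length(mt) == 1, mt > 0)
  h <- nrow(edges); w <- ncol(edges)
  v <- (edges > mt) * 1

  row_has <- rowSums(v) > 0
  first <- max.col(v, ties.method = "first")
  last  <- w + 1 - max.col(v[, w:1, drop = FALSE], ties.method = "first")
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  rows_mask <- row_has & (cols < first | cols > last)

  tv <- t(v)
  col_has <- rowSums(tv) > 0
  firstc <- max.col(tv, ties.method = "first")
  lastc  <- h + 1 - max.col(tv[, h:1, drop = FALSE], ties.method = "first")
  rws <- matrix(seq_len(h), h, w)
  cols_mask <- matrix(col_has, h, w, byrow = TRUE) &
    (rws < matrix(firstc, h, w, byrow = TRUE) |
     rws > matrix(lastc,  h, w, byrow = TRUE))

  rows_mask | cols_mask
}

#' Clean a captured image for matching
#'
#' Runs the full preprocessing chain: detect overlay annotations by palette
#' color (color inputs only), inpaint them, collapse to grayscale, then mask
#' the collimator-blocked region from the Sobel edge image.
#'
#' @param image A `radiograph` (gray or color captured image).
#' @param config A [match_config()]; supplies `mt`, `overlay_palette`,
#'   `overlay_tolerance` and `bit_depth`.
#' @return A list with elements `image` (cleaned single-channel
#'   `radiograph`), `valid` (logical matrix, `TRUE` = usable), and the
#'   intermediate `overlay_mask` and `collimator_mask`.
#' @export
preprocess_captured <- function(image, config = match_config()) {
  stopifnot(is_radiograph(image))
  overlay <- NULL
  if (image$channels == 3L) {
    overlay <- detect_overlay_mask(image, config$overlay_palette,
                                   config$overlay_tolerance)
    gray <- to_gray(image)
    gray <- inpaint_overlay(gray, overlay)
  } else {
    gray <- image
    overlay <- matrix(FALSE, nrow(image$pixels), ncol(image$pixels))
  }
  mt_eff <- if (config$bit_depth == 8) config$mt / 257 else config$mt
  coll <- detect_collimator_mask(sobel_magnitude(gray), mt_eff)
  list(image = gray, valid = !coll,
       overlay_mask = overlay, collimator_mask = coll)
}
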