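#' Radiograph container
#'
#' Holds one 2-D radiograph: either a grayscale DR/DRR or a color "captured"
#' image carrying rendered overlay annotations.  Pixels are stored on a
#' 16-bit intensity scale (0--65535) as a numeric matrix (gray) or an
#' height x width x 3 array (color).  Pixel coordinates are 1-based
#' `(x, y) = (column, row)` with the origin at the top-left pixel, matching R
#' matrix indexing; all physical quantities are derived from
#' `pixel_spacing_mm` only.
#'
#' @param pixels Numeric matrix (grayscale) or h x w x 3 array (color) of
#'   nonnegative intensities on a 16-bit scale.
#' @param view `"frontal"` or `"lateral"`.  The frontal image x-axis maps to
#'   the lateral couch axis, the lateral image x-axis to the vertical couch
#'   axis, and both images' y-axes to the longitudinal couch axis.
#' @param pixel_spacing_mm Physical size of one pixel in mm (> 0).
#' @param isocenter_px Length-2 numeric `(x, y)` isocenter position in pixel
#'   coordinates; defaults to the image center.  Must lie inside the image.
#' @return An object of class `radiograph`.
#' @export
radiograph <- function(pixels, view = c("frontal", "lateral"),
                       pixel_spacing_mm = 0.446, isocenter_px = NULL) {
  view <- match.arg(view)
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    channels <- 3L
  } else {
    abort("`pixels` must be a numeric matrix or an h x w x 3 array",
          class = "couchmatch_input_error")
  }
  d <- dim(pixels)[1:2]
  if (any(d < 1)) {
    abort("image is empty", class = "couchmatch_input_error")
  }
  if (!is.numeric(pixels) || anyNA(pixels) || min(pixels) < 0) {
    abort("pixel intensities must be finite and nonnegative",
          class = "couchmatch_input_error")
  }
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1 ||
      pixel_spacing_mm <= 0) {
    abort("`pixel_spacing_mm` must be a single positive number",
          class = "couchmatch_input_error")
  }
  if (is.null(isocenter_px)) {
    isocenter_px <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
  }
  if (length(isocenter_px) != 2 ||
      isocenter_px[1] < 1 || isocenter_px[1] > d[2] ||
      isocenter_px[2] < 1 || isocenter_px[2] > d[1]) {
    abort("`isocenter_px` must be an (x, y) position inside the image",
          class = "couchmatch_input_error")
  }
  structure(
    list(pixels = pixels, view = view, channels = channels,
         pixel_spacing_mm = pixel_spacing_mm,
         isocenter_px = as.numeric(isocenter_px)),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<radiograph> %s, %d x %d px (%s), %.3f mm/px, IC (%.1f, %.1f)\n",
              x$view, d[2], d[1], if (x$channels == 3) "color" else "gray",
              x$pixel_spacing_mm, x$isocenter_px[1], x$isocenter_px[2]))
  invisible(x)
}

#' Test for the radiograph class
#' @param x An object.
#' @return `TRUE` for `radiograph` objects.
#' @export
is_radiograph <- function(x) inherits(x, "radiograph")

#' Convert a color radiograph to grayscale
#'
#' Channel mean; a pure-gray color image (r = g = b) is recovered exactly.
#'
#' @param image A `radiograph`.
#' @return A single-channel `radiograph`.
#' @export
to_gray <- function(image) {
  stopifnot(is_radiograph(image))
  if (image$channels == 1L) return(image)
  px <- (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / 3
  radiograph(px, view = image$view,
             pixel_spacing_mm = image$pixel_spacing_mm,
             isocenter_px = image$isocenter_px)
}

#' Read a radiograph from PNG or TIFF
#'
#' 8- and 16-bit, gray or RGB files are accepted; intensities are rescaled to
#' the internal 16-bit scale (0--65535) regardless of file bit depth, so the
#' default masking threshold applies uniformly.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @inheritParams radiograph
#' @return A `radiograph`.
#' @export
read_radiograph <- function(path, view = c("frontal", "lateral"),
                            pixel_spacing_mm = 0.446, isocenter_px = NULL) {
  if (!file.exists(path)) {
    abort(paste0("cannot read image: ", path), class = "couchmatch_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext),
          class = "couchmatch_io_error")
  )
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 3 && dim(px)[3] == 2) px <- px[, , 1]    # gray+alpha
  radiograph(px * 65535, view = view, pixel_spacing_mm = pixel_spacing_mm,
             isocenter_px = isocenter_px)
}

#' Write a radiograph or mask to PNG or TIFF
#'
#' A `.tif`/`.tiff` path writes full 16-bit precision; a `.png` path writes
#' 8-bit (adequate for display and for the color captured images).  Logical
#' masks are written as single-channel 0/255 PNG.
#'
#' @param x A `radiograph` or a logical matrix mask.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(x, path) {
  if (is.logical(x) && is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x), nrow(x), ncol(x)), path)
    return(invisible(path))
  }
  stopifnot(is_radiograph(x))
  px <- pmin(pmax(x$pixels / 65535, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px, path, bits.per.sample = 16L)
  } else {
    png::writePNG(px, path)
  }
  invisible(path)
}
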