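#' Matching configuration
#'
#' Collects the registration tunables.  `s`, `sn`, `s_sigma`, `M` and `mt`
#' are the method's parameters; the remainder are engineering settings.
#'
#' @param s Nominal image side length in pixels used to size the calculation
#'   window (`NULL` derives it from the image).  Default 480.
#' @param sn Window-size fraction in (0, 1]; the calculation window side is
#'   `N = round(s * sn)`.  Default 0.8.
#' @param s_sigma Gaussian-weight width as a fraction of the window side
#'   (`sigma = N * s_sigma`); default 0.4.
#' @param M Search radius in pixels: integer candidate offsets span
#'   `[-M, M]` on each axis.  Default 40, which covers displacements up to
#'   about 17.8 mm at the default pixel spacing.
#' @param mt Sobel masking threshold on the 16-bit scale; default 30000.
#' @param subpixel_step_px Pitch of the fractional-offset refinement grid in
#'   pixels, in (0, 1]; default 0.05 (about 0.022 mm).
#' @param pixel_spacing_mm Pixel size in mm; default 0.446.
#' @param bit_depth 16 (default) or 8; with 8-bit inputs `mt` is rescaled by
#'   1/257 so the printed 16-bit threshold keeps its meaning.
#' @param min_valid_px Minimum number of contributing pixels for a candidate
#'   offset to be defined; default 16.
#' @param weight `"gaussian"` (default) or `"uniform"` (the sigma -> Inf
#'   limit, w = 1 everywhere).
#' @param overlay_palette,overlay_tolerance Overlay annotation colors (16-bit
#'   RGB rows) and per-channel match tolerance for [detect_overlay_mask()].
#' @return A list of class `match_config`.
#' @export
match_config <- function(s = 480, sn = 0.8, s_sigma = 0.4, M = 40,
                         mt = 30000, subpixel_step_px = 0.05,
                         pixel_spacing_mm = 0.446, bit_depth = 16,
                         min_valid_px = 16, weight = c("gaussian", "uniform"),
                         overlay_palette = default_overlay_palette(),
                         overlay_tolerance = 500) {
  weight <- match.arg(weight)
  stopifnot(sn > 0, sn <= 1, s_sigma > 0, M >= 1,
            subpixel_step_px > 0, subpixel_step_px <= 1,
            pixel_spacing_mm > 0, mt > 0, min_valid_px >= 2,
            bit_depth %in% c(8, 16))
  if (!is.null(s) && round(s * sn) < 3) {
    abort("calculation window N = round(s * sn) must be at least 3",
          class = "couchmatch_config_error")
  }
  structure(
    list(s = s, sn = sn, s_sigma = s_sigma, M = as.integer(M), mt = mt,
         subpixel_step_px = subpixel_step_px,
         pixel_spacing_mm = pixel_spacing_mm, bit_depth = bit_depth,
         min_valid_px = as.integer(min_valid_px), weight = weight,
         overlay_palette = overlay_palette,
         overlay_tolerance = overlay_tolerance),
    class = "match_config"
  )
}

#' Default overlay annotation palette
#'
#' Saturated 16-bit RGB colors for the rendered decorations on captured
#' images: target-contour blue, axis orange, grid green, pointing-mark red.
#' No grayscale pixel (r = g = b) can fall within the default tolerance of
#' any entry.
#'
#' @return A 4 x 3 numeric matrix of RGB rows.
#' @export
default_overlay_palette <- function() {
  rbind(contour = c(0, 0, 65535),
        axis    = c(65535, 38000, 0),
        grid    = c(0, 52000, 0),
        mark    = c(65535, 0, 0))
}

#' Gaussian-weight sigma from the window size
#'
#' @param N Calculation-window side in pixels (>= 1).
#' @param s_sigma Width fraction (> 0).
#' @return `N * s_sigma`, the Gaussian sigma in pixels.
#' @export
compute_sigma <- function(N, s_sigma) {
  stopifnot(is.numeric(N), N >= 1, is.numeric(s_sigma), s_sigma > 0)
  N * s_sigma
}

#' Isocenter-centered Gaussian weight
#'
#' Weight of a window pixel `p` under candidate offset `d`:
#' `exp(-((x_ic - x - dx)^2 + (y_ic - y - dy)^2) / (2 sigma^2))`, i.e. a
#' Gaussian in the distance from the displaced pixel to the isocenter, so
#' importance concentrates near the planned beam axis.
#'
#' @param p Pixel position `(x, y)` (vector or 2-column matrix).
#' @param d Candidate offset `(dx, dy)`.
#' @param ic Isocenter position `(x, y)`.
#' @param sigma Gaussian width in pixels (> 0).
#' @return Weight(s) in (0, 1].
#' @export
gaussian_weight <- function(p, d, ic, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number",
          class = "couchmatch_input_error")
  }
  p <- if (is.null(dim(p))) matrix(p, ncol = 2) else p
  exp(-((ic[1] - p[, 1] - d[1])^2 + (ic[2] - p[, 2] - d[2])^2) /
        (2 * sigma^2))
}

# Calculation-window bounds (1-based, inclusive) centered on the isocenter.
#' @noRd
.match_window <- function(dim_hw, ic, config) {
  s_eff <- min(config$s %||% min(dim_hw), min(dim_hw))
  N <- max(3, round(s_eff * config$sn))
  x0 <- max(1, round(ic[1] - N / 2)); x1 <- min(dim_hw[2], x0 + N - 1)
  y0 <- max(1, round(ic[2] - N / 2)); y1 <- min(dim_hw[1], y0 + N - 1)
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1, N = N)
}

# Shared entry to the compiled scan.  dr/drr: radiographs or matrices.
#' @noRd
.zncc_scan <- function(dr, drr, dx, dy, valid = NULL, config = match_config()) {
  dr_px <- .px_matrix(dr, "DR")
  drr_px <- .px_matrix(drr, "DRR")
  if (!identical(dim(dr_px), dim(drr_px))) {
    abort("DR and DRR must have identical dimensions",
          class = "couchmatch_input_error")
  }
  if (is_radiograph(dr) && is_radiograph(drr) &&
      !isTRUE(all.equal(dr$pixel_spacing_mm, drr$pixel_spacing_mm))) {
    abort("DR and DRR pixel spacings differ", class = "couchmatch_input_error")
  }
  ic <- if (is_radiograph(dr)) dr$isocenter_px else (rev(dim(dr_px)) + 1) / 2
  if (is.null(valid)) valid <- matrix(TRUE, nrow(dr_px), ncol(dr_px))
  win <- .match_window(dim(dr_px), ic, config)
  sigma <- if (config$weight == "uniform") -1 else
    compute_sigma(win$N, config$s_sigma)
  res <- zncc_scan_cpp(drr_px, dr_px, valid, as.numeric(dx), as.numeric(dy),
                       ic[1] - 1, ic[2] - 1, sigma,
                       win$x0 - 1L, win$x1 - 1L, win$y0 - 1L, win$y1 - 1L,
                       config$min_valid_px)
  list(R = res[, 1], n = res[, 2], window = win, ic = ic)
}

#' Weighted zero-mean normalized cross-correlation at one offset
#'
#' Correlates the DR calculation window against the DRR displaced by `d`,
#' after multiplying both by the isocenter-centered Gaussian weight evaluated
#' at the displaced positions.  Collimated and out-of-bounds pixels are
#' excluded from all sums.  Returns `NA` (the "undefined correlation"
#' sentinel) when fewer than `config$min_valid_px` pixels contribute or
#' either weighted patch has zero variance; callers skip such candidates.
#'
#' @param dr,drr Single-channel `radiograph`s (or matrices) of equal size;
#'   `dr` is the treatment-room image, `drr` the planning reference.
#' @param d Candidate offset `(dx, dy)` in pixels (may be fractional).
#' @param valid Logical matrix of usable DR pixels (default: all).
#' @param config A [match_config()].
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
weighted_zncc <- function(dr, drr, d, valid = NULL, config = match_config()) {
  .zncc_scan(dr, drr, d[1], d[2], valid, config)$R[1]
}

#' Correlation surface over the integer search grid
#'
#' Evaluates the weighted ZNCC at every integer offset in the centered
#' `[-M, M] x [-M, M]` search grid.
#'
#' @inheritParams weighted_zncc
#' @return An object of class `correlation_surface`: list with `R` (matrix,
#'   rows indexed by dy, columns by dx), `dx`, `dy` (offset axes), and `n`
#'   (contributing-pixel counts).
#' @export
correlation_surface <- function(dr, drr, valid = NULL,
                                config = match_config()) {
  offs <- seq(-config$M, config$M)
  grid <- expand.grid(dx = offs, dy = offs)
  sc <- .zncc_scan(dr, drr, grid$dx, grid$dy, valid, config)
  if (all(is.na(sc$R))) {
    abort("correlation undefined at every candidate offset",
          class = "couchmatch_match_error")
  }
  k <- length(offs)
  structure(
    list(R = matrix(sc$R, k, k, byrow = TRUE,
                    dimnames = list(dy = offs, dx = offs)),
         n = matrix(sc$n, k, k, byrow = TRUE),
         dx = offs, dy = offs, window = sc$window, ic = sc$ic),
    class = "correlation_surface"
  )
}

# deterministic argmax: highest R, then smallest offset norm, then row-major
#' @noRd
.pick_peak <- function(R, dx, dy) {
  rmax <- max(R, na.rm = TRUE)
  idx <- which(!is.na(R) & R == rmax)
  if (length(idx) > 1) {
    nrm <- dx[idx]^2 + dy[idx]^2
    idx <- idx[nrm == min(nrm)]
    idx <- idx[1]  # candidates are generated in row-major order
  }
  idx
}

#' Best-matching displacement with subpixel refinement
#'
#' Finds the integer argmax of the correlation surface, then re-evaluates the
#' correlation on a fractional grid of pitch `config$subpixel_step_px` within
#' +/- 1 px of the peak, sampling the DRR by bilinear interpolation.  Ties are
#' broken toward the smallest offset norm, then row-major order.  The
#' reported offset is the displacement applied to the DRR that best overlays
#' it on the DR, so a couch correction equals the negated report.
#'
#' @inheritParams weighted_zncc
#' @return An object of class `displacement`: list with `dx_px`, `dy_px`
#'   (signed, possibly fractional), `peak_correlation`, `n_valid`, `view`,
#'   `border_peak` (`TRUE` when the integer peak lies on the search-grid
#'   border, suggesting the true displacement exceeds the search radius) and
#'   `pixel_spacing_mm`.
#' @export
best_match <- function(dr, drr, valid = NULL, config = match_config()) {
  M <- config$M
  offs <- seq(-M, M)
  grid <- expand.grid(dx = offs, dy = offs)  # row-major in dy, dx
  grid <- grid[order(grid$dy, grid$dx), ]
  sc <- .zncc_scan(dr, drr, grid$dx, grid$dy, valid, config)
  if (all(is.na(sc$R))) {
    abort("correlation undefined at every candidate offset",
          class = "couchmatch_match_error")
  }
  i0 <- .pick_peak(sc$R, grid$dx, grid$dy)
  dx0 <- grid$dx[i0]; dy0 <- grid$dy[i0]
  border <- abs(dx0) == M || abs(dy0) == M

  gg <- seq(0, 1, by = config$subpixel_step_px)
  rel <- sort(unique(c(-gg, gg)))
  fg <- expand.grid(dx = dx0 + rel, dy = dy0 + rel)
  fg <- fg[order(fg$dy, fg$dx), ]
  fs <- .zncc_scan(dr, drr, fg$dx, fg$dy, valid, config)
  if (all(is.na(fs$R))) {
    best <- list(dx = dx0, dy = dy0, R = sc$R[i0], n = sc$n[i0])
  } else {
    j <- .pick_peak(fs$R, fg$dx, fg$dy)
    best <- list(dx = fg$dx[j], dy = fg$dy[j], R = fs$R[j], n = fs$n[j])
  }

  structure(
    list(dx_px = best$dx, dy_px = best$dy,
         peak_correlation = best$R, n_valid = as.integer(best$n),
         view = if (is_radiograph(dr)) dr$view else NA_character_,
         border_peak = border,
         pixel_spacing_mm = if (is_radiograph(dr)) dr$pixel_spacing_mm
                            else config$pixel_spacing_mm),
    class = "displacement"
  )
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf(
    "<displacement> %s: dx = %+.3f px, dy = %+.3f px (R = %.4f, n = %d)%s\n",
    x$view, x$dx_px, x$dy_px, x$peak_correlation, x$n_valid,
    if (isTRUE(x$border_peak)) " [peak on search border]" else ""))
  invisible(x)
}

#' @rdname best_match
#' @param x A `displacement`.
#' @param ... Unused.
#' @export
tidy.displacement <- function(x, ...) {
  tibble::tibble(view = x$view, dx_px = x$dx_px, dy_px = x$dy_px,
                 dx_mm = x$dx_px * x$pixel_spacing_mm,
                 dy_mm = x$dy_px * x$pixel_spacing_mm,
                 peak_correlation = x$peak_correlation,
                 n_valid = x$n_valid, border_peak = x$border_peak)
}

#' Plot a correlation surface
#'
#' @param object A `correlation_surface`.
#' @param ... Unused.
#' @return A ggplot raster of R over candidate offsets.
#' @export
autoplot.correlation_surface <- function(object, ...) {
  df <- tidyr::expand_grid(dy = object$dy, dx = object$dx)
  df$R <- as.vector(t(object$R))  # row-major over (dy, dx)
  ggplot2::ggplot(df, ggplot2::aes(.data$dx, .data$dy, fill = .data$R)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "candidate dx (px)", y = "candidate dy (px)",
                  fill = "R")
}
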