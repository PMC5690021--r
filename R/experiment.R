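#' Register one DR/DRR pair per view
#'
#' Preprocesses each treatment-room image (overlay inpainting, collimator
#' masking) and runs [best_match()] against its planning reference.  Color
#' references are inpainted and collapsed to gray; reference images are not
#' collimator-masked (the valid mask belongs to the DR side).
#'
#' @param dr_frontal,dr_lateral Captured `radiograph`s (gray or color).
#' @param drr_frontal,drr_lateral Reference `radiograph`s.
#' @param config A [match_config()].
#' @return List with `frontal` and `lateral` [best_match()] displacements
#'   and the per-view `preprocess` results.
#' @export
run_registration <- function(dr_frontal, dr_lateral, drr_frontal, drr_lateral,
                             config = match_config()) {
  one <- function(dr, drr) {
    pre <- preprocess_captured(dr, config)
    ref <- if (drr$channels == 3L) {
      mk <- detect_overlay_mask(drr, config$overlay_palette,
                                config$overlay_tolerance)
      inpaint_overlay(to_gray(drr), mk)
    } else drr
    list(pre = pre, disp = best_match(pre$image, ref, pre$valid, config))
  }
  f <- one(dr_frontal, drr_frontal)
  l <- one(dr_lateral, drr_lateral)
  list(frontal = f$disp, lateral = l$disp,
       preprocess = list(frontal = f$pre, lateral = l$pre))
}

#' Run the synthetic couch-shift accuracy experiment
#'
#' Renders a phantom DRR per view, acquires a simulated DR at the origin and
#' at each couch-pattern position, runs the full preprocessing + matching
#' chain on every image, and evaluates couch-space errors against the
#' origin-position reference registration.
#'
#' @param spec A [phantom_spec()].
#' @param config A [match_config()].
#' @param pattern Couch-shift tibble; default [couch_pattern()].
#' @return Object of class `couch_experiment`: list with `displacements`
#'   (per position/view: applied and recovered offsets), `errors`
#'   (Table-style per-pattern couch errors), `summary`
#'   ([aggregate_pattern()] row), `correlation` (Pearson r between recovered
#'   and applied components pooled over all positions and views), plus the
#'   `spec` and `config` used.
#' @export
run_couch_experiment <- function(spec = phantom_spec(),
                                 config = match_config(),
                                 pattern = couch_pattern()) {
  stopifnot(inherits(spec, "phantom_spec"))
  positions <- dplyr::bind_rows(
    tibble::tibble(pattern = 0L, lat_mm = 0, vert_mm = 0, long_mm = 0),
    pattern
  )
  drrs <- list(frontal = render_drr(spec, "frontal"),
               lateral = render_drr(spec, "lateral"))

  disp <- purrr::pmap_dfr(positions, function(pattern, lat_mm, vert_mm,
                                              long_mm) {
    shift <- c(lat_mm, vert_mm, long_mm)
    purrr::map_dfr(c("frontal", "lateral"), function(vw) {
      rd <- render_dr(drrs[[vw]], shift, spec)
      pre <- preprocess_captured(rd$image, config)
      d <- best_match(pre$image, drrs[[vw]], pre$valid, config)
      tibble::tibble(
        pattern = pattern, view = vw,
        applied_dx_px = rd$truth$offset_px[1],
        applied_dy_px = rd$truth$offset_px[2],
        dx_px = d$dx_px, dy_px = d$dy_px,
        est_dx_px = -d$dx_px, est_dy_px = -d$dy_px,
        peak_correlation = d$peak_correlation,
        n_valid = d$n_valid, border_peak = d$border_peak
      )
    })
  })

  get_disp <- function(pat, vw) {
    r <- disp[disp$pattern == pat & disp$view == vw, ]
    list(dx_px = r$dx_px, dy_px = r$dy_px)
  }
  ref <- list(frontal = get_disp(0L, "frontal"),
              lateral = get_disp(0L, "lateral"))
  errors <- purrr::pmap_dfr(pattern, function(pattern, lat_mm, vert_mm,
                                              long_mm) {
    meas <- list(frontal = get_disp(pattern, "frontal"),
                 lateral = get_disp(pattern, "lateral"))
    e <- couch_error(meas, ref, c(lat_mm, vert_mm, long_mm),
                     pixel_spacing_mm = spec$pixel_spacing_mm)
    dplyr::bind_cols(tibble::tibble(pattern = pattern, m_lat = lat_mm,
                                    m_vert = vert_mm, m_long = long_mm), e)
  })

  correlation <- correlate_with_reference(
    c(disp$est_dx_px, disp$est_dy_px),
    c(disp$applied_dx_px, disp$applied_dy_px)
  )

  structure(
    list(displacements = disp, errors = errors,
         summary = aggregate_pattern(errors), correlation = correlation,
         spec = spec, config = config),
    class = "couch_experiment"
  )
}

#' @export
print.couch_experiment <- function(x, ...) {
  s <- x$summary
  cat("<couch_experiment>\n")
  cat(sprintf("  %d patterns, %d registrations\n",
              nrow(x$errors), nrow(x$displacements)))
  cat(sprintf("  RMSE %.2f +/- %.2f mm; axis means (lat/vert/long) %+.2f / %+.2f / %+.2f mm\n",
              s$mean_rmse, s$sd_rmse, s$mean_lat, s$mean_vert, s$mean_long))
  cat(sprintf("  recovered-vs-applied Pearson r = %.4f\n", x$correlation))
  invisible(x)
}

#' @rdname run_couch_experiment
#' @param x A `couch_experiment`.
#' @param ... Unused.
#' @export
tidy.couch_experiment <- function(x, ...) x$errors

#' @rdname run_couch_experiment
#' @export
glance.couch_experiment <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(pearson_r = x$correlation,
                                  n_registrations = nrow(x$displacements)))
}

#' @rdname run_couch_experiment
#' @param object A `couch_experiment`.
#' @export
autoplot.couch_experiment <- function(object, ...) {
  d <- object$displacements
  sp <- object$spec$pixel_spacing_mm
  df <- dplyr::bind_rows(
    tibble::tibble(view = d$view, axis = "x",
                   applied = d$applied_dx_px * sp, recovered = d$est_dx_px * sp),
    tibble::tibble(view = d$view, axis = "y",
                   applied = d$applied_dy_px * sp, recovered = d$est_dy_px * sp)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$applied, .data$recovered,
                                   color = .data$view,
                                   shape = .data$axis)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "applied displacement (mm)",
                  y = "recovered displacement (mm)")
}

#' Evaluate a table of displacements against couch shifts
#'
#' Tabular form of the accuracy evaluation: one row per pattern with the
#' applied couch shift and the per-view pixel displacements; the row whose
#' `pattern` equals `ref_pattern` supplies the reference registration.
#'
#' @param df Tibble with columns `pattern`, `m_lat`, `m_vert`, `m_long`
#'   (mm), `dx_f`, `dy_f`, `dx_l`, `dy_l` (px).
#' @param pixel_spacing_mm mm per pixel.
#' @param ref_pattern Pattern label of the reference row (default 0).
#' @return Tibble of per-pattern couch errors (non-reference rows), with the
#'   [aggregate_pattern()] summary attached as attribute `"summary"`.
#' @export
evaluate_displacements <- function(df, pixel_spacing_mm = 0.446,
                                   ref_pattern = 0) {
  need <- c("pattern", "m_lat", "m_vert", "m_long",
            "dx_f", "dy_f", "dx_l", "dy_l")
  if (!all(need %in% names(df))) {
    abort(paste("missing columns:",
                paste(setdiff(need, names(df)), collapse = ", ")),
          class = "couchmatch_input_error")
  }
  refrow <- df[df$pattern == ref_pattern, ]
  if (nrow(refrow) != 1) {
    abort("exactly one reference row (pattern == ref_pattern) is required",
          class = "couchmatch_input_error")
  }
  ref <- list(frontal = c(refrow$dx_f, refrow$dy_f),
              lateral = c(refrow$dx_l, refrow$dy_l))
  rows <- df[df$pattern != ref_pattern, ]
  out <- purrr::pmap_dfr(rows, function(pattern, m_lat, m_vert, m_long,
                                        dx_f, dy_f, dx_l, dy_l, ...) {
    e <- couch_error(list(frontal = c(dx_f, dy_f), lateral = c(dx_l, dy_l)),
                     ref, c(m_lat, m_vert, m_long),
                     pixel_spacing_mm = pixel_spacing_mm)
    dplyr::bind_cols(tibble::tibble(pattern = pattern, m_lat = m_lat,
                                    m_vert = m_vert, m_long = m_long), e)
  })
  attr(out, "summary") <- aggregate_pattern(out)
  out
}
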