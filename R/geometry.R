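#' @noRd
.disp_px <- function(d, what) {
  if (inherits(d, "displacement") || is.list(d)) {
    c(d$dx_px, d$dy_px)
  } else if (is.numeric(d) && length(d) == 2) {
    d
  } else {
    abort(paste0(what, " must be a displacement or (dx, dy) pair"),
          class = "couchmatch_input_error")
  }
}

#' @noRd
.shift_mm <- function(shift) {
  if (is.data.frame(shift)) {
    c(shift$lat_mm[1], shift$vert_mm[1], shift$long_mm[1])
  } else if (is.numeric(shift) && length(shift) == 3) {
    unname(shift)
  } else {
    abort("`couch` must be (lat, vert, long) mm or a couch-pattern row",
          class = "couchmatch_input_error")
  }
}

#' Root-mean-square of the three axis errors
#'
#' `sqrt((e_lat^2 + e_vert^2 + e_long^2) / 3)`; invariant to sign flips and
#' permutations of the axes.  Vectorized.
#'
#' @param e_lat,e_vert,e_long Signed per-axis errors in mm.
#' @return RMSE in mm.
#' @export
rmse_of_axes <- function(e_lat, e_vert, e_long) {
  stopifnot(is.finite(e_lat), is.finite(e_vert), is.finite(e_long))
  sqrt((e_lat^2 + e_vert^2 + e_long^2) / 3)
}

#' Couch-space positioning error from paired-view displacements
#'
#' Maps frontal/lateral image displacements to couch-axis errors against the
#' zero-position reference registration: the frontal x-axis carries the
#' lateral couch axis, the lateral x-axis the vertical axis, and the
#' longitudinal error averages the two views' y-differences:
#' \deqn{E_{lat} = m_{lat} - (\Delta x_{F,ref} - \Delta x_{F,i})}
#' \deqn{E_{vert} = m_{vert} - (\Delta x_{L,ref} - \Delta x_{L,i})}
#' \deqn{E_{long} = m_{long} - \tfrac{1}{2}\left[(\Delta y_{F,ref} -
#'   \Delta y_{F,i}) + (\Delta y_{L,ref} - \Delta y_{L,i})\right]}
#' with all displacements converted from pixels to mm first.
#'
#' @param meas,ref Lists with elements `frontal` and `lateral`, each a
#'   [best_match()] displacement (or a `(dx, dy)` pixel pair); `ref` is the
#'   registration at the reference (zero) couch position.
#' @param couch Applied couch shift `(lat, vert, long)` in mm, or a
#'   [couch_pattern()] row.
#' @param pixel_spacing_mm mm per pixel, shared by both views; defaults to
#'   the spacing carried by the displacements, which must agree.
#' @return One-row tibble: `e_lat_mm`, `e_vert_mm`, `e_long_mm`, `rmse_mm`.
#' @export
couch_error <- function(meas, ref, couch = c(0, 0, 0),
                        pixel_spacing_mm = NULL) {
  sp <- pixel_spacing_mm
  if (is.null(sp)) {
    sps <- unlist(lapply(c(meas, ref), function(d)
      if (is.list(d)) d$pixel_spacing_mm else NULL))
    if (length(sps)) {
      if (diff(range(sps)) > 1e-9) {
        abort("pixel spacing differs between views",
              class = "couchmatch_input_error")
      }
      sp <- sps[1]
    } else {
      abort("`pixel_spacing_mm` is required", class = "couchmatch_input_error")
    }
  }
  mF <- .disp_px(meas$frontal, "meas$frontal")
  mL <- .disp_px(meas$lateral, "meas$lateral")
  rF <- .disp_px(ref$frontal, "ref$frontal")
  rL <- .disp_px(ref$lateral, "ref$lateral")
  m <- .shift_mm(couch)
  e_lat  <- m[1] - (rF[1] - mF[1]) * sp
  e_vert <- m[2] - (rL[1] - mL[1]) * sp
  e_long <- m[3] - ((rF[2] - mF[2]) + (rL[2] - mL[2])) / 2 * sp
  tibble::tibble(e_lat_mm = e_lat, e_vert_mm = e_vert, e_long_mm = e_long,
                 rmse_mm = rmse_of_axes(e_lat, e_vert, e_long))
}

#' @noRd
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate per-pattern positioning errors
#'
#' Per-axis means and population standard deviations (divisor n), plus the
#' mean and population SD of the per-pattern RMSEs — the conventions of the
#' phantom accuracy experiment's summary row.
#'
#' @param errors Tibble with columns `e_lat_mm`, `e_vert_mm`, `e_long_mm`
#'   and optionally `rmse_mm` (recomputed when absent).
#' @return One-row tibble: `n`, `mean_lat`, `sd_lat`, `mean_vert`, `sd_vert`,
#'   `mean_long`, `sd_long`, `mean_rmse`, `sd_rmse` (all mm).
#' @export
aggregate_pattern <- function(errors) {
  if (!is.data.frame(errors) || nrow(errors) == 0) {
    abort("`errors` must be a non-empty data frame",
          class = "couchmatch_input_error")
  }
  rmse <- errors[["rmse_mm"]] %||%
    rmse_of_axes(errors$e_lat_mm, errors$e_vert_mm, errors$e_long_mm)
  tibble::tibble(
    n = nrow(errors),
    mean_lat = mean(errors$e_lat_mm),  sd_lat = .pop_sd(errors$e_lat_mm),
    mean_vert = mean(errors$e_vert_mm), sd_vert = .pop_sd(errors$e_vert_mm),
    mean_long = mean(errors$e_long_mm), sd_long = .pop_sd(errors$e_long_mm),
    mean_rmse = mean(rmse), sd_rmse = .pop_sd(rmse)
  )
}

#' Pearson correlation of calculated vs reference displacement components
#'
#' @param calc,ref Equal-length numeric vectors (n >= 3) of pooled
#'   displacement components.
#' @return The Pearson product-moment correlation.
#' @export
correlate_with_reference <- function(calc, ref) {
  if (length(calc) != length(ref) || length(calc) < 3) {
    abort("need equal-length vectors with at least 3 points",
          class = "couchmatch_input_error")
  }
  if (stats::var(calc) == 0 || stats::var(ref) == 0) {
    abort("zero variance; correlation undefined",
          class = "couchmatch_input_error")
  }
  stats::cor(calc, ref)
}

#' Screen positioning errors against a tolerance
#'
#' Flags each case whose RMSE, or absolute per-axis error, exceeds
#' `limit_mm` — the clinical action level at which patient setup is repeated.
#'
#' @param errors Tibble as for [aggregate_pattern()].
#' @param limit_mm Action level in mm (default 2).
#' @return List with `cases` (per-case logical flags `lat_over`, `vert_over`,
#'   `long_over`, `rmse_over`) and `summary` (counts under/over per metric).
#' @export
screen_threshold <- function(errors, limit_mm = 2) {
  if (!is.data.frame(errors) || nrow(errors) == 0) {
    abort("`errors` must be a non-empty data frame",
          class = "couchmatch_input_error")
  }
  rmse <- errors[["rmse_mm"]] %||%
    rmse_of_axes(errors$e_lat_mm, errors$e_vert_mm, errors$e_long_mm)
  cases <- tibble::tibble(
    case = seq_len(nrow(errors)),
    lat_over = abs(errors$e_lat_mm) > limit_mm,
    vert_over = abs(errors$e_vert_mm) > limit_mm,
    long_over = abs(errors$e_long_mm) > limit_mm,
    rmse_over = rmse > limit_mm
  )
  summary <- tibble::tibble(
    metric = c("lat", "vert", "long", "rmse"),
    n_over = c(sum(cases$lat_over), sum(cases$vert_over),
               sum(cases$long_over), sum(cases$rmse_over)),
    n_under = nrow(cases) - n_over
  )
  list(cases = cases, summary = summary)
}

#' Published phantom-accuracy reference table
#'
#' The per-pattern couch setup shifts, per-axis calculation errors and RMSEs
#' reported for the pelvic-phantom accuracy experiment (values as printed, 2
#' decimal places).  Distributed so the summary arithmetic — per-pattern
#' RMSE, per-axis means and the mean +/- SD of the RMSEs — can be validated
#' against published numbers.
#'
#' @return Tibble with columns `pattern`, `m_lat`, `m_vert`, `m_long`
#'   (setup, mm), `e_lat_mm`, `e_vert_mm`, `e_long_mm` (calculation errors,
#'   mm) and `rmse_mm` (printed RMSE, mm).
#' @export
phantom_accuracy_table <- function() {
  tibble::tribble(
    ~pattern, ~m_lat, ~m_vert, ~m_long, ~e_lat_mm, ~e_vert_mm, ~e_long_mm, ~rmse_mm,
    1L,   0.5,   0.5,   0.5,  0.01, -0.03, -0.25, 0.14,
    2L,   1.0,   1.0,   1.0, -0.04,  0.08, -0.26, 0.16,
    3L,   2.0,   2.0,   2.0, -0.14, -0.19, -0.36, 0.25,
    4L,   4.0,   4.0,   4.0,  0.08,  0.04, -0.40, 0.24,
    5L,  10.0,  10.0,  10.0,  0.33, -0.15, -0.37, 0.30,
    6L,  -0.5,  -0.5,  -0.5,  0.12,  0.08, -0.32, 0.20,
    7L,  -1.0,  -1.0,  -1.0, -0.00,  0.13, -0.31, 0.19,
    8L,  -2.0,  -2.0,  -2.0, -0.17, -0.21, -0.38, 0.27,
    9L,  -4.0,  -4.0,  -4.0,  0.05,  0.00, -0.39, 0.23,
    10L, -10.0, -10.0, -10.0, -0.20,  0.20, -0.46, 0.31
  )
}
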