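#' Phantom specification for the synthetic accuracy experiment
#'
#' Describes a procedural pelvic-like phantom and the imaging-chain
#' degradations applied when turning its DRR into a treatment-room DR:
#' intensity gain/offset, additive Gaussian noise, collimated border bands
#' with a sharp field edge, and colored overlay annotations.  The defaults
#' are the study conditions of the couch-shift accuracy experiment; the
#' noise level was calibrated once so that default-configuration recovery
#' error is comparable to what the method achieves on a physical phantom.
#'
#' @param size_px Image side length (>= 64); default 480.
#' @param pixel_spacing_mm mm per pixel; default 0.446.
#' @param noise_sd Additive Gaussian noise SD on the 16-bit scale.
#' @param contrast_gain,contrast_offset DR intensity transform
#'   `I -> gain * I + offset`.
#' @param lateral_contrast Contrast compression factor (< 1) applied to the
#'   lateral view, whose longer transmission path lowers contrast.
#' @param collimation_px Named blocked border widths
#'   `c(left, right, top, bottom)` in pixels.
#' @param overlays Paint colored annotations on the DR (default TRUE).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size_px = 480, pixel_spacing_mm = 0.446,
                         noise_sd = 10000, contrast_gain = 1.05,
                         contrast_offset = 300, lateral_contrast = 0.7,
                         collimation_px = c(left = 40, right = 40,
                                            top = 32, bottom = 32),
                         overlays = TRUE, seed = 1L) {
  stopifnot(size_px >= 64, pixel_spacing_mm > 0, noise_sd >= 0,
            contrast_gain > 0, lateral_contrast > 0,
            all(collimation_px >= 0))
  collimation_px <- rep_len(collimation_px, 4)
  names(collimation_px) <- c("left", "right", "top", "bottom")
  if (size_px - collimation_px["left"] - collimation_px["right"] < 64 ||
      size_px - collimation_px["top"] - collimation_px["bottom"] < 64) {
    abort("collimation margins leave too little usable image",
          class = "couchmatch_input_error")
  }
  structure(
    list(size_px = as.integer(size_px), pixel_spacing_mm = pixel_spacing_mm,
         noise_sd = noise_sd, contrast_gain = contrast_gain,
         contrast_offset = contrast_offset,
         lateral_contrast = lateral_contrast,
         collimation_px = collimation_px, overlays = overlays,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# soft-edged primitives over a normalized [0,1]^2 canvas
#' @noRd
.feature_field <- function(S, features) {
  x <- matrix(seq_len(S) / S, S, S, byrow = TRUE)
  y <- matrix(seq_len(S) / S, S, S)
  img <- matrix(0, S, S)
  sig <- function(z, s) 1 / (1 + exp(-z / s))
  for (f in features) {
    soft <- f$softness %||% 0.02
    if (f$type == "ellipse") {
      r <- sqrt(((x - f$cx) / f$ax)^2 + ((y - f$cy) / f$ay)^2)
      img <- img + f$intensity * sig(1 - r, soft)
    } else if (f$type == "ring") {
      r <- sqrt(((x - f$cx) / f$ax)^2 + ((y - f$cy) / f$ay)^2)
      img <- img + f$intensity * sig(f$width - abs(r - 1), soft)
    } else if (f$type == "bar") {
      img <- img + f$intensity *
        sig(x - f$x0, soft) * sig(f$x1 - x, soft) *
        sig(y - f$y0, soft) * sig(f$y1 - y, soft)
    }
  }
  img
}

#' @noRd
.default_features <- function(view) {
  if (view == "frontal") {
    list(
      list(type = "ring", cx = 0.50, cy = 0.55, ax = 0.33, ay = 0.24,
           width = 0.16, intensity = 14000, softness = 0.03),
      list(type = "ellipse", cx = 0.30, cy = 0.72, ax = 0.075, ay = 0.075,
           intensity = 16000, softness = 0.025),
      list(type = "ellipse", cx = 0.70, cy = 0.72, ax = 0.075, ay = 0.075,
           intensity = 16000, softness = 0.025),
      list(type = "ellipse", cx = 0.36, cy = 0.40, ax = 0.13, ay = 0.16,
           intensity = 9000, softness = 0.04),
      list(type = "ellipse", cx = 0.64, cy = 0.40, ax = 0.13, ay = 0.16,
           intensity = 9000, softness = 0.04),
      list(type = "bar", x0 = 0.46, x1 = 0.54, y0 = 0.12, y1 = 0.52,
           intensity = 15000, softness = 0.02)
    )
  } else {
    list(
      list(type = "ellipse", cx = 0.50, cy = 0.68, ax = 0.10, ay = 0.10,
           intensity = 20000, softness = 0.025),
      list(type = "ring", cx = 0.55, cy = 0.50, ax = 0.26, ay = 0.30,
           width = 0.14, intensity = 12000, softness = 0.035),
      list(type = "bar", x0 = 0.30, x1 = 0.42, y0 = 0.10, y1 = 0.60,
           intensity = 16000, softness = 0.02),
      list(type = "bar", x0 = 0.55, x1 = 0.80, y0 = 0.30, y1 = 0.42,
           intensity = 9000, softness = 0.03)
    )
  }
}

#' Render a phantom DRR
#'
#' Deterministic, noise-free projection of soft-edged bone-like structures
#' over a graded background.  The lateral view uses its own anatomy layout
#' and is contrast-compressed by `spec$lateral_contrast` around a mid-gray
#' pivot, mimicking the longer lateral transmission path.
#'
#' @param spec A [phantom_spec()].
#' @param view `"frontal"` or `"lateral"`.
#' @param features Optional feature list overriding the built-in anatomy;
#'   `list()` renders the bare background.
#' @return A single-channel `radiograph`.
#' @export
render_drr <- function(spec, view = c("frontal", "lateral"),
                       features = NULL) {
  view <- match.arg(view)
  S <- spec$size_px
  x <- matrix(seq_len(S) / S, S, S, byrow = TRUE)
  y <- matrix(seq_len(S) / S, S, S)
  img <- 11000 + 3000 * y + 800 * x
  img <- img + .feature_field(S, features %||% .default_features(view))
  if (view == "lateral") {
    img <- 13000 + (img - 13000) * spec$lateral_contrast
  }
  img <- pmin(pmax(img, 0), 65535)
  radiograph(img, view = view, pixel_spacing_mm = spec$pixel_spacing_mm)
}

# sample A at (x - vx, y - vy), bilinear, edge-replicated
#' @noRd
.bilinear_shift <- function(A, vx, vy) {
  H <- nrow(A); W <- ncol(A)
  xs <- seq_len(W) - vx; ys <- seq_len(H) - vy
  x0 <- floor(xs); fx <- xs - x0
  y0 <- floor(ys); fy <- ys - y0
  cx0 <- pmin(pmax(x0, 1), W); cx1 <- pmin(pmax(x0 + 1, 1), W)
  cy0 <- pmin(pmax(y0, 1), H); cy1 <- pmin(pmax(y0 + 1, 1), H)
  FX <- matrix(fx, H, W, byrow = TRUE); FY <- matrix(fy, H, W)
  (1 - FY) * ((1 - FX) * A[cy0, cx0] + FX * A[cy0, cx1]) +
       FY  * ((1 - FX) * A[cy1, cx0] + FX * A[cy1, cx1])
}

#' @noRd
.view_offset_px <- function(shift_mm, view, spacing) {
  if (view == "frontal") {
    c(shift_mm[1] / spacing, shift_mm[3] / spacing)
  } else {
    c(shift_mm[2] / spacing, shift_mm[3] / spacing)
  }
}

#' Simulate a treatment-room DR from a phantom DRR
#'
#' Translates the DRR by the view-mapped couch shift (frontal x carries the
#' lateral axis, lateral x the vertical axis, both y the longitudinal axis;
#' a positive couch shift displaces the anatomy by the same amount in image
#' coordinates), applies the intensity gain/offset, adds Gaussian noise,
#' zeroes the collimated border bands (leaving a sharp field edge), and
#' paints the overlay annotations in the standard palette.  Everything the
#' generator did is recorded as ground truth.
#'
#' @param drr A `radiograph` from [render_drr()].
#' @param shift Couch shift `(lat, vert, long)` in mm or a [couch_pattern()]
#'   row.
#' @param spec The [phantom_spec()] used for the DRR.
#' @return List with `image` (a captured `radiograph`, color when
#'   `spec$overlays`) and `truth` (class `ground_truth`: `applied_shift_mm`,
#'   `offset_px` = the view-mapped `(vx, vy)`, `view`, `pixel_spacing_mm`,
#'   `overlay_mask`, `blocked_mask`).
#' @export
render_dr <- function(drr, shift, spec) {
  stopifnot(is_radiograph(drr), inherits(spec, "phantom_spec"))
  m <- .shift_mm(shift)
  S <- spec$size_px
  v <- .view_offset_px(m, drr$view, spec$pixel_spacing_mm)
  if (any(abs(v) >= S / 4)) {
    abort("couch shift leaves too little usable image for matching",
          class = "couchmatch_input_error")
  }
  B <- if (all(v == 0)) drr$pixels else .bilinear_shift(drr$pixels, v[1], v[2])
  B <- B * spec$contrast_gain + spec$contrast_offset
  if (spec$noise_sd > 0) {
    seed_use <- (spec$seed * 100003 +
                   (round(v[1] * 100) * 251 + round(v[2] * 100) * 641) %%
                   1000003) %% 2147483647
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed_use)
    B <- B + matrix(rnorm(length(B), sd = spec$noise_sd), nrow(B))
  }
  B <- pmin(pmax(B, 0), 65535)

  cp <- spec$collimation_px
  blocked <- matrix(FALSE, S, S)
  if (cp["left"] > 0)   blocked[, seq_len(cp["left"])] <- TRUE
  if (cp["right"] > 0)  blocked[, (S - cp["right"] + 1):S] <- TRUE
  if (cp["top"] > 0)    blocked[seq_len(cp["top"]), ] <- TRUE
  if (cp["bottom"] > 0) blocked[(S - cp["bottom"] + 1):S, ] <- TRUE
  B[blocked] <- 0

  overlay_mask <- matrix(FALSE, S, S)
  if (spec$overlays) {
    om <- .overlay_layout(S, cp, drr$isocenter_px)
    rgb <- array(B, dim = c(S, S, 3))
    pal <- default_overlay_palette()
    for (i in seq_along(om)) {
      mk <- om[[i]]
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[mk] <- pal[i, ch]
        rgb[, , ch] <- plane
      }
      overlay_mask <- overlay_mask | mk
    }
    image <- radiograph(rgb, view = drr$view,
                        pixel_spacing_mm = spec$pixel_spacing_mm,
                        isocenter_px = drr$isocenter_px)
  } else {
    image <- radiograph(B, view = drr$view,
                        pixel_spacing_mm = spec$pixel_spacing_mm,
                        isocenter_px = drr$isocenter_px)
  }
  truth <- structure(
    list(applied_shift_mm = m, offset_px = v, view = drr$view,
         pixel_spacing_mm = spec$pixel_spacing_mm,
         overlay_mask = overlay_mask, blocked_mask = blocked),
    class = "ground_truth"
  )
  list(image = image, truth = truth)
}

# overlay shapes: contour ring, axes through the isocenter, grid dots,
# pointing marks; confined to the unblocked interior with a small guard so
# the field edge stays sharp
#' @noRd
.overlay_layout <- function(S, cp, ic) {
  guard <- 4
  x <- matrix(seq_len(S), S, S, byrow = TRUE)
  y <- matrix(seq_len(S), S, S)
  interior <- x > cp["left"] + guard & x <= S - cp["right"] - guard &
              y > cp["top"] + guard & y <= S - cp["bottom"] - guard

  r <- sqrt(((x - ic[1]) / (0.26 * S))^2 + ((y - ic[2]) / (0.20 * S))^2)
  contour <- abs(r - 1) < 0.012 & interior

  axes <- (x == round(ic[1]) | y == round(ic[2])) & interior

  step <- max(16, round(S / 10))
  grid <- (x %% step == 0) & (y %% step == 0) & interior

  marks <- matrix(FALSE, S, S)
  for (p in list(c(0.35, 0.35), c(0.62, 0.5), c(0.45, 0.68))) {
    px <- round(p[1] * S); py <- round(p[2] * S)
    marks[py + 0:1, px + 0:1] <- TRUE
  }
  marks <- marks & interior

  list(contour = contour, axis = axes, grid = grid, mark = marks)
}

#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The 10-position couch-shift pattern
#'
#' The evaluation pattern of the accuracy experiment: shifts of 0.5, 1, 2,
#' 4, 10, -0.5, -1, -2, -4, -10 mm applied simultaneously to the lateral,
#' vertical and longitudinal axes.
#'
#' @return Tibble with columns `pattern` (1--10), `lat_mm`, `vert_mm`,
#'   `long_mm`.
#' @export
couch_pattern <- function() {
  v <- c(0.5, 1, 2, 4, 10, -0.5, -1, -2, -4, -10)
  tibble::tibble(pattern = 1:10, lat_mm = v, vert_mm = v, long_mm = v)
}

#' Simulate manual pointing of a displacement
#'
#' Stand-in for the technicians' manual landmark pointing: each observer
#' reports the ground-truth per-view displacement plus independent Gaussian
#' error per component.  The default observer SD is 0.21 mm, the mean
#' reported inter-observer variability for phantom images.
#'
#' @param truth A `ground_truth` from [render_dr()].
#' @param observer_sd_mm Per-component observer noise SD in mm (>= 0).
#' @param n_observers Number of observers (>= 1).
#' @param seed Integer seed.
#' @return Tibble: `observer`, `view`, `dx_mm`, `dy_mm`.
#' @export
simulate_pointing <- function(truth, observer_sd_mm = 0.21, n_observers = 3,
                              seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), observer_sd_mm >= 0,
            n_observers >= 1)
  true_mm <- truth$offset_px * truth$pixel_spacing_mm
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tibble::tibble(
    observer = seq_len(n_observers),
    view = truth$view,
    dx_mm = true_mm[1] + rnorm(n_observers, sd = observer_sd_mm),
    dy_mm = true_mm[2] + rnorm(n_observers, sd = observer_sd_mm)
  )
}
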