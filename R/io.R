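#' Read a matching configuration from YAML or JSON
#'
#' Recognized keys are the arguments of [match_config()]; unknown keys are
#' rejected.  Missing keys take the built-in defaults (sn = 0.8,
#' s_sigma = 0.4, M = 40, mt = 30000, s = 480, pixel spacing 0.446 mm/px).
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for the defaults.
#' @return A [match_config()].
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(match_config())
  if (!file.exists(path)) {
    abort(paste0("cannot read config: ", path), class = "couchmatch_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort(paste0("unsupported config format: .", ext),
          class = "couchmatch_io_error")
  )
  known <- names(formals(match_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste("unknown config keys:", paste(bad, collapse = ", ")),
          class = "couchmatch_config_error")
  }
  if (!is.null(vals$overlay_palette)) {
    vals$overlay_palette <- matrix(unlist(vals$overlay_palette),
                                   ncol = 3, byrow = TRUE)
  }
  do.call(match_config, vals)
}

#' Run the full measurement pipeline on image files
#'
#' Reads the four images, cleans each treatment-room image (overlay
#' inpainting, collimator masking), registers each view against its
#' reference, and maps the displacements to couch-space residual errors
#' (reference displacement zero, couch shift zero: the report's errors are
#' the residual misalignment itself).  Inputs are never modified.
#'
#' @param frontal_path,lateral_path Captured DR image files.
#' @param frontal_drr_path,lateral_drr_path Reference DRR image files.
#' @param config_path Optional YAML/JSON config file.
#' @param config A [match_config()]; overrides `config_path` when given.
#' @return Object of class `run_report`: configuration echo, input
#'   checksums, per-view displacements (px and mm), couch-space errors, and
#'   warning flags (`border_peak`, `low_valid`).
#' @export
run_pipeline <- function(frontal_path, lateral_path,
                         frontal_drr_path, lateral_drr_path,
                         config_path = NULL, config = NULL) {
  cfg <- config %||% read_config(config_path)
  paths <- c(frontal = frontal_path, lateral = lateral_path,
             frontal_drr = frontal_drr_path, lateral_drr = lateral_drr_path)
  for (p in paths) {
    if (!file.exists(p)) {
      abort(paste0("cannot read image: ", p), class = "couchmatch_io_error")
    }
  }
  drf <- read_radiograph(frontal_path, "frontal", cfg$pixel_spacing_mm)
  drl <- read_radiograph(lateral_path, "lateral", cfg$pixel_spacing_mm)
  rff <- read_radiograph(frontal_drr_path, "frontal", cfg$pixel_spacing_mm)
  rfl <- read_radiograph(lateral_drr_path, "lateral", cfg$pixel_spacing_mm)

  reg <- run_registration(drf, drl, rff, rfl, cfg)
  err <- couch_error(
    list(frontal = reg$frontal, lateral = reg$lateral),
    list(frontal = c(0, 0), lateral = c(0, 0)),
    c(0, 0, 0), pixel_spacing_mm = cfg$pixel_spacing_mm
  )

  win <- .match_window(dim(drf$pixels), drf$isocenter_px, cfg)
  full_n <- (win$x1 - win$x0 + 1) * (win$y1 - win$y0 + 1)
  disp_fields <- function(d) {
    list(dx_px = d$dx_px, dy_px = d$dy_px,
         dx_mm = d$dx_px * cfg$pixel_spacing_mm,
         dy_mm = d$dy_px * cfg$pixel_spacing_mm,
         peak_correlation = d$peak_correlation, n_valid = d$n_valid)
  }
  cfg_echo <- cfg[c("s", "sn", "s_sigma", "M", "mt", "subpixel_step_px",
                    "pixel_spacing_mm", "bit_depth", "min_valid_px",
                    "weight", "overlay_tolerance")]
  structure(
    list(
      tool = "couchmatch",
      version = as.character(utils::packageVersion("couchmatch")),
      config = cfg_echo,
      checksums = as.list(tools::md5sum(paths)),
      frontal = disp_fields(reg$frontal),
      lateral = disp_fields(reg$lateral),
      error = list(e_lat_mm = err$e_lat_mm, e_vert_mm = err$e_vert_mm,
                   e_long_mm = err$e_long_mm, rmse_mm = err$rmse_mm),
      warnings = list(
        border_peak = isTRUE(reg$frontal$border_peak) ||
                      isTRUE(reg$lateral$border_peak),
        low_valid = reg$frontal$n_valid < full_n / 4 ||
                    reg$lateral$n_valid < full_n / 4
      )
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  frontal: dx %+.3f mm, dy %+.3f mm (R = %.4f)\n",
              x$frontal$dx_mm, x$frontal$dy_mm, x$frontal$peak_correlation))
  cat(sprintf("  lateral: dx %+.3f mm, dy %+.3f mm (R = %.4f)\n",
              x$lateral$dx_mm, x$lateral$dy_mm, x$lateral$peak_correlation))
  cat(sprintf("  residual error (lat/vert/long): %+.3f / %+.3f / %+.3f mm, RMSE %.3f mm\n",
              x$error$e_lat_mm, x$error$e_vert_mm, x$error$e_long_mm,
              x$error$rmse_mm))
  if (isTRUE(x$warnings$border_peak))
    cat("  WARNING: correlation peak on the search-grid border\n")
  if (isTRUE(x$warnings$low_valid))
    cat("  WARNING: few valid pixels in the calculation window\n")
  invisible(x)
}

#' Write or read a run report as JSON
#'
#' Reports round-trip exactly: `read_report(write_report(x, p))` equals `x`.
#'
#' @param report A `run_report`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `run_report` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read report: ", path), class = "couchmatch_io_error")
  }
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE),
            class = "run_report")
}

#' Batch-evaluate a couch-pattern manifest
#'
#' Registers every manifest row's image pair against the shared references
#' and evaluates couch-space errors against the reference row (`pattern ==
#' ref_pattern`).  Per-row failures are recorded and the run continues.
#'
#' @param manifest CSV path or tibble with columns `pattern`, `m_lat`,
#'   `m_vert`, `m_long` (mm) and `frontal`, `lateral` (image paths).
#' @param frontal_drr_path,lateral_drr_path Reference image files.
#' @param config A [match_config()].
#' @param ref_pattern Reference row label (default 0).
#' @return List with `results` (per-pattern error table), `summary`
#'   ([aggregate_pattern()] of the successful rows), `displacements`, and
#'   `failures` (tibble of failed rows and messages).
#' @export
batch_evaluate <- function(manifest, frontal_drr_path, lateral_drr_path,
                           config = match_config(), ref_pattern = 0) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      abort(paste0("cannot read manifest: ", manifest),
            class = "couchmatch_io_error")
    }
    manifest <- tibble::as_tibble(utils::read.csv(manifest,
                                                  stringsAsFactors = FALSE))
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0) {
    abort("manifest is empty", class = "couchmatch_input_error")
  }
  need <- c("pattern", "m_lat", "m_vert", "m_long", "frontal", "lateral")
  if (!all(need %in% names(manifest))) {
    abort(paste("manifest missing columns:",
                paste(setdiff(need, names(manifest)), collapse = ", ")),
          class = "couchmatch_input_error")
  }
  cfg <- config
  rff <- read_radiograph(frontal_drr_path, "frontal", cfg$pixel_spacing_mm)
  rfl <- read_radiograph(lateral_drr_path, "lateral", cfg$pixel_spacing_mm)

  rows <- purrr::pmap(manifest, function(pattern, m_lat, m_vert, m_long,
                                         frontal, lateral, ...) {
    tryCatch({
      drf <- read_radiograph(frontal, "frontal", cfg$pixel_spacing_mm)
      drl <- read_radiograph(lateral, "lateral", cfg$pixel_spacing_mm)
      reg <- run_registration(drf, drl, rff, rfl, cfg)
      tibble::tibble(pattern = pattern, m_lat = m_lat, m_vert = m_vert,
                     m_long = m_long,
                     dx_f = reg$frontal$dx_px, dy_f = reg$frontal$dy_px,
                     dx_l = reg$lateral$dx_px, dy_l = reg$lateral$dy_px,
                     status = "ok", message = "")
    }, error = function(e) {
      tibble::tibble(pattern = pattern, m_lat = m_lat, m_vert = m_vert,
                     m_long = m_long, dx_f = NA_real_, dy_f = NA_real_,
                     dx_l = NA_real_, dy_l = NA_real_,
                     status = "failed", message = conditionMessage(e))
    })
  })
  disp <- dplyr::bind_rows(rows)
  ok <- disp[disp$status == "ok", ]
  failures <- disp[disp$status != "ok", c("pattern", "message")]
  if (!any(ok$pattern == ref_pattern)) {
    abort("reference row failed or missing; cannot evaluate",
          class = "couchmatch_input_error")
  }
  results <- evaluate_displacements(ok, cfg$pixel_spacing_mm, ref_pattern)
  list(results = results, summary = attr(results, "summary"),
       displacements = disp, failures = failures)
}
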