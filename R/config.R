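#' Scan-artifact settings
#'
#' Magnitudes of the smartphone-scan artifact model. Each page drawn with
#' these settings receives a rotation uniform in `[-rotation_deg,
#' rotation_deg]`, a linear illumination fall-off of at most `illum_frac`
#' of the dynamic range (random direction), and i.i.d. Gaussian pixel noise
#' with standard deviation `noise_sd`, in that fixed order.
#'
#' @param rotation_deg Maximum absolute page rotation, degrees (bounded by 3).
#' @param illum_frac Maximum illumination gradient as a fraction of the
#'   dynamic range (bounded by 0.2).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the dynamic
#'   range (bounded by 0.05).
#' @return An `hw_artifact_params` list.
#' @export
artifact_params <- function(rotation_deg = 1.5, illum_frac = 0.10,
                            noise_sd = 0.02) {
  for (v in c(rotation_deg, illum_frac, noise_sd))
    if (!is_scalar_number(v) || v < 0) stop_config("artifact parameters must be non-negative numbers")
  if (rotation_deg > 3) stop_config("rotation_deg must be <= 3 degrees")
  if (illum_frac > 0.2) stop_config("illum_frac must be <= 0.2 of the dynamic range")
  if (noise_sd > 0.05) stop_config("noise_sd must be <= 0.05 of the dynamic range")
  structure(list(rotation_deg = rotation_deg, illum_frac = illum_frac,
                 noise_sd = noise_sd), class = "hw_artifact_params")
}

micrographr_default_artifacts <- function() artifact_params()

#' Synthetic handwriting-sheet generator configuration
#'
#' Defaults encode the study conditions this generator emulates: an A4
#' (210 x 297 mm) sheet written 10 times in a single column, with group
#' ink-area and sequence-effect distributions matching the reported
#' healthy-subject and Parkinson's-disease (OFF state) means and SDs
#' (pen stroke area 126.72 +/- 44.85 vs 89.78 +/- 26.37 mm^2; sequence
#' effect 1.05 +/- 0.16 vs 0.92 +/- 0.23).
#'
#' @param page_width_mm,page_height_mm Sheet size in mm (A4 by default).
#' @param dpi Raster resolution; fixes the calibration 25.4/dpi mm per
#'   pixel and the raster size `round(page_mm / calibration)`.
#' @param rows_per_sheet Number of repeated written rows (>= 2).
#' @param tasks_per_subject Number of handwriting tasks (sentence, name).
#' @param group_area_params Named list mapping group label to
#'   `c(mean, sd)` of the per-subject base pen-stroke area in mm^2.
#' @param group_seqeffect_params Named list mapping group label to
#'   `c(mean, sd)` of the per-subject sequence effect (last-5/first-5
#'   mean row-area ratio; < 1 means progressive shrinkage).
#' @param artifact_params Default scan-artifact settings; `NULL` means
#'   [artifact_params()] defaults.
#' @param margins_mm Page margins `c(top, bottom, left, right)` in mm.
#' @param on_area_shift_mm2 Mean shift applied to the base area of
#'   ON-state pages relative to OFF. The default 0 reflects the absence of
#'   an L-Dopa effect on stroke size; a nonzero value is available for
#'   power exploration.
#' @param seed Default seed for all generator randomness.
#' @return An `hw_generator_config` list.
#' @export
generator_config <- function(page_width_mm = 210, page_height_mm = 297,
                             dpi = 300, rows_per_sheet = 10L,
                             tasks_per_subject = 2L,
                             group_area_params = list(
                               HS = c(mean = 126.72, sd = 44.85),
                               PD = c(mean = 89.78, sd = 26.37)
                             ),
                             group_seqeffect_params = list(
                               HS = c(mean = 1.05, sd = 0.16),
                               PD = c(mean = 0.92, sd = 0.23)
                             ),
                             artifact_params = NULL,
                             margins_mm = c(top = 20, bottom = 20, left = 15, right = 15),
                             on_area_shift_mm2 = 0,
                             seed = 1L) {
  if (!is_scalar_number(page_width_mm) || page_width_mm <= 0 ||
      !is_scalar_number(page_height_mm) || page_height_mm <= 0)
    stop_config("page dimensions must be positive")
  if (!is_scalar_number(dpi) || dpi <= 0) stop_config("dpi must be positive")
  rows_per_sheet <- as.integer(rows_per_sheet)
  if (rows_per_sheet < 2) stop_config("rows_per_sheet must be >= 2 (sequence effect needs at least two rows)")
  tasks_per_subject <- as.integer(tasks_per_subject)
  if (tasks_per_subject < 1 || tasks_per_subject > 2)
    stop_config("tasks_per_subject must be 1 or 2")
  check_group_params <- function(p, what, ratio = FALSE) {
    if (!is.list(p) || is.null(names(p)) || any(!nzchar(names(p))))
      stop_config(sprintf("%s must be a named list of c(mean, sd)", what))
    for (g in names(p)) {
      v <- p[[g]]
      if (length(v) != 2 || !all(is.finite(v)))
        stop_config(sprintf("%s[['%s']] must be c(mean, sd)", what, g))
      if (v[[1]] <= 0) stop_config(sprintf("%s[['%s']]: mean must be > 0", what, g))
      if (v[[2]] < 0) stop_config(sprintf("%s[['%s']]: sd must be >= 0", what, g))
    }
  }
  if (is.null(artifact_params)) artifact_params <- micrographr_default_artifacts()
  check_group_params(group_area_params, "group_area_params")
  check_group_params(group_seqeffect_params, "group_seqeffect_params")
  if (!setequal(names(group_area_params), names(group_seqeffect_params)))
    stop_config("area and sequence-effect parameters must cover the same groups")
  stopifnot(inherits(artifact_params, "hw_artifact_params"))
  margins_mm <- margins_mm[c("top", "bottom", "left", "right")]
  if (any(is.na(margins_mm)) || any(margins_mm < 0))
    stop_config("margins_mm must name non-negative top/bottom/left/right")

  structure(
    list(
      page_width_mm = page_width_mm, page_height_mm = page_height_mm,
      dpi = dpi, mm_per_px = mm_per_pixel(dpi),
      rows_per_sheet = rows_per_sheet, tasks_per_subject = tasks_per_subject,
      group_area_params = group_area_params,
      group_seqeffect_params = group_seqeffect_params,
      artifact_params = artifact_params,
      margins_mm = margins_mm,
      on_area_shift_mm2 = on_area_shift_mm2,
      seed = as.integer(seed)
    ),
    class = "hw_generator_config"
  )
}

#' @export
print.hw_generator_config <- function(x, ...) {
  cat(sprintf("<hw_generator_config> %g x %g mm at %g dpi, %d rows, groups: %s\n",
              x$page_width_mm, x$page_height_mm, x$dpi, x$rows_per_sheet,
              paste(names(x$group_area_params), collapse = ", ")))
  invisible(x)
}
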