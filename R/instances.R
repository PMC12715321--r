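#' Build a labelled row-instance dataset for a comparison
#'
#' Turns every page of the manifest that enters the named comparison into
#' `expected_rows` cropped, normalised row instances, each labelled with
#' its subject's class. Pages failing segmentation are skipped with a
#' warning and counted (the study-design analogue of a small perceptual
#' quality discard), never silently imputed.
#'
#' Comparisons and their class factor levels (second level = the
#' "impaired"/positive convention used downstream):
#' \describe{
#'   \item{HS_vs_PD}{healthy subjects vs patients (OFF-state pages);
#'     levels `HS`, `PD`.}
#'   \item{early_vs_mid}{patients only, OFF-state pages; levels
#'     `mid_advanced`, `early`.}
#'   \item{OFF_vs_ON}{patients only, both states; levels `ON`, `OFF`.
#'     Labels live at the page level here (each patient contributes both
#'     classes); fold grouping stays patient-disjoint.}
#' }
#'
#' @param manifest Manifest tibble (see [write_dataset()]).
#' @param comparison One of `"HS_vs_PD"`, `"early_vs_mid"`, `"OFF_vs_ON"`.
#' @param expected_rows Rows per sheet.
#' @param target_size Instance raster size `c(height, width)`.
#' @param deskew Deskew pages before segmentation.
#' @param tasks Optional subset of task ids (default: all; the study
#'   pooled both handwriting tasks).
#' @return Tibble with one row per instance: identifiers, `row_index`,
#'   `class` (factor, 2 levels), `raster` (list of matrices),
#'   `mm_per_px`; attribute `skipped_pages` counts discarded pages.
#' @export
build_instances <- function(manifest,
                            comparison = c("HS_vs_PD", "early_vs_mid", "OFF_vs_ON"),
                            expected_rows = 10L,
                            target_size = c(32L, 128L),
                            deskew = TRUE, tasks = NULL) {
  comparison <- match.arg(comparison)
  if (!is.null(tasks)) manifest <- dplyr::filter(manifest, .data$task_id %in% tasks)

  off_like <- function(s) s %in% c("OFF", "none") | is.na(s)
  sel <- switch(comparison,
    HS_vs_PD = manifest |>
      dplyr::filter(.data$group == "HS" | off_like(.data$state)) |>
      dplyr::mutate(class = factor(ifelse(.data$group == "HS", "HS", "PD"),
                                   levels = c("HS", "PD"))),
    early_vs_mid = manifest |>
      dplyr::filter(.data$group != "HS", off_like(.data$state)) |>
      dplyr::mutate(class = factor(.data$stage,
                                   levels = c("mid_advanced", "early"))),
    OFF_vs_ON = manifest |>
      dplyr::filter(.data$group != "HS", .data$state %in% c("OFF", "ON")) |>
      dplyr::mutate(class = factor(.data$state, levels = c("ON", "OFF")))
  )
  if (any(is.na(sel$class)))
    abort("manifest rows with labels outside the comparison's classes",
          class = "micrographr_dataset_error")

  skipped <- 0L
  out <- purrr::pmap(sel, function(subject_id, group, stage, state, task_id,
                                   path, dpi, class, ...) {
    page <- read_page(path, dpi = dpi, subject_id = subject_id, task_id = task_id)
    if (deskew) page <- deskew_page(page)
    boxes <- tryCatch(segment_rows(page, expected_rows),
                      micrographr_segmentation_error = function(e) {
                        warn(sprintf("skipping %s/%s/%s: %s", subject_id, state,
                                     task_id, conditionMessage(e)))
                        NULL
                      })
    if (is.null(boxes)) { skipped <<- skipped + 1L; return(NULL) }
    rasters <- purrr::pmap(boxes, function(row_index, x0, y0, x1, y1) {
      crop_and_normalize(page, list(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
                         target_size)
    })
    tibble::tibble(
      subject_id = subject_id, group = group, stage = stage, state = state,
      task_id = task_id, row_index = boxes$row_index, class = class,
      raster = rasters, mm_per_px = page$mm_per_px
    )
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    abort("no instances could be built", class = "micrographr_dataset_error")
  counts <- table(res$class)
  if (any(counts == 0))
    abort(sprintf("class '%s' has zero instances",
                  names(counts)[counts == 0][1]),
          class = "micrographr_dataset_error")
  attr(res, "skipped_pages") <- skipped
  attr(res, "comparison") <- comparison
  res
}
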