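#' Task labels for a configuration
#'
#' The sentence task comes first so that single-task runs use the task on
#' which consistent micrographia is defined.
#' @param config An [generator_config()].
#' @return Character vector of task ids.
#' @export
task_labels <- function(config) {
  c("sentence", "name")[seq_len(config$tasks_per_subject)]
}

#' Write a synthetic handwriting dataset to disk
#'
#' Renders one page per subject x task (x state, if profiles carry both
#' OFF and ON rows), optionally applies scan artifacts, and writes PNG
#' pages, per-sheet ground-truth JSON, and a manifest CSV. Re-running with
#' `overwrite = TRUE` reproduces the dataset byte-identically.
#'
#' @param profiles Profile tibble from [sample_subject_profiles()].
#' @param config An [generator_config()].
#' @param dir Output directory (created if needed).
#' @param artifacts `NULL` for clean renders, or an [artifact_params()].
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @param seed Seed; each sheet derives its own substream from it.
#' @return The manifest tibble (also written to `dir/manifest.csv`):
#'   subject_id, group, stage, state, task_id, path, truth_path, dpi,
#'   mm_per_px, base_area_mm2, seq_effect.
#' @export
write_dataset <- function(profiles, config, dir, artifacts = NULL,
                          overwrite = FALSE, seed = config$seed) {
  stopifnot(inherits(config, "hw_generator_config"))
  manifest_path <- file.path(dir, "manifest.csv")
  if (file.exists(manifest_path) && !overwrite)
    stop_config(sprintf("manifest already exists at %s (use overwrite = TRUE)", manifest_path))
  dir.create(file.path(dir, "pages"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)

  if (nrow(profiles) == 0) {
    manifest <- tibble::tibble(
      subject_id = character(), group = character(), stage = character(),
      state = character(), task_id = character(), path = character(),
      truth_path = character(), dpi = numeric(), mm_per_px = numeric(),
      base_area_mm2 = numeric(), seq_effect = numeric()
    )
    readr::write_csv(manifest, manifest_path)
    return(manifest)
  }

  tasks <- task_labels(config)
  grid <- tidyr::crossing(profiles, task_id = tasks)
  records <- purrr::pmap(
    list(seq_len(nrow(grid))),
    function(i) {
      row <- grid[i, ]
      stem <- sprintf("%s_%s_%s", row$subject_id, row$state, row$task_id)
      sheet_seed <- derive_seed(seed, row$subject_id, row$state, row$task_id)
      res <- render_sheet(row, row$task_id, config, seed = sheet_seed)
      page <- res$page
      if (!is.null(artifacts))
        page <- add_scan_artifacts(page, artifacts, seed = sheet_seed + 1L)
      path <- file.path(dir, "pages", paste0(stem, ".png"))
      truth_path <- file.path(dir, "truth", paste0(stem, ".json"))
      write_page(page, path)
      jsonlite::write_json(res$truth, truth_path, digits = NA)
      tibble::tibble(
        subject_id = row$subject_id, group = row$group, stage = row$stage,
        state = row$state, task_id = row$task_id,
        path = path, truth_path = truth_path,
        dpi = config$dpi, mm_per_px = config$mm_per_px,
        base_area_mm2 = row$base_area_mm2, seq_effect = row$seq_effect
      )
    }
  )
  manifest <- dplyr::bind_rows(records)
  readr::write_csv(manifest, manifest_path)
  manifest
}

#' Read a dataset manifest written by [write_dataset()]
#' @param path Manifest CSV path.
#' @return Manifest tibble.
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = "c", group = "c", stage = "c", state = "c",
                    task_id = "c", path = "c", truth_path = "c"
                  ))
}

#' Read the ground truth for one sheet
#' @param path Truth JSON path (see [write_dataset()]).
#' @return Tibble with per-row target/realized areas and bounding boxes.
#' @export
read_truth <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
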