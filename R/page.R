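#' Construct a handwriting page object
#'
#' A page is a grayscale raster (matrix, rows = scanlines top to bottom,
#' values in \[0, 1\] with 1 = white paper and ink towards 0) together with
#' the physical calibration. The calibration is always carried as metadata
#' and never inferred from image content.
#'
#' @param pixels Numeric matrix in \[0, 1\]; `pixels[1, 1]` is the top-left
#'   corner of the sheet.
#' @param dpi Raster resolution the page was rendered/scanned at.
#' @param subject_id,task_id Optional identifiers carried for provenance.
#' @param rotation_deg Accumulated rotation applied by scan artifacts.
#' @return An object of class `hw_page`.
#' @export
hw_page <- function(pixels, dpi, subject_id = NA_character_,
                    task_id = NA_character_, rotation_deg = 0) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < -1e-8 | pixels > 1 + 1e-8, na.rm = TRUE))
    stop_config("page pixels must lie in [0, 1]")
  structure(
    list(
      pixels = pixels,
      dpi = dpi,
      mm_per_px = mm_per_pixel(dpi),
      subject_id = subject_id,
      task_id = task_id,
      rotation_deg = rotation_deg
    ),
    class = "hw_page"
  )
}

#' @export
print.hw_page <- function(x, ...) {
  cat(sprintf(
    "<hw_page> %d x %d px (%.1f x %.1f mm at %g dpi)%s\n",
    nrow(x$pixels), ncol(x$pixels),
    nrow(x$pixels) * x$mm_per_px, ncol(x$pixels) * x$mm_per_px,
    x$dpi,
    if (!is.na(x$subject_id)) sprintf(" subject=%s task=%s", x$subject_id, x$task_id) else ""
  ))
  invisible(x)
}

#' Read a page image from disk
#'
#' @param path PNG file (8-bit grayscale or RGB; RGB is averaged).
#' @param dpi Resolution metadata for the file (calibration is metadata,
#'   it is never guessed from pixels).
#' @inheritParams hw_page
#' @return An `hw_page`.
#' @export
read_page <- function(path, dpi, subject_id = NA_character_,
                      task_id = NA_character_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  hw_page(px, dpi = dpi, subject_id = subject_id, task_id = task_id)
}

#' Write a page image to disk
#'
#' @param page An `hw_page`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_page <- function(page, path) {
  stopifnot(inherits(page, "hw_page"))
  png::writePNG(pmin(pmax(page$pixels, 0), 1), target = path)
  invisible(path)
}
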