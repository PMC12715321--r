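# Page preprocessing: deskew, projection-profile row segmentation, and
# crop normalisation for the classifier. Replaces the manual row-basis
# cropping of scanned sheets with a reproducible procedure.

#' Estimate and undo a small page rotation
#'
#' Smartphone captures are rarely axis-aligned. The skew angle is found
#' by maximising the variance of the horizontal ink-projection profile
#' over candidate rotations (text lines give the sharpest profile when
#' horizontal), on a downsampled copy for speed; the full page is then
#' rotated once.
#'
#' @param page An [hw_page()].
#' @param max_deg Search range, degrees.
#' @param step_deg Search step, degrees.
#' @return A deskewed `hw_page` (unchanged if the best angle is ~0).
#' @export
deskew_page <- function(page, max_deg = 3, step_deg = 0.25) {
  stopifnot(inherits(page, "hw_page"))
  px <- page$pixels
  fac <- max(1L, floor(ncol(px) / 500))
  small <- px[seq(1, nrow(px), by = fac), seq(1, ncol(px), by = fac), drop = FALSE]
  ink <- 1 - small
  ink[ink < 0.5] <- 0  # keep strong ink only; robust to illumination ramps
  angles <- seq(-max_deg, max_deg, by = step_deg)
  scores <- vapply(angles, function(a) {
    img <- if (abs(a) < 1e-9) EBImage::Image(t(ink))
           else EBImage::rotate(EBImage::Image(t(ink)), a, bg.col = 0)
    stats::var(colSums(EBImage::imageData(img)))  # EBImage y = our rows
  }, numeric(1))
  best <- angles[which.max(scores)]
  if (abs(best) < step_deg / 2) return(page)
  img <- EBImage::rotate(EBImage::Image(t(px)), best, bg.col = 1,
                         filter = "none")  # area-preserving, see artifacts
  hw_page(pmin(pmax(t(EBImage::imageData(img)), 0), 1), dpi = page$dpi,
          subject_id = page$subject_id, task_id = page$task_id,
          rotation_deg = page$rotation_deg + best)
}

#' Segment a page into written rows
#'
#' Binarises the page, sums ink per scanline, bridges blank gaps shorter
#' than `min_gap_mm`, drops bands shorter than `min_height_mm`, and
#' requires exactly `expected_rows` bands.
#'
#' @param page An [hw_page()].
#' @param expected_rows Number of rows that must be found (>= 1).
#' @param min_gap_mm Blank runs at least this tall split rows.
#' @param min_height_mm Bands shorter than this are discarded as specks.
#' @param mask Optional precomputed ink mask (logical matrix).
#' @return Tibble of half-open, 0-based boxes sorted top to bottom:
#'   `row_index`, `x0`, `y0`, `x1`, `y1`.
#' @export
segment_rows <- function(page, expected_rows, min_gap_mm = 2,
                         min_height_mm = 2, mask = NULL) {
  stopifnot(inherits(page, "hw_page"))
  expected_rows <- as.integer(expected_rows)
  if (expected_rows < 1) stop_config("expected_rows must be >= 1")
  if (is.null(mask)) mask <- binarize_ink(page)
  c_mm <- page$mm_per_px
  profile <- rowSums(mask)
  has_ink <- profile > 0

  if (!any(has_ink))
    stop_segmentation(sprintf("expected %d rows, found 0 ink bands", expected_rows))

  min_gap_px <- max(1L, round(min_gap_mm / c_mm))
  min_h_px <- max(1L, round(min_height_mm / c_mm))

  ## bridge blank runs shorter than the minimum inter-row gap
  r <- rle(has_ink)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  interior <- which(!r$values & r$lengths < min_gap_px &
                      seq_along(r$values) > 1 &
                      seq_along(r$values) < length(r$values))
  for (i in interior) has_ink[starts[i]:ends[i]] <- TRUE

  r <- rle(has_ink)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bands <- which(r$values & r$lengths >= min_h_px)
  if (length(bands) != expected_rows)
    stop_segmentation(sprintf("expected %d rows, found %d ink bands",
                              expected_rows, length(bands)))

  purrr::map_dfr(seq_along(bands), function(i) {
    b <- bands[[i]]
    ys <- starts[[b]]; ye <- ends[[b]]
    cols <- which(colSums(mask[ys:ye, , drop = FALSE]) > 0)
    tibble::tibble(row_index = i,
                   x0 = min(cols) - 1L, y0 = ys - 1L,
                   x1 = max(cols), y1 = ye)
  })
}

#' Crop a row box and normalise it for classification
#'
#' The crop is converted to ink intensity (background 0, ink towards 1)
#' by min-max normalisation, padded symmetrically with background to the
#' target aspect ratio, and rescaled to `target_size` pixels (bilinear).
#' A constant crop normalises to all-zero background. Deterministic.
#'
#' @param page An [hw_page()].
#' @param box One row of [segment_rows()] output (half-open, 0-based), or
#'   any list with `x0, y0, x1, y1`.
#' @param target_size Output size `c(height, width)` in pixels.
#' @return Numeric matrix `target_size[1] x target_size[2]` in \[0, 1\].
#' @export
crop_and_normalize <- function(page, box, target_size = c(32L, 128L)) {
  stopifnot(inherits(page, "hw_page"))
  box <- as.list(box)
  H <- nrow(page$pixels); W <- ncol(page$pixels)
  if (box$x0 < 0 || box$y0 < 0 || box$x1 > W || box$y1 > H ||
      box$x1 <= box$x0 || box$y1 <= box$y0)
    stop_config("box is empty or outside page bounds")
  crop <- page$pixels[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, drop = FALSE]

  rng <- range(crop)
  ink <- if (diff(rng) < 1e-12) matrix(0, nrow(crop), ncol(crop))
         else (rng[2] - crop) / (rng[2] - rng[1])

  th <- as.integer(target_size[[1]]); tw <- as.integer(target_size[[2]])
  h <- nrow(ink); w <- ncol(ink)
  ## pad with background to the target aspect ratio before resizing
  if (w * th > h * tw) {
    need <- ceiling(w * th / tw) - h
    top <- need %/% 2
    ink <- rbind(matrix(0, top, w), ink, matrix(0, need - top, w))
  } else if (w * th < h * tw) {
    need <- ceiling(h * tw / th) - w
    left <- need %/% 2
    ink <- cbind(matrix(0, nrow(ink), left), ink,
                 matrix(0, nrow(ink), need - left))
  }
  if (nrow(ink) == th && ncol(ink) == tw) return(ink)
  out <- EBImage::resize(EBImage::Image(t(ink)), w = tw, h = th)
  pmin(pmax(t(EBImage::imageData(out)), 0), 1)
}
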