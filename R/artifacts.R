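#' Apply smartphone-scan artifacts to a page
#'
#' Applies, in this fixed order: a rotation drawn uniformly in
#' `[-rotation_deg, rotation_deg]` (white background fill), a linear
#' illumination fall-off of `illum_frac` of the dynamic range in a random
#' direction, and additive Gaussian pixel noise with SD `noise_sd`,
#' clamped back to \[0, 1\]. All randomness is governed by `seed`; a
#' parameter set of all zeros returns the input bit-identically. The
#' applied rotation angle is accumulated in the page metadata (the mm/px
#' calibration itself is rotation-invariant).
#'
#' @param page An [hw_page()].
#' @param params An [artifact_params()].
#' @param seed Integer seed.
#' @return A new `hw_page` (dimensions may grow slightly under rotation).
#' @export
add_scan_artifacts <- function(page, params = artifact_params(), seed = 1L) {
  stopifnot(inherits(page, "hw_page"))
  if (!inherits(params, "hw_artifact_params"))
    stop_config("params must be created by artifact_params()")
  if (params$rotation_deg == 0 && params$illum_frac == 0 && params$noise_sd == 0)
    return(page)

  with_seed(derive_seed(seed, "artifacts"), {
    px <- page$pixels
    angle <- 0
    if (params$rotation_deg > 0) {
      angle <- runif(1, -params$rotation_deg, params$rotation_deg)
      ## nearest-neighbour resampling: keeps the bilevel stroke bilevel, so
      ## the binarised ink area is preserved rather than convolved with the
      ## interpolation kernel
      img <- EBImage::rotate(EBImage::Image(t(px)), angle, bg.col = 1,
                             filter = "none")
      px <- t(EBImage::imageData(img))
      px <- pmin(pmax(px, 0), 1)
    }
    if (params$illum_frac > 0) {
      dir <- sample(c("left", "right", "top", "bottom"), 1)
      ramp <- switch(dir,
        left   = matrix(seq(1, 0, length.out = ncol(px)), nrow(px), ncol(px), byrow = TRUE),
        right  = matrix(seq(0, 1, length.out = ncol(px)), nrow(px), ncol(px), byrow = TRUE),
        top    = matrix(seq(1, 0, length.out = nrow(px)), nrow(px), ncol(px)),
        bottom = matrix(seq(0, 1, length.out = nrow(px)), nrow(px), ncol(px))
      )
      px <- px * (1 - params$illum_frac * ramp)
    }
    if (params$noise_sd > 0) {
      px <- px + rnorm(length(px), 0, params$noise_sd)
      px <- pmin(pmax(px, 0), 1)
    }
    hw_page(px, dpi = page$dpi, subject_id = page$subject_id,
            task_id = page$task_id,
            rotation_deg = page$rotation_deg + angle)
  })
}
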