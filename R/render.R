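# Sheet rendering: parametric pseudo-handwriting with exact ink-area control.
#
# Each row is a cursive-like oscillatory curve drawn inside its row band.
# Stroke thickness is not guessed: the curve is rasterised as a one-pixel
# polyline, the Euclidean distance transform to the polyline is computed,
# and the stroke is the set of pixels whose distance is at most r, where r
# is chosen as the k-th smallest distance with k = round(target / c^2).
# The realised binarised ink area is therefore exact to pixel resolution.

#' Per-row area decay profile
#'
#' Geometric progression `g(r) = a * q^(r - 1)` normalised so that the mean
#' over the first `h = floor(n/2)` rows is 1 and the ratio of the last-h to
#' first-h means equals `seq_effect` (so `q = seq_effect^(1/(n - h))`).
#' A subject's row `r` target ink area is `base_area_mm2 * g(r)`.
#'
#' @param seq_effect Target last-h/first-h mean-area ratio (> 0).
#' @param n_rows Number of rows (>= 2).
#' @return Numeric vector of length `n_rows`.
#' @export
row_decay_profile <- function(seq_effect, n_rows = 10L) {
  if (!is_scalar_number(seq_effect) || seq_effect <= 0)
    stop_config("seq_effect must be a positive number")
  n_rows <- as.integer(n_rows)
  if (n_rows < 2) stop_config("n_rows must be >= 2")
  h <- n_rows %/% 2
  q <- seq_effect^(1 / (n_rows - h))
  g <- q^(seq_len(n_rows) - 1)
  g / mean(g[seq_len(h)])
}

# Internal geometry of the writing area for one config.
page_layout <- function(config) {
  c_mm <- config$mm_per_px
  W <- round(config$page_width_mm / c_mm)
  H <- round(config$page_height_mm / c_mm)
  m <- config$margins_mm
  slot_h_mm <- (config$page_height_mm - m[["top"]] - m[["bottom"]]) / config$rows_per_sheet
  gap_mm <- max(2.5, 0.12 * slot_h_mm)  # guaranteed blank strip between rows
  list(
    W = W, H = H, c_mm = c_mm,
    x0 = round(m[["left"]] / c_mm) + 1L,
    x1 = round((config$page_width_mm - m[["right"]]) / c_mm),
    slot_h_mm = slot_h_mm, gap_mm = gap_mm,
    slot_top_mm = m[["top"]] + slot_h_mm * (seq_len(config$rows_per_sheet) - 1)
  )
}

#' Render one synthetic handwriting sheet
#'
#' Draws `config$rows_per_sheet` pseudo-handwriting rows whose binarised
#' ink areas hit the subject's per-row targets
#' `base_area_mm2 * row_decay_profile(seq_effect)` to within 2% (in
#' practice to one pixel). The output page is bilevel (ink 0, paper 1);
#' scan artifacts are added separately by [add_scan_artifacts()].
#'
#' @param profile A one-row profile (see [sample_subject_profiles()]) or a
#'   list with `subject_id`, `base_area_mm2`, `seq_effect`.
#' @param task_id Task label, e.g. `"sentence"` or `"name"`.
#' @param config An [generator_config()].
#' @param seed Seed controlling the curve shapes.
#' @return A list with elements `page` (an [hw_page()]) and `truth`, a
#'   tibble with one row per written row: `row_index`, `target_area_mm2`,
#'   `realized_area_mm2` and the half-open bounding box `x0, y0, x1, y1`
#'   in page pixel coordinates (origin top-left, x rightward, y downward).
#' @export
render_sheet <- function(profile, task_id, config, seed = config$seed) {
  stopifnot(inherits(config, "hw_generator_config"))
  profile <- as.list(profile)
  base <- profile$base_area_mm2
  seqe <- profile$seq_effect
  if (!is_scalar_number(base) || base <= 0) stop_config("base_area_mm2 must be > 0")
  if (!is_scalar_number(seqe) || seqe <= 0) stop_config("seq_effect must be > 0")

  lay <- page_layout(config)
  g <- row_decay_profile(seqe, config$rows_per_sheet)
  targets <- base * g
  page <- matrix(1, nrow = lay$H, ncol = lay$W)

  truth <- vector("list", config$rows_per_sheet)
  with_seed(derive_seed(seed, profile$subject_id %||% "anon", task_id, "render"), {
    for (r in seq_len(config$rows_per_sheet)) {
      res <- render_row(page, r, targets[[r]], lay, config)
      page <- res$page
      truth[[r]] <- res$truth
    }
  })

  truth <- dplyr::bind_rows(truth)
  pg <- hw_page(page, dpi = config$dpi,
                subject_id = profile$subject_id %||% NA_character_,
                task_id = task_id)
  list(page = pg, truth = tibble::tibble(
    subject_id = profile$subject_id %||% NA_character_,
    task_id = task_id, truth
  ))
}

# Draw one row into the page matrix; returns updated page + truth record.
render_row <- function(page, r, target_mm2, lay, config) {
  c_mm <- lay$c_mm
  ## content band: the row slot minus the inter-row gap strip
  top_mm <- lay$slot_top_mm[[r]] + lay$gap_mm / 2
  bot_mm <- lay$slot_top_mm[[r]] + lay$slot_h_mm - lay$gap_mm / 2
  ry0 <- round(top_mm / c_mm) + 1L
  ry1 <- round(bot_mm / c_mm)
  band_h <- ry1 - ry0 + 1L
  band_w <- lay$x1 - lay$x0 + 1L
  if (band_h < 4 || band_w < 4)
    stop_generation(sprintf("row %d: row band degenerate at this dpi", r))

  k <- max(1L, as.integer(round(target_mm2 / c_mm^2)))
  if (k > 0.8 * band_h * band_w)
    stop_generation(sprintf(
      "row %d: target area %.1f mm^2 would overflow its row band", r, target_mm2))

  ## cursive-like trajectory: two superimposed oscillations plus jitter.
  ## The one-pixel polyline must use well under the pixel budget k so a
  ## positive stroke radius remains solvable; shrink the curve until the
  ## polyline occupies at most 60% of the budget (deterministic loop).
  amp_mm <- 5 * sqrt(target_mm2 / 120)
  amp_mm <- min(max(amp_mm, 1), 0.36 * band_h * c_mm)
  f1 <- 11 + runif(1, -1.5, 1.5)
  ph1 <- runif(1, 0, 2 * pi)
  ph2 <- runif(1, 0, 2 * pi)
  x_start <- runif(1, 0, 0.02)
  x_end <- 1 - runif(1, 0, 0.02)

  band <- NULL
  span <- 1
  for (attempt in seq_len(24)) {
    f2 <- 2.3 * f1
    traj <- function(u) {
      x <- (x_start + u * span * (x_end - x_start)) * (band_w - 1) + 1
      y_mm <- amp_mm * sin(2 * pi * f1 * u + ph1) +
        0.35 * amp_mm * sin(2 * pi * f2 * u + ph2)
      y <- band_h / 2 + y_mm / c_mm
      cbind(x, pmin(pmax(y, 2), band_h - 1))
    }
    p0 <- traj(seq(0, 1, length.out = 4000))
    len_px <- sum(sqrt(rowSums(diff(p0)^2)))
    n_samp <- max(4000L, as.integer(ceiling(2.5 * len_px)))
    p <- traj(seq(0, 1, length.out = n_samp))
    band <- matrix(1, nrow = band_h, ncol = band_w)
    band[cbind(round(p[, 2]), round(p[, 1]))] <- 0
    if (sum(band == 0) <= 0.6 * k) break
    ## very small writing shrinks in every dimension: first fewer/flatter
    ## oscillations, then a shorter written line
    if (f1 > 1.5 || amp_mm > 1) {
      f1 <- max(f1 * 0.72, 1.5)
      amp_mm <- max(amp_mm * 0.85, 1)
    } else if (span > 0.12) {
      span <- max(span * 0.8, 0.12)
    } else break
  }
  if (sum(band == 0) > k)
    stop_generation(sprintf(
      "row %d: target area %.2f mm^2 is below the thinnest drawable stroke at %g dpi",
      r, target_mm2, 25.4 / c_mm))

  ## distance transform -> k-th order statistic radius
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(t(band))))
  d <- as.vector(d)  # distances for all band pixels (0 on the polyline)
  if (k >= length(d))
    stop_generation(sprintf("row %d: target area %.1f mm^2 would overflow its row band",
                            r, target_mm2))
  ## grid distances are heavily tied (1, sqrt 2, 2, ...): take the full
  ## shell below the k-th distance, then top up deterministically from the
  ## tie shell so the stroke has exactly k ink pixels. Tie pixels are
  ## 4-connected to the stroke interior, so the stroke stays one component.
  r_th <- sort(d, partial = k)[k]
  mask_v <- d < r_th
  short <- k - sum(mask_v)
  if (short > 0) {
    shell <- which(d == r_th)
    mask_v[shell[seq_len(min(short, length(shell)))]] <- TRUE
  }
  realized_px <- sum(mask_v)
  realized_mm2 <- realized_px * c_mm^2
  if (abs(realized_mm2 - target_mm2) / target_mm2 > 0.02)
    stop_generation(sprintf(
      "row %d: cannot hit target area %.2f mm^2 (closest achievable %.2f mm^2); raise dpi or shrink the curve",
      r, target_mm2, realized_mm2))

  mask <- matrix(mask_v, nrow = band_w, ncol = band_h)  # EBImage x-major
  mask <- t(mask)
  sub <- page[ry0:ry1, lay$x0:(lay$x0 + band_w - 1L)]
  sub[mask] <- 0
  page[ry0:ry1, lay$x0:(lay$x0 + band_w - 1L)] <- sub

  ink_rows <- which(rowSums(mask) > 0)
  ink_cols <- which(colSums(mask) > 0)
  truth <- tibble::tibble(
    row_index = r,
    target_area_mm2 = target_mm2,
    realized_area_mm2 = realized_mm2,
    x0 = lay$x0 + min(ink_cols) - 2L,      # half-open, 0-based
    y0 = ry0 + min(ink_rows) - 2L,
    x1 = lay$x0 + max(ink_cols) - 1L,
    y1 = ry0 + max(ink_rows) - 1L
  )
  list(page = page, truth = truth)
}
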