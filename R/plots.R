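# ggplot2 visualisations.

#' Plot an ROC curve
#'
#' @param object An `hw_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: ROC curve with the chance diagonal and the
#'   Youden-optimal operating point marked.
#' @method autoplot hw_roc
#' @export
autoplot.hw_roc <- function(object, ...) {
  crv <- object$curve
  best <- youden(object)
  at <- crv[crv$threshold == best$criterion, ][1, ]
  ggplot2::ggplot(crv, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::geom_point(data = at, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %.2f, Youden J = %.2f (criterion %.2f)",
                      object$auc, object$youden_j, object$criterion)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation training curves
#'
#' @param object An `hw_cv` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot of per-fold loss and accuracy across epochs for the
#'   training and validation sets.
#' @method autoplot hw_cv
#' @export
autoplot.hw_cv <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(dplyr::matches("^(train|val)_"),
                        names_to = c("set", "metric"), names_sep = "_",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set,
                                     group = interaction(.data$set, .data$fold))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rendered page with its row boxes
#'
#' @param page An [hw_page()].
#' @param boxes Optional tibble of boxes (`x0, y0, x1, y1`), e.g. ground
#'   truth or [segment_rows()] output.
#' @param max_px Downsample the raster to roughly this many pixels on the
#'   long side before plotting.
#' @return A ggplot.
#' @export
plot_page <- function(page, boxes = NULL, max_px = 600) {
  stopifnot(inherits(page, "hw_page"))
  px <- page$pixels
  fac <- max(1L, ceiling(max(dim(px)) / max_px))
  px <- px[seq(1, nrow(px), by = fac), seq(1, ncol(px), by = fac), drop = FALSE]
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$v <- as.vector(t(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$v)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(boxes)) {
    b <- dplyr::mutate(boxes, dplyr::across(dplyr::all_of(c("x0", "y0", "x1", "y1")),
                                            ~ .x / fac))
    p <- p + ggplot2::geom_rect(
      data = b, inherit.aes = FALSE, colour = "red", fill = NA,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1,
                   ymin = .data$y0, ymax = .data$y1))
  }
  p
}
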