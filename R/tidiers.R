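# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC result into its curve points
#' @param x An `hw_roc`.
#' @param ... Unused.
#' @return Tibble of threshold/sensitivity/specificity points.
#' @method tidy hw_roc
#' @export
tidy.hw_roc <- function(x, ...) x$curve

#' One-row summary of an ROC result
#' @inheritParams tidy.hw_roc
#' @return Tibble with auc, youden_j, criterion and the operating metrics.
#' @method glance hw_roc
#' @export
glance.hw_roc <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(auc = x$auc, youden_j = x$youden_j,
                   criterion = x$criterion, positive = x$positive),
    dplyr::select(x$operating, -"youden_j"))
}

#' Tidy cross-validation results into patient scores
#' @param x An `hw_cv`.
#' @param ... Unused.
#' @return The per-patient likelihood-ratio tibble.
#' @method tidy hw_cv
#' @export
tidy.hw_cv <- function(x, ...) x$scores

#' One-row summary of a cross-validation run
#' @inheritParams tidy.hw_cv
#' @return Tibble with fold/instance counts, mean validation accuracy of
#'   the final epoch, and the patient-level AUC.
#' @method glance hw_cv
#' @export
glance.hw_cv <- function(x, ...) {
  final <- x$history |>
    dplyr::group_by(.data$fold) |>
    dplyr::filter(.data$epoch == max(.data$epoch)) |>
    dplyr::ungroup()
  tibble::tibble(
    folds = length(unique(x$folds$fold)),
    n_instances = nrow(x$oof),
    n_subjects = length(unique(x$oof$subject_id)),
    mean_val_accuracy = mean(final$val_accuracy),
    patient_auc = roc_curve(x$scores, class, lr)$auc
  )
}

#' Tidy a fitted scorer into its training history
#' @param x An `hw_scorer`.
#' @param ... Unused.
#' @return Per-epoch loss/accuracy tibble.
#' @method tidy hw_scorer
#' @export
tidy.hw_scorer <- function(x, ...) x$history
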