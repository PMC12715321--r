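#' Classifier configuration
#'
#' The default backbone is a small convolutional scorer trained from
#' scratch on CPU (one conv layer, average pooling, linear head); see the
#' methods vignette for the architecture. `pretrained_plugin` instead
#' treats a user-supplied function as a frozen feature extractor and
#' trains only the added linear head, the fine-tuning scheme used with
#' large pretrained backbones.
#'
#' @param backbone `"small_conv"` (default) or `"pretrained_plugin"`.
#' @param input_size Instance raster size `c(height, width)`; must match
#'   the preprocessing `target_size`.
#' @param n_filters,kernel_size,stride Conv layer shape (small_conv).
#' @param pool_grid Average-pooling grid `c(rows, cols)` over the conv map.
#' @param head_width Hidden units of the classification head; 0 = a
#'   single linear layer.
#' @param learning_rate,epochs,batch_size,momentum SGD settings.
#' @param folds Cross-validation folds (>= 2).
#' @param class_weights Inverse-frequency loss weighting (default on;
#'   the cohorts are imbalanced, 57 patients vs 25 controls).
#' @param feature_fun For `pretrained_plugin`: `function(raster) ->`
#'   numeric feature vector (frozen backbone).
#' @param seed Seed controlling weight init, batch order and folds.
#' @return An `hw_classifier_config`.
#' @export
classifier_config <- function(backbone = c("small_conv", "pretrained_plugin"),
                              input_size = c(32L, 128L),
                              n_filters = 8L, kernel_size = 5L, stride = 2L,
                              pool_grid = c(4L, 8L), head_width = 0L,
                              learning_rate = 0.1, epochs = 8L,
                              batch_size = 32L, momentum = 0.9,
                              folds = 5L, class_weights = TRUE,
                              feature_fun = NULL, seed = 1L) {
  backbone <- match.arg(backbone)
  folds <- as.integer(folds); epochs <- as.integer(epochs)
  if (folds < 2) stop_config("folds must be >= 2")
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (learning_rate <= 0) stop_config("learning_rate must be > 0")
  if (backbone == "pretrained_plugin" && !is.function(feature_fun))
    stop_config("pretrained_plugin requires a feature_fun(raster) function")
  structure(list(
    backbone = backbone, input_size = as.integer(input_size),
    n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
    stride = as.integer(stride), pool_grid = as.integer(pool_grid),
    head_width = as.integer(head_width), learning_rate = learning_rate,
    epochs = epochs, batch_size = as.integer(batch_size), momentum = momentum,
    folds = folds, class_weights = isTRUE(class_weights),
    feature_fun = feature_fun, seed = as.integer(seed)
  ), class = "hw_classifier_config")
}

#' Patient-disjoint stratified fold assignment
#'
#' Every instance of a subject shares that subject's fold, so no
#' identity ever appears in both a training and its validation set.
#' Subjects are stratified by their class (subjects contributing both
#' classes, as in an OFF-vs-ON design, form their own stratum) and dealt
#' round-robin after a seeded shuffle, so per-class fold sizes differ by
#' at most one subject.
#'
#' @param instances Instance tibble with `subject_id` and `class`.
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @return Tibble `subject_id`, `fold` (1-based).
#' @export
assign_folds <- function(instances, folds = 5L, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) stop_config("folds must be >= 2")
  subj <- instances |>
    dplyr::distinct(.data$subject_id, .data$class) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(stratum = if (dplyr::n() == 1) as.character(.data$class[[1]])
                     else "mixed", .groups = "drop")
  if (folds > nrow(subj))
    stop_config(sprintf("%d folds but only %d subjects", folds, nrow(subj)))
  if (folds < nrow(subj)) {
    ## leave-one-subject-out (folds == subjects) is always admissible;
    ## otherwise every pure class must fill all folds
    small <- subj |>
      dplyr::count(.data$stratum) |>
      dplyr::filter(.data$stratum != "mixed", .data$n < folds)
    if (nrow(small) > 0)
      stop_config(sprintf("class '%s' has %d subjects, fewer than %d folds",
                          small$stratum[[1]], small$n[[1]], folds))
  }
  with_seed(derive_seed(seed, "folds"), {
    offset <- 0L
    subj |>
      dplyr::group_by(.data$stratum) |>
      dplyr::group_modify(function(d, g) {
        d <- d[sample.int(nrow(d)), , drop = FALSE]
        ## continue the deal across strata so total fold sizes stay balanced
        d$fold <- ((offset + seq_len(nrow(d)) - 1L) %% folds) + 1L
        offset <<- (offset + nrow(d)) %% folds
        d
      }) |>
      dplyr::ungroup() |>
      dplyr::select("subject_id", "fold") |>
      dplyr::arrange(.data$subject_id)
  })
}

# instances -> model-ready per-sample inputs + targets
prepare_inputs <- function(instances, config, geom = NULL) {
  rasters <- instances$raster
  ok <- vapply(rasters, function(r)
    identical(dim(r), as.integer(config$input_size)), logical(1))
  if (!all(ok))
    stop_config("instance raster size does not match config input_size")
  if (config$backbone == "small_conv") {
    lapply(rasters, im2col, geom = geom)
  } else {
    lapply(rasters, function(r) {
      f <- config$feature_fun(r)
      if (!is.numeric(f)) stop_config("feature_fun must return a numeric vector")
      as.numeric(f)
    })
  }
}

class_targets <- function(class, levels) as.integer(class == levels[[2]])

#' Train a two-class scorer on one training set
#'
#' With the `small_conv` backbone all weights are trained from scratch;
#' with `pretrained_plugin` the frozen `feature_fun` supplies features
#' and only the linear head is fitted. Training is deterministic under
#' `seed`.
#'
#' @param instances Training instances (see [build_instances()]); both
#'   classes must be present.
#' @param config An [classifier_config()].
#' @param seed Training seed (weight init + batch order).
#' @return An `hw_scorer` with the fitted parameters and the per-epoch
#'   training history.
#' @export
train_fold <- function(instances, config = classifier_config(),
                       seed = config$seed) {
  stopifnot(inherits(config, "hw_classifier_config"))
  levels_ <- levels(instances$class)
  if (length(levels_) != 2) stop_config("class must be a 2-level factor")
  y <- class_targets(instances$class, levels_)
  if (length(unique(y)) < 2)
    stop_config("training set contains a single class")

  geom <- if (config$backbone == "small_conv")
    conv_geometry(config$input_size[1], config$input_size[2],
                  config$kernel_size, config$stride,
                  config$pool_grid[1], config$pool_grid[2]) else NULL
  inputs <- prepare_inputs(instances, config, geom)
  n_feat <- if (config$backbone == "small_conv")
    geom$G * config$n_filters else length(inputs[[1]])

  w <- rep(1, length(y))
  if (config$class_weights) {
    tab <- table(factor(y, levels = 0:1))
    w <- length(y) / (2 * as.numeric(tab[as.character(y)]))
  }

  fit <- with_seed(derive_seed(seed, "train"), {
    params <- net_init(n_feat, config, conv = config$backbone == "small_conv")
    net_train(inputs, y, w, params, config, geom = geom)
  })
  structure(list(params = fit$params, config = config, geom = geom,
                 levels = levels_, history = fit$history),
            class = "hw_scorer")
}

#' @export
print.hw_scorer <- function(x, ...) {
  cat(sprintf("<hw_scorer> %s, classes %s -> P(%s), %d epochs (final loss %.4f)\n",
              x$config$backbone, paste(x$levels, collapse = "/"),
              x$levels[[2]], nrow(x$history),
              tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Predict instance probabilities
#'
#' @param object An `hw_scorer`.
#' @param new_data Instance tibble with a `raster` list-column, or a bare
#'   list of rasters.
#' @param ... Unused.
#' @return Numeric vector of probabilities of the positive (second-level)
#'   class, one per instance; independent of batch order.
#' @export
predict.hw_scorer <- function(object, new_data, ...) {
  rasters <- if (is.data.frame(new_data)) new_data$raster else new_data
  inst <- tibble::tibble(raster = rasters)
  inputs <- prepare_inputs(inst, object$config, object$geom)
  vapply(inputs, function(inp) {
    feat <- if (object$config$backbone == "small_conv")
      conv_features(inp, object$params, object$geom) else inp
    sigmoid(head_forward(feat, object$params))
  }, numeric(1))
}

#' Patient-grouped cross-validated classification
#'
#' Trains one scorer per fold on the out-of-fold subjects and scores each
#' instance exactly once, with the model whose validation fold contains
#' its subject. Per-patient likelihood-ratio scores in \[0, 1\] are the
#' mean of the patient's held-out instance probabilities (for a
#' within-patient design such as OFF vs ON, per patient and class).
#'
#' @param instances Instance tibble from [build_instances()].
#' @param config An [classifier_config()].
#' @param seed Master seed: folds use `seed`, fold `f` trains with a
#'   seed derived from `seed` and `f`.
#' @return An `hw_cv` object: `oof` (per-instance out-of-fold
#'   probabilities), `scores` (per-patient LR), `folds`, `history`
#'   (per-fold, per-epoch train/validation loss and accuracy), `config`.
#' @export
cross_validate <- function(instances, config = classifier_config(),
                           seed = config$seed) {
  stopifnot(inherits(config, "hw_classifier_config"))
  fold_map <- assign_folds(instances, config$folds, seed)
  inst <- dplyr::left_join(instances, fold_map, by = "subject_id")

  geom <- if (config$backbone == "small_conv")
    conv_geometry(config$input_size[1], config$input_size[2],
                  config$kernel_size, config$stride,
                  config$pool_grid[1], config$pool_grid[2]) else NULL
  inputs <- prepare_inputs(inst, config, geom)
  y <- class_targets(inst$class, levels(inst$class))
  n_feat <- if (config$backbone == "small_conv")
    geom$G * config$n_filters else length(inputs[[1]])

  oof <- rep(NA_real_, nrow(inst))
  histories <- list()
  for (f in sort(unique(fold_map$fold))) {
    tr <- which(inst$fold != f)
    va <- which(inst$fold == f)
    if (length(unique(y[tr])) < 2)
      stop_config(sprintf("fold %d: training subjects cover a single class", f))
    w <- rep(1, length(tr))
    if (config$class_weights) {
      tab <- table(factor(y[tr], levels = 0:1))
      w <- length(tr) / (2 * as.numeric(tab[as.character(y[tr])]))
    }
    fit <- with_seed(derive_seed(seed, "train", f), {
      params <- net_init(n_feat, config, conv = config$backbone == "small_conv")
      net_train(inputs[tr], y[tr], w, params, config, geom = geom,
                val = list(inputs = inputs[va], y = y[va]))
    })
    oof[va] <- vapply(inputs[va], function(inp) {
      feat <- if (config$backbone == "small_conv")
        conv_features(inp, fit$params, geom) else inp
      sigmoid(head_forward(feat, fit$params))
    }, numeric(1))
    histories[[length(histories) + 1]] <-
      dplyr::mutate(fit$history, fold = f, .before = 1)
  }

  oof_tbl <- inst |>
    dplyr::select(-"raster") |>
    dplyr::mutate(prob = oof)
  scores <- oof_tbl |>
    dplyr::group_by(.data$subject_id, .data$class) |>
    dplyr::summarise(lr = mean(.data$prob), n_instances = dplyr::n(),
                     fold = .data$fold[[1]], .groups = "drop")

  structure(list(oof = oof_tbl, scores = scores, folds = fold_map,
                 history = dplyr::bind_rows(histories), config = config),
            class = "hw_cv")
}

#' @export
print.hw_cv <- function(x, ...) {
  cat(sprintf("<hw_cv> %d folds, %d instances, %d patient scores\n",
              length(unique(x$folds$fold)), nrow(x$oof), nrow(x$scores)))
  invisible(x)
}
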