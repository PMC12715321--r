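#' Configuration for a full pipeline run
#'
#' Validates all stage configurations up front (a run must fail before
#' any generation starts if, say, a class has fewer subjects than folds).
#'
#' @param out_dir Run directory; every stage writes beneath it.
#' @param n_per_group Named subject counts, e.g. `c(HS = 6, PD = 6)`.
#' @param comparison Classification comparison (see [build_instances()]).
#' @param generator An [generator_config()].
#' @param classifier An [classifier_config()].
#' @param artifacts `NULL` (clean pages) or [artifact_params()].
#' @param positive Positive class for the ROC (default: second level).
#' @param seeds Named list/vector with `generate`, `folds_train` seeds.
#' @param overwrite Allow overwriting an existing run directory.
#' @return An `hw_run_config`.
#' @export
run_config <- function(out_dir, n_per_group = c(HS = 6, PD = 6),
                       comparison = "HS_vs_PD",
                       generator = generator_config(),
                       classifier = classifier_config(),
                       artifacts = NULL, positive = NULL,
                       seeds = list(generate = 1L, folds_train = 2L),
                       overwrite = FALSE) {
  stopifnot(inherits(generator, "hw_generator_config"),
            inherits(classifier, "hw_classifier_config"))
  comparison <- match.arg(comparison, c("HS_vs_PD", "early_vs_mid", "OFF_vs_ON"))
  if (!is.null(artifacts)) stopifnot(inherits(artifacts, "hw_artifact_params"))
  ## fail fast: enough subjects per class for the fold count?
  n_class <- switch(comparison,
    HS_vs_PD = c(sum(n_per_group[names(n_per_group) == "HS"]),
                 sum(n_per_group[names(n_per_group) != "HS"])),
    early_vs_mid = {
      pd <- sum(n_per_group[names(n_per_group) != "HS"])
      c(ceiling(pd / 2), floor(pd / 2))
    },
    OFF_vs_ON = rep(sum(n_per_group[names(n_per_group) != "HS"]), 2)
  )
  if (comparison != "OFF_vs_ON" && any(n_class < classifier$folds))
    stop_config(sprintf(
      "comparison %s yields class sizes %s; each class needs >= %d subjects (folds)",
      comparison, paste(n_class, collapse = "/"), classifier$folds))
  structure(list(out_dir = out_dir, n_per_group = n_per_group,
                 comparison = comparison, generator = generator,
                 classifier = classifier, artifacts = artifacts,
                 positive = positive, seeds = seeds, overwrite = overwrite),
            class = "hw_run_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate -> preprocess -> metrics -> cross-validated
#' classification -> ROC -> report, writing every artifact (pages,
#' manifest, per-row metrics, per-subject summaries, out-of-fold
#' probabilities, patient LR scores, ROC points and report tables) plus
#' a machine-readable provenance record under one directory. Rerunning
#' with identical configuration reproduces all outputs.
#'
#' @param config An [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return An `hw_run` list with the run directory and all in-memory
#'   results (`manifest`, `metrics`, `micro`, `cv`, `roc`, `report`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "hw_run_config"))
  say <- function(stage, ...) if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  gen <- config$generator
  seeds <- config$seeds

  say("generate", "sampling %s subjects",
      paste(sprintf("%d %s", config$n_per_group, names(config$n_per_group)),
            collapse = " + "))
  profiles <- sample_subject_profiles(
    gen, config$n_per_group, seed = seeds$generate,
    pd_states = if (config$comparison == "OFF_vs_ON") c("OFF", "ON") else "OFF")
  manifest <- write_dataset(profiles, gen, file.path(out, "data"),
                            artifacts = config$artifacts,
                            overwrite = config$overwrite,
                            seed = seeds$generate)
  say("generate", "%d pages written", nrow(manifest))

  say("metrics", "measuring %d sheets", nrow(manifest))
  metrics <- measure_sheets(manifest, expected_rows = gen$rows_per_sheet)
  readr::write_csv(metrics, file.path(out, "row_metrics.csv"))
  micro <- summarize_micrographia(metrics, n_rows = gen$rows_per_sheet)
  readr::write_csv(micro, file.path(out, "micrographia_summary.csv"))

  say("train-cv", "building %s instances", config$comparison)
  instances <- build_instances(manifest, config$comparison,
                               expected_rows = gen$rows_per_sheet,
                               target_size = config$classifier$input_size)
  cv <- cross_validate(instances, config$classifier, seed = seeds$folds_train)
  readr::write_csv(cv$oof, file.path(out, "oof_probabilities.csv"))
  readr::write_csv(cv$scores, file.path(out, "patient_lr.csv"))
  readr::write_csv(cv$history, file.path(out, "training_history.csv"))

  say("roc", "patient-level ROC")
  roc <- roc_curve(cv$scores, class, lr, positive = config$positive)
  readr::write_csv(roc$curve, file.path(out, "roc_points.csv"))
  jsonlite::write_json(
    c(list(auc = roc$auc, youden_j = roc$youden_j, criterion = roc$criterion,
           positive = roc$positive), as.list(roc$operating)),
    file.path(out, "roc_metrics.json"), auto_unbox = TRUE, digits = NA)

  say("report", "summary tables")
  lr_by_subject <- cv$scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(lr = mean(.data$lr), .groups = "drop")
  report <- build_report(micro, lr_by_subject)
  readr::write_csv(report$group_summary, file.path(out, "report_group_summary.csv"))
  if (!is.null(report$comparisons))
    readr::write_csv(report$comparisons, file.path(out, "report_comparisons.csv"))
  if (!is.null(report$correlations))
    readr::write_csv(report$correlations, file.path(out, "report_correlations.csv"))

  provenance <- list(
    package = "micrographr",
    version = as.character(utils::packageVersion("micrographr")),
    r_version = R.version.string,
    comparison = config$comparison,
    n_per_group = as.list(config$n_per_group),
    seeds = config$seeds,
    generator = config$generator[setdiff(names(config$generator), "artifact_params")],
    classifier = config$classifier[setdiff(names(config$classifier), "feature_fun")],
    artifacts = if (is.null(config$artifacts)) "none" else unclass(config$artifacts)
  )
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  structure(list(dir = out, manifest = manifest, metrics = metrics,
                 micro = micro, cv = cv, roc = roc, report = report),
            class = "hw_run")
}

#' @export
print.hw_run <- function(x, ...) {
  cat(sprintf("<hw_run> %s\n", x$dir))
  print(x$roc)
  invisible(x)
}
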