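#' Sample synthetic subject profiles
#'
#' Draws one profile per subject: a base pen-stroke area (target mean ink
#' area of the first five rows, mm^2) and a sequence effect (target
#' last-five/first-five mean row-area ratio). Both are drawn from the
#' configured per-group normal distributions, truncated below at 10% of the
#' group mean so that large SDs cannot produce non-physical values.
#'
#' Subjects in any non-"HS" group are treated as patients: they receive a
#' disease stage (alternating `early` / `mid_advanced` so that uneven
#' cohort splits stay within one subject) and a medication state. Healthy
#' subjects carry `stage = "none"`, `state = "none"`.
#'
#' @param config An [generator_config()].
#' @param n_per_group Named integer vector, subjects per group, e.g.
#'   `c(HS = 25, PD = 57)`.
#' @param seed Seed for the draws (defaults to `config$seed`).
#' @param pd_states Medication states to instantiate for patient groups:
#'   `"OFF"` (default) or `c("OFF", "ON")`. With both states each patient
#'   appears twice (same id, different state); ON base areas are shifted by
#'   `config$on_area_shift_mm2`.
#' @return A tibble with columns `subject_id`, `group`, `stage`, `state`,
#'   `base_area_mm2`, `seq_effect`.
#' @export
sample_subject_profiles <- function(config, n_per_group, seed = config$seed,
                                    pd_states = "OFF") {
  stopifnot(inherits(config, "hw_generator_config"))
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop_config("n_per_group must be a named vector of subject counts")
  unknown <- setdiff(names(n_per_group), names(config$group_area_params))
  if (length(unknown) > 0)
    stop_config(sprintf("unknown group label(s): %s (configured: %s)",
                        paste(unknown, collapse = ", "),
                        paste(names(config$group_area_params), collapse = ", ")))
  if (!all(pd_states %in% c("OFF", "ON")) || length(pd_states) < 1)
    stop_config("pd_states must be a subset of c('OFF', 'ON')")

  with_seed(derive_seed(seed, "profiles"), {
    rows <- purrr::imap(as.list(n_per_group), function(n, grp) {
      n <- as.integer(n)
      if (n < 1) return(NULL)
      ap <- config$group_area_params[[grp]]
      sp <- config$group_seqeffect_params[[grp]]
      base <- rtrunc_normal(n, ap[[1]], ap[[2]], floor = 0.1 * ap[[1]])
      seqe <- rtrunc_normal(n, sp[[1]], sp[[2]], floor = 0.1 * sp[[1]])
      is_patient <- !identical(grp, "HS")
      tibble::tibble(
        subject_id = sprintf("%s%03d", grp, seq_len(n)),
        group = grp,
        stage = if (is_patient)
          rep(c("early", "mid_advanced"), length.out = n) else "none",
        state = if (is_patient) pd_states[[1]] else "none",
        base_area_mm2 = base,
        seq_effect = seqe
      )
    })
    out <- dplyr::bind_rows(rows)
    ## duplicate patients into the ON state when asked for both states
    if (length(pd_states) == 2) {
      on <- dplyr::filter(out, .data$group != "HS")
      if (nrow(on) > 0) {
        on$state <- "ON"
        on$base_area_mm2 <- pmax(on$base_area_mm2 + config$on_area_shift_mm2,
                                 0.1 * on$base_area_mm2)
        out <- dplyr::bind_rows(out, on)
      }
    }
    out
  })
}

# normal draw truncated below (rejection sampling; exact for sd = 0)
rtrunc_normal <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= floor])
  }
  out[seq_len(n)]
}
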