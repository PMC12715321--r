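# Shared fixtures, built in code at test time.

# Low-resolution config for fast round trips; parameters otherwise default.
test_config <- function(dpi = 120, tasks = 1, ...) {
  generator_config(dpi = dpi, tasks_per_subject = tasks, ...)
}

# Strongly separated cohorts for classifier sanity runs. The default group
# distributions overlap; these do not, by construction.
separated_config <- function(dpi = 100, tasks = 1) {
  generator_config(
    dpi = dpi, tasks_per_subject = tasks,
    group_area_params = list(HS = c(mean = 130, sd = 12),
                             PD = c(mean = 70, sd = 10)),
    group_seqeffect_params = list(HS = c(mean = 1.05, sd = 0.05),
                                  PD = c(mean = 0.85, sd = 0.05))
  )
}

# Toy instance tibble with two trivially separable ink patterns:
# class "A" has an ink block in the left quarter, class "B" in the right.
toy_instances <- function(n_subjects = 10, per_subject = 4,
                          size = c(32L, 128L), seed = 42,
                          shuffle_labels = FALSE) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cls <- if (s <= n_subjects / 2) "A" else "B"
    for (i in seq_len(per_subject)) {
      r <- matrix(0, size[1], size[2])
      xs <- if (cls == "A") 1:(size[2] %/% 4) else (3 * size[2] %/% 4):size[2]
      r[8:24, xs] <- 0.8 + 0.2 * matrix(runif(17 * length(xs)), 17)
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = sprintf("S%02d", s), task_id = "toy", row_index = i,
        class = cls, raster = list(r), mm_per_px = 0.2
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  lev <- c("A", "B")
  if (shuffle_labels) {
    set.seed(seed + 1)
    subj <- unique(out$subject_id)
    newlab <- setNames(sample(rep(lev, length.out = length(subj))), subj)
    out$class <- unname(newlab[out$subject_id])
  }
  out$class <- factor(out$class, levels = lev)
  out
}

# Render one subject's sheet and return page + truth.
render_one <- function(base_area = 100, seq_effect = 0.92, cfg = test_config(),
                       seed = 11) {
  profile <- tibble::tibble(subject_id = "T001", group = "PD", stage = "early",
                            state = "OFF", base_area_mm2 = base_area,
                            seq_effect = seq_effect)
  render_sheet(profile, "sentence", cfg, seed = seed)
}

# Brute-force AUC: exhaustive pairwise rank statistic.
auc_rank_oracle <- function(pos, neg) {
  grid <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(grid)
}
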