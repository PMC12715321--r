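# Synthetic sheet generator: profile sampling, area targeting, artifacts,
# dataset writing.

test_that("profile sampling follows the configured group distributions", {
  cfg <- test_config()

  # degenerate SD: every profile carries exactly the group mean
  cfg0 <- generator_config(
    group_area_params = list(HS = c(mean = 126.72, sd = 0)),
    group_seqeffect_params = list(HS = c(mean = 1.05, sd = 0)))
  p0 <- sample_subject_profiles(cfg0, c(HS = 5))
  expect_equal(p0$base_area_mm2, rep(126.72, 5))
  expect_equal(p0$seq_effect, rep(1.05, 5))

  # large-n sample mean within 3 SE of the configured mean
  p <- sample_subject_profiles(cfg, c(HS = 1000), seed = 123)
  se <- 44.85 / sqrt(1000)
  expect_lt(abs(mean(p$base_area_mm2) - 126.72), 3 * se + 1)  # +truncation bias
  expect_true(all(p$base_area_mm2 >= 0.1 * 126.72))

  # reproducible under seed, distinct across seeds
  expect_identical(sample_subject_profiles(cfg, c(HS = 5, PD = 5), seed = 9),
                   sample_subject_profiles(cfg, c(HS = 5, PD = 5), seed = 9))
  expect_false(identical(
    sample_subject_profiles(cfg, c(HS = 5), seed = 9)$base_area_mm2,
    sample_subject_profiles(cfg, c(HS = 5), seed = 10)$base_area_mm2))

  # stage/state bookkeeping: patients staged, controls not
  pp <- sample_subject_profiles(cfg, c(HS = 2, PD = 3), seed = 1)
  expect_setequal(pp$stage[pp$group == "PD"], c("early", "mid_advanced"))
  expect_true(all(pp$stage[pp$group == "HS"] == "none"))

  expect_error(sample_subject_profiles(cfg, c(XX = 3)),
               class = "micrographr_config_error")
  expect_error(sample_subject_profiles(cfg, c(3, 4)),
               class = "micrographr_config_error")
})

test_that("row decay profile encodes the sequence effect by construction", {
  expect_equal(row_decay_profile(1, 10), rep(1, 10))
  g <- row_decay_profile(0.9, 10)
  expect_equal(mean(g[6:10]) / mean(g[1:5]), 0.9)
  expect_equal(mean(g[1:5]), 1)
  g2 <- row_decay_profile(1.2, 8)
  expect_equal(mean(g2[5:8]) / mean(g2[1:4]), 1.2)
  expect_error(row_decay_profile(0), class = "micrographr_config_error")
})

test_that("rendered sheets hit per-row target areas and record ground truth", {
  cfg <- test_config()
  res <- render_one(base_area = 110, seq_effect = 0.92, cfg = cfg)
  tt <- res$truth
  expect_equal(nrow(tt), 10)
  expect_true(all(abs(tt$realized_area_mm2 - tt$target_area_mm2) /
                    tt$target_area_mm2 <= 0.02))
  # realized areas reproduce the sequence effect by construction
  expect_equal(mean(tt$realized_area_mm2[6:10]) / mean(tt$realized_area_mm2[1:5]),
               0.92, tolerance = 0.005)
  # boxes ordered top to bottom and vertically disjoint
  expect_true(all(diff(tt$y0) > 0))
  expect_true(all(tt$y0[-1] >= tt$y1[-10]))
  # equal-target case: seq_effect 1 gives equal targets
  res1 <- render_one(base_area = 100, seq_effect = 1, cfg = cfg)
  expect_equal(res1$truth$target_area_mm2, rep(100, 10))
})

test_that("round trip: metrics module recovers rendered row areas within 2%", {
  cfg <- test_config()
  for (par in list(c(126.72, 1.05), c(89.78, 0.92))) {
    res <- render_one(base_area = par[1], seq_effect = par[2], cfg = cfg,
                      seed = round(par[1]))
    m <- measure_page(res$page, expected_rows = 10)
    expect_true(all(abs(m$ink_area_mm2 - res$truth$realized_area_mm2) /
                      res$truth$realized_area_mm2 <= 0.02))
    expect_equal(sequence_effect(m), par[2], tolerance = 0.02)
    expect_equal(consistent_micrographia(m), res$truth$realized_area_mm2[1],
                 tolerance = 0.02)
  }
})

test_that("realized ink pixels increase strictly with base area", {
  cfg <- test_config()
  a <- render_one(base_area = 90, cfg = cfg, seed = 3)$truth$realized_area_mm2
  b <- render_one(base_area = 120, cfg = cfg, seed = 3)$truth$realized_area_mm2
  expect_true(all(b > a))
})

test_that("infeasible row targets raise a generation error naming the row", {
  cfg <- test_config()
  expect_error(render_one(base_area = 6000, cfg = cfg),
               regexp = "row 1", class = "micrographr_generation_error")
})

test_that("scan artifacts are bounded, ordered and deterministic", {
  cfg <- test_config()
  res <- render_one(cfg = cfg)

  # all-zero parameters: identity
  p0 <- artifact_params(0, 0, 0)
  expect_identical(add_scan_artifacts(res$page, p0, seed = 1)$pixels,
                   res$page$pixels)

  # determinism under seed
  pa <- artifact_params(1.5, 0.1, 0.02)
  a1 <- add_scan_artifacts(res$page, pa, seed = 7)
  a2 <- add_scan_artifacts(res$page, pa, seed = 7)
  expect_identical(a1$pixels, a2$pixels)
  a3 <- add_scan_artifacts(res$page, pa, seed = 8)
  expect_false(identical(a1$pixels, a3$pixels))
  expect_false(a1$rotation_deg == 0)

  # out-of-bounds parameters rejected
  expect_error(artifact_params(rotation_deg = 4), class = "micrographr_config_error")
  expect_error(artifact_params(illum_frac = 0.5), class = "micrographr_config_error")
  expect_error(artifact_params(noise_sd = 0.2), class = "micrographr_config_error")

  # robustness round trip: default artifacts, deskewed measurement within 5%
  art <- add_scan_artifacts(res$page, artifact_params(), seed = 21)
  m <- measure_page(deskew_page(art), expected_rows = 10)
  expect_true(all(abs(m$ink_area_mm2 - res$truth$realized_area_mm2) /
                    res$truth$realized_area_mm2 <= 0.05))
})

test_that("write_dataset writes one page per subject-task with a manifest", {
  cfg <- test_config(dpi = 80, tasks = 2)
  prof <- sample_subject_profiles(cfg, c(HS = 1, PD = 1), seed = 2)
  dir <- withr::local_tempdir()
  man <- write_dataset(prof, cfg, dir)
  expect_equal(nrow(man), 4)  # 2 subjects x 2 tasks
  expect_true(all(file.exists(man$path)))
  expect_true(all(file.exists(man$truth_path)))
  expect_setequal(unique(man$task_id), c("sentence", "name"))

  # refuses to clobber, honours overwrite
  expect_error(write_dataset(prof, cfg, dir), class = "micrographr_config_error")
  man2 <- write_dataset(prof, cfg, dir, overwrite = TRUE)
  expect_identical(man$path, man2$path)

  # empty profile list: empty manifest, no page files
  dir2 <- withr::local_tempdir()
  man0 <- write_dataset(prof[0, ], cfg, dir2)
  expect_equal(nrow(man0), 0)
  expect_equal(length(list.files(file.path(dir2, "pages"))), 0)

  # ground truth JSON round-trips
  tt <- read_truth(man$truth_path[1])
  expect_equal(nrow(tt), cfg$rows_per_sheet)
  expect_true(all(abs(tt$realized_area_mm2 - tt$target_area_mm2) /
                    tt$target_area_mm2 <= 0.02))
})
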