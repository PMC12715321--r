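# Statistical reporting layer: group tests, Spearman correlations,
# report assembly.

long2 <- function(x, y, labels = c("g1", "g2"), ids = NULL) {
  d <- tibble::tibble(value = c(x, y),
                      group = rep(labels, c(length(x), length(y))))
  if (!is.null(ids)) d$id <- c(ids, ids)
  d
}

test_that("group tests match their textbook formulas on fixed vectors", {
  x <- c(5.1, 4.8, 6.0, 5.5, 5.9, 4.2)
  y <- c(3.9, 4.4, 4.1, 5.0, 3.5, 4.6)

  # equal-variance t statistic, computed from first principles
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  res <- compare_groups(long2(x, y), value, group)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$test, "unpaired_t")
  expect_equal(c(res$mean1, res$sd1), c(mean(x), sd(x)))

  # paired t equals one-sample t on differences
  resp <- compare_groups(long2(x, y, ids = letters[1:6]), value, group,
                         design = "paired", id = id)
  d <- x - y
  expect_equal(resp$statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)

  # Mann-Whitney U from the rank-sum definition
  resw <- compare_groups(long2(x, y), value, group, family = "rank")
  U_oracle <- sum(rank(c(x, y))[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  expect_equal(unname(resw$statistic), U_oracle)

  # chi-square on a 2x2 table with evenly split identical margins is 0
  d2 <- tibble::tibble(value = rep(c("f", "m"), 10),
                       group = rep(c("g1", "g2"), each = 10))
  resc <- compare_groups(d2, value, group, family = "categorical")
  expect_equal(resc$statistic, 0)
  expect_equal(resc$p_value, 1)
})

test_that("identical groups sit at the null centre", {
  x <- c(1, 2, 3, 4, 5)
  res <- compare_groups(long2(x, x), value, group)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("paired designs demand matched samples", {
  d <- tibble::tibble(value = c(1, 2, 3, 4, 5),
                      group = c("a", "a", "a", "b", "b"),
                      id = c("s1", "s2", "s3", "s1", "s2"))
  expect_error(compare_groups(d, value, group, design = "paired", id = id),
               class = "micrographr_config_error")
  expect_error(compare_groups(d, value, group, design = "paired"),
               class = "micrographr_config_error")
})

test_that("type-I error of the tests is near nominal under the null", {
  set.seed(2024)
  n_rep <- 1000
  p_t <- p_w <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(19); y <- rnorm(15)
    d <- long2(x, y)
    p_t[i] <- compare_groups(d, value, group)$p_value
    p_w[i] <- compare_groups(d, value, group, family = "rank")$p_value
  }
  mc3 <- 3 * sqrt(0.05 * 0.95 / n_rep)  # three Monte-Carlo SEs
  expect_lt(abs(mean(p_t < 0.05) - 0.05), mc3 + 0.005)
  expect_lt(abs(mean(p_w < 0.05) - 0.05), mc3 + 0.005)
})

test_that("group separation at the study's area distributions is detectable", {
  set.seed(11)
  rejections <- 0L
  for (i in 1:200) {
    hs <- rnorm(19, 126.72, 44.85)
    pd <- rnorm(15, 89.78, 26.37)
    p <- compare_groups(long2(hs, pd, c("HS", "PD")), value, group)$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_gt(rejections / 200, 0.5)  # power well above the 5% level
})

test_that("Spearman correlation is monotone-invariant with tie handling", {
  d <- tibble::tibble(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6))
  expect_equal(correlate(d, a, b)$spearman_rho, 1)
  d$b <- -d$a^3
  expect_equal(correlate(d, a, b)$spearman_rho, -1)
  # rho via rank transform + product-moment formula, average ranks for ties
  set.seed(5)
  d2 <- tibble::tibble(a = sample(1:4, 20, TRUE), b = sample(1:4, 20, TRUE))
  expect_equal(correlate(d2, a, b)$spearman_rho,
               cor(rank(d2$a), rank(d2$b)), tolerance = 1e-12)
  expect_warning(out <- correlate(tibble::tibble(a = c(1, 1, 1), b = 1:3), a, b),
                 regexp = "undefined")
  expect_true(is.na(out$spearman_rho))
  expect_error(correlate(tibble::tibble(a = 1:2, b = 1:2), a, b),
               class = "micrographr_config_error")
})

test_that("LR correlates negatively with sequence effect when shrinkage drives it", {
  set.seed(9)
  seq_eff <- runif(30, 0.6, 1.2)
  lr <- 1 - seq_eff + rnorm(30, 0, 0.05)  # more shrinkage -> higher LR
  out <- correlate(tibble::tibble(lr = lr, seq_eff = seq_eff), lr, seq_eff)
  expect_lt(out$spearman_rho, -0.8)
  expect_lt(out$p_value, 0.01)
})

test_that("the report assembles summaries, tests and correlations", {
  set.seed(1)
  micro <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:20),
    group = rep(c("HS", "PD"), each = 10),
    consistent_area_mm2 = c(rnorm(10, 120, 10), rnorm(10, 90, 10)),
    sequence_effect = c(rnorm(10, 1.05, 0.05), rnorm(10, 0.9, 0.05)))
  scores <- tibble::tibble(subject_id = micro$subject_id,
                           lr = c(runif(10, 0, 0.4), runif(10, 0.6, 1)))
  rep1 <- build_report(micro, scores)
  expect_equal(nrow(rep1$group_summary), 4)  # 2 variables x 2 groups
  expect_equal(nrow(rep1$comparisons), 2)
  expect_equal(nrow(rep1$correlations), 2)
  expect_equal(rep1$comparisons$test, rep("unpaired_t", 2))

  # deterministic: regenerating from the same inputs is identical
  expect_identical(rep1, build_report(micro, scores))

  # single group: summaries only
  rep2 <- build_report(dplyr::filter(micro, group == "HS"))
  expect_null(rep2$comparisons)
  expect_null(rep2$correlations)

  # orphan scores are an error naming the subject
  bad <- dplyr::bind_rows(scores, tibble::tibble(subject_id = "ZZ99", lr = 0.5))
  expect_error(build_report(micro, bad), regexp = "ZZ99")
})
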