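# Fold assignment, the small conv scorer, and patient-grouped CV.

test_that("fold assignment is patient-disjoint and stratified", {
  inst <- toy_instances(n_subjects = 10, per_subject = 3)
  fa <- assign_folds(inst, folds = 5, seed = 1)
  expect_equal(nrow(fa), 10)
  expect_equal(anyDuplicated(fa$subject_id), 0)  # one fold per subject
  by_class <- dplyr::left_join(dplyr::distinct(inst, subject_id, class), fa,
                               by = "subject_id")
  sizes <- table(by_class$class, by_class$fold)
  expect_true(all(sizes == 1))  # 5+5 subjects in 5 folds: 1 per class per fold

  # determinism and seed sensitivity
  expect_identical(fa, assign_folds(inst, 5, seed = 1))
  expect_false(identical(fa$fold, assign_folds(inst, 5, seed = 2)$fold))

  # too few subjects in a class
  expect_error(assign_folds(inst, folds = 6),
               class = "micrographr_config_error")
})

test_that("the 82-subject cohort splits into folds of 16-17 subjects", {
  subj <- tibble::tibble(
    subject_id = c(sprintf("HS%03d", 1:25), sprintf("PD%03d", 1:57)),
    class = factor(rep(c("HS", "PD"), c(25, 57)), levels = c("HS", "PD")))
  fa <- assign_folds(subj, folds = 5, seed = 3)
  sizes <- table(fa$fold)
  expect_setequal(as.integer(sizes), c(16, 17))
  per_class <- table(dplyr::left_join(subj, fa, by = "subject_id")$class,
                     fa$fold[match(subj$subject_id, fa$subject_id)])
  expect_true(all(abs(per_class["HS", ] - 5) <= 1))
  expect_true(all(per_class["PD", ] %in% c(11, 12)))
})

test_that("the small conv scorer fits a separable toy problem", {
  inst <- toy_instances(n_subjects = 10, per_subject = 4)
  cfg <- classifier_config(epochs = 5, seed = 11)
  fit <- train_fold(inst, cfg)
  hist <- tidy(fit)
  expect_equal(nrow(hist), 5)
  expect_lt(hist$train_loss[5], hist$train_loss[1])  # loss decreases
  expect_equal(hist$train_accuracy[5], 1)            # separable => perfect

  pr <- predict(fit, inst)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(mean(pr[inst$class == "B"]), mean(pr[inst$class == "A"]))

  # duplicated instance gets an identical probability; batch-order invariant
  pr2 <- predict(fit, inst[c(1, 1, 40), ])
  expect_equal(pr2[1], pr2[2])
  expect_equal(rev(predict(fit, inst[40:1, ])), pr)

  # determinism: identical seed and data give identical predictions
  fit2 <- train_fold(inst, cfg)
  expect_identical(predict(fit2, inst), pr)

  # single-class training set is refused
  expect_error(train_fold(dplyr::filter(inst, class == "A"), cfg),
               class = "micrographr_config_error")
  # wrong raster size is refused
  bad <- inst; bad$raster[[1]] <- matrix(0, 8, 8)
  expect_error(train_fold(bad, cfg), class = "micrographr_config_error")
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  tr <- toy_instances(n_subjects = 16, per_subject = 6, seed = 5,
                      shuffle_labels = TRUE)
  te <- toy_instances(n_subjects = 16, per_subject = 6, seed = 99,
                      shuffle_labels = TRUE)
  fit <- train_fold(tr, classifier_config(epochs = 4, seed = 2))
  acc <- mean((predict(fit, te) > 0.5) == (te$class == "B"))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("cross-validation scores each instance once, out of fold", {
  inst <- toy_instances(n_subjects = 10, per_subject = 4)
  cfg <- classifier_config(epochs = 4, folds = 5, seed = 6)
  cv <- cross_validate(inst, cfg)

  expect_equal(nrow(cv$oof), nrow(inst))
  expect_false(any(is.na(cv$oof$prob)))
  # every instance's scoring fold is its subject's fold (leakage-free)
  expect_equal(cv$oof$fold,
               cv$folds$fold[match(cv$oof$subject_id, cv$folds$subject_id)])

  # patient LR = mean of that subject's out-of-fold probabilities
  agg <- cv$oof |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(lr = mean(prob))
  expect_equal(cv$scores$lr[match(agg$subject_id, cv$scores$subject_id)], agg$lr)
  expect_true(all(cv$scores$lr >= 0 & cv$scores$lr <= 1))
  expect_true(all(cv$scores$n_instances == 4))

  # LR invariant to instance ordering
  cv2 <- cross_validate(inst[sample(nrow(inst)), ], cfg)
  expect_equal(dplyr::arrange(cv2$scores, subject_id)$lr,
               dplyr::arrange(cv$scores, subject_id)$lr)

  # history logs train and validation curves for every fold
  expect_setequal(unique(cv$history$fold), 1:5)
  expect_true(all(c("train_loss", "train_accuracy", "val_loss", "val_accuracy")
                  %in% names(cv$history)))
})

test_that("a constant frozen backbone collapses every LR to its fold's constant", {
  inst <- toy_instances(n_subjects = 8, per_subject = 3)
  cfg <- classifier_config(backbone = "pretrained_plugin",
                           feature_fun = function(r) c(1, 1),
                           epochs = 3, folds = 4, seed = 1)
  cv <- cross_validate(inst, cfg)
  # constant inputs: a fold's model scores every instance identically, so
  # each subject's LR equals their fold's constant probability
  spread <- cv$scores |>
    dplyr::group_by(fold) |>
    dplyr::summarise(spread = diff(range(lr)))
  expect_true(all(spread$spread < 1e-9))
  # balanced classes + inverse-frequency weighting: near-chance everywhere
  expect_true(all(abs(cv$scores$lr - 0.5) < 0.2))
})

test_that("leave-one-subject-out is the degenerate case of grouped CV", {
  inst <- toy_instances(n_subjects = 8, per_subject = 2)
  cfg <- classifier_config(epochs = 3, folds = 8, seed = 4)
  cv <- cross_validate(inst, cfg)
  expect_equal(sort(unique(cv$folds$fold)), 1:8)
  expect_equal(nrow(cv$scores), 8)
  expect_false(any(is.na(cv$oof$prob)))
})
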