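test_that("fold plans keep subjects whole and stratify classes", {
  co <- shared_cohort()
  plan <- make_fold_plan(co$subject_id, co$severity, k = 5, r = 4, seed = 31)
  # both knees of every subject share a fold, in every repeat
  for (j in seq_len(plan$r)) {
    knee_folds <- plan$assignment[co$subject_id, j]
    per_sub <- tapply(knee_folds, co$subject_id, function(f) length(unique(f)))
    expect_true(all(per_sub == 1))
  }

  # ten single-knee subjects into ten folds: one subject per fold (sparse
  # classes trigger the degraded-stratification warning)
  expect_warning(
    plan10 <- make_fold_plan(paste0("P", 1:10),
                             rep(c("KL01", "KL2", "KL34"), c(8, 1, 1)),
                             k = 10, r = 2, seed = 1),
    "stratification")
  for (j in 1:2) expect_setequal(plan10$assignment[, j], 1:10)

  expect_error(make_fold_plan(paste0("P", 1:5), rep("KL01", 5), k = 10, r = 1),
               class = "kneecast_config_error")
})

test_that("per-fold class proportions track the global distribution", {
  co <- label_cohort(simulate_cohort(generation_config(n_subjects = 500,
                                                       seed = 33)))
  plan <- make_fold_plan(co$subject_id, co$severity, k = 10, r = 3, seed = 7)
  global <- mean(co$severity == "KL01")
  for (j in seq_len(plan$r)) {
    knee_folds <- plan$assignment[co$subject_id, j]
    for (i in seq_len(plan$k)) {
      frac <- mean(co$severity[knee_folds == i] == "KL01")
      expect_lt(abs(frac - global), 0.10)
    }
  }
})

test_that("balanced accuracy matches hand-computed per-class recalls", {
  expect_equal(balanced_accuracy(diag(c(10, 10, 10))), 1)
  cm <- rbind(c(8, 2, 0), c(0, 6, 4), c(0, 0, 10))
  expect_equal(balanced_accuracy(cm), 0.8)
  # everything predicted into class 1 with balanced truth: one recall of 1
  all_first <- cbind(c(5, 5, 5), 0, 0)
  expect_equal(balanced_accuracy(all_first), 1 / 3)
  # a zero-support row is excluded from the mean
  cm0 <- rbind(c(4, 0, 0), c(0, 0, 0), c(0, 0, 6))
  expect_equal(balanced_accuracy(cm0), 1)
  expect_error(balanced_accuracy(matrix(0, 3, 3)),
               class = "kneecast_metric_error")
})

test_that("weighted F1 matches the brute-force oracle, including edge cases", {
  expect_equal(weighted_f1(diag(c(3, 2, 1))), 1)
  cm <- rbind(c(8, 2, 0), c(0, 6, 4), c(0, 0, 10))
  # frozen from the brute-force per-class computation
  expect_equal(weighted_f1(cm), 0.7962962962962963, tolerance = 1e-12)
  expect_equal(weighted_f1(cm), oracle_weighted_f1(cm), tolerance = 1e-15)
  # zero-support class contributes weight zero
  cm0 <- rbind(c(7, 1, 0), c(0, 0, 0), c(2, 0, 5))
  expect_equal(weighted_f1(cm0), oracle_weighted_f1(cm0), tolerance = 1e-15)
  expect_error(weighted_f1(matrix(0, 3, 3)), class = "kneecast_metric_error")
})

test_that("class distribution summary reports one-decimal percentages", {
  d <- class_distribution(c(KL01 = 950, KL2 = 140, KL34 = 132))
  expect_equal(d$pct, c(77.7, 11.5, 10.8))
  d2 <- class_distribution(severity_factor(rep(c("KL01", "KL34"), c(3, 1))))
  expect_equal(d2$pct, c(75, 0, 25))
})

test_that("an oracle learner scores perfectly in every cell", {
  co <- shared_cohort()
  truth <- stats::setNames(as.character(co$severity), rownames(co))
  oracle <- list(fit = function(x, y, seed) NULL,
                 predict = function(model, x) truth[rownames(x)])
  plan <- make_fold_plan(co$subject_id, co$severity, k = 5, r = 2, seed = 2)
  cv <- run_cv(co, "MERGED", plan = plan, learner = oracle, tag = "oracle")
  expect_true(all(cv$per_cell$wf1 == 1))
  expect_true(all(cv$per_cell$ba == 1))
  expect_equal(cv$failures, 0)
})

test_that("a majority-class learner sits at chance balanced accuracy", {
  co <- shared_cohort()
  majority <- list(fit = function(x, y, seed)
                     constant_classifier("KL01", severity_levels()),
                   predict = function(model, x) predict(model, x))
  plan <- make_fold_plan(co$subject_id, co$severity, k = 5, r = 2, seed = 3)
  cv <- run_cv(co, "MERGED", plan = plan, learner = majority, tag = "majority")
  expect_true(all(abs(cv$per_cell$ba - 1 / 3) < 1e-12))
})

test_that("per-cell metrics are reconstructable from stored confusions", {
  co <- shared_cohort()
  plan <- make_fold_plan(co$subject_id, co$severity, k = 4, r = 2, seed = 5)
  cv <- run_cv(co, "SD", balanced_ensemble_config(n_trees = 15, seed = 1), plan)
  for (cell in seq_len(nrow(cv$per_cell))) {
    cm <- cv$confusions[, , cell]
    expect_equal(cv$per_cell$wf1[cell], weighted_f1(cm), tolerance = 1e-12)
    expect_equal(cv$per_cell$ba[cell], balanced_accuracy(cm), tolerance = 1e-12)
    expect_equal(sum(cm), cv$per_cell$n_test[cell])
  }
  s <- summary(cv)
  expect_equal(s$n_cells, 8)
  expect_equal(sum(s$pooled_confusion),
               sum(cv$per_cell$n_test))
})

test_that("corrected t statistic reproduces its defining formulas", {
  set.seed(41)
  for (trial in 1:25) {
    k <- sample(3:10, 1); r <- sample(1:5, 1)
    x <- matrix(rnorm(k * r, sd = 0.05), k, r)
    n2 <- 20; n1 <- 180
    mine <- corrected_ttest_stat(as.numeric(x), k, r, n2 / n1)
    ref <- oracle_corrected_t(x, k, r, n1, n2)
    expect_equal(mine$t, ref$t, tolerance = 1e-12)
    expect_equal(mine$df, ref$df)
    # correction factor relative to the naive paired t statistic
    naive <- mean(x) / sqrt(stats::var(as.numeric(x)) / (k * r))
    shrink <- sqrt((1 / (k * r)) / (1 / (k * r) + n2 / n1))
    expect_equal(mine$t, naive * shrink, tolerance = 1e-12)
  }
  expect_equal(corrected_ttest_stat(numeric(250), 10, 25)$df, 249)
})

test_that("degenerate difference vectors are handled as documented", {
  z <- corrected_ttest_stat(rep(0, 20), 4, 5)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  expect_warning(w <- corrected_ttest_stat(rep(0.1, 20), 4, 5),
                 "degenerate")
  expect_equal(w$t, Inf); expect_equal(w$p, 0)
})

test_that("model comparison demands identical fold plans and complete cells", {
  co <- shared_cohort()
  plan <- make_fold_plan(co$subject_id, co$severity, k = 4, r = 2, seed = 6)
  plan2 <- make_fold_plan(co$subject_id, co$severity, k = 4, r = 2, seed = 66)
  oracle <- list(fit = function(x, y, seed) NULL,
                 predict = function(model, x) {
                   stats::setNames(as.character(co$severity),
                                   rownames(co))[rownames(x)]
                 })
  a <- run_cv(co, "MERGED", plan = plan, learner = oracle, tag = "a")
  b <- run_cv(co, "MERGED", plan = plan2, learner = oracle, tag = "b")
  expect_error(corrected_cv_ttest(a, b), class = "kneecast_pairing_error")

  b2 <- run_cv(co, "MERGED", plan = plan, learner = oracle, tag = "b2")
  tt <- corrected_cv_ttest(a, b2)
  expect_equal(tt$t, 0); expect_equal(tt$p, 1)
  expect_false(tt$significant)
  expect_equal(tt$df, 4 * 2 - 1)
})
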