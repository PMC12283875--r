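test_that("balanced bootstrap draws n_min per class with replacement", {
  labels <- factor(rep(c("A", "B"), c(90, 10)))
  set.seed(1)
  idx <- balanced_bootstrap(labels)
  expect_length(idx, 20)
  expect_equal(unname(table(labels[idx])), c(10L, 10L),
               ignore_attr = TRUE)

  even <- factor(rep(c("A", "B"), each = 5))
  set.seed(2)
  draws <- replicate(20, balanced_bootstrap(even))
  expect_true(all(apply(draws, 2, function(d) all(table(even[d]) == 5))))
  # with replacement: duplicates occur across repeated draws
  expect_true(any(apply(draws, 2, anyDuplicated) > 0))

  expect_error(balanced_bootstrap(factor(rep("A", 100))),
               class = "kneecast_degenerate_error")
})

test_that("the fitted ensemble honours its balance and size contracts", {
  set.seed(3)
  d <- make_imbalanced_blobs(120, 30)
  cfg <- balanced_ensemble_config(n_trees = 40, seed = 5)
  fit <- fit_ensemble(d$x, d$y, cfg)
  expect_equal(nrow(fit$sample_log), 40)
  expect_true(all(fit$sample_log == 30))
  expect_identical(fit$classes, c("maj", "min"))
})

test_that("fits are deterministic under the seed", {
  set.seed(4)
  d <- make_imbalanced_blobs(60, 20)
  probe <- data.frame(f1 = rnorm(30), f2 = rnorm(30))
  cfg <- balanced_ensemble_config(n_trees = 30, seed = 9)
  p1 <- predict_proba(fit_ensemble(d$x, d$y, cfg), probe)
  p2 <- predict_proba(fit_ensemble(d$x, d$y, cfg), probe)
  expect_identical(p1, p2)
  p3 <- predict_proba(
    fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 30, seed = 10)),
    probe)
  expect_false(identical(p1, p3))
})

test_that("a separable toy problem is learned perfectly on its training set", {
  x <- data.frame(f = c(seq(0, 1, length.out = 10), seq(3, 4, length.out = 10)))
  y <- factor(rep(c("lo", "hi"), each = 10), levels = c("hi", "lo"))
  fit <- fit_ensemble(x, y, balanced_ensemble_config(n_trees = 20, seed = 1))
  expect_equal(as.character(predict(fit, x)), as.character(y))
})

test_that("balancing protects minority-class recall on imbalanced blobs", {
  # paired comparison against an otherwise-identical ensemble with plain
  # (unbalanced) bootstraps, averaged over 10 seeds
  rec <- function(cm) cm["min", "min"] / sum(cm["min", ])
  diffs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    train <- make_imbalanced_blobs(180, 20)
    test <- make_imbalanced_blobs(90, 60)
    bal <- fit_ensemble(train$x, train$y,
                        balanced_ensemble_config(n_trees = 60, seed = s))
    unbal <- ranger::ranger(x = train$x, y = train$y, probability = TRUE,
                            num.trees = 60, mtry = 1, min.node.size = 1,
                            seed = s, num.threads = 1)
    p_b <- as.character(predict(bal, test$x))
    pr_u <- predict(unbal, data = test$x, num.threads = 1)$predictions
    p_u <- colnames(pr_u)[max.col(pr_u, ties.method = "first")]
    cm_b <- table(truth = test$y, pred = factor(p_b, levels(test$y)))
    cm_u <- table(truth = test$y, pred = factor(p_u, levels(test$y)))
    rec(cm_b) - rec(cm_u)
  }, numeric(1))
  expect_gte(mean(diffs), 0)
})

test_that("prediction scores are normalised and ties break to the first class", {
  set.seed(6)
  d <- make_imbalanced_blobs(50, 25)
  fit <- fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 25, seed = 2))
  probe <- data.frame(f1 = rnorm(40, 0.75), f2 = rnorm(40, 0.75))
  pr <- predict_proba(fit, probe)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  expect_identical(colnames(pr), fit$classes)

  # two identical feature points with opposite labels: every leaf holds both,
  # so the score is exactly 0.5/0.5 and the first class in the order wins
  tie <- fit_ensemble(data.frame(f = c(0, 0)),
                      factor(c("A", "B")),
                      balanced_ensemble_config(n_trees = 10, seed = 3))
  pr_tie <- predict_proba(tie, data.frame(f = 0.5))
  expect_equal(unname(pr_tie[1, ]), c(0.5, 0.5))
  expect_equal(as.character(predict(tie, data.frame(f = 0.5))), "A")
})

test_that("hard voting is available and agrees broadly with score averaging", {
  set.seed(8)
  d <- make_imbalanced_blobs(80, 40, shift = 3)
  soft <- fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 30, seed = 4))
  hard <- fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 30, seed = 4,
                                                          vote = "hard"))
  probe <- make_imbalanced_blobs(30, 30, shift = 3)$x
  agree <- mean(predict(soft, probe) == predict(hard, probe))
  expect_gt(agree, 0.9)
  expect_true(all(abs(rowSums(predict_proba(hard, probe)) - 1) < 1e-9))
})

test_that("validation errors name the offending columns", {
  x <- data.frame(a = c(1, NA, 3), b = 1:3)
  expect_error(fit_ensemble(x, factor(c("A", "B", "A"))),
               "a", class = "kneecast_validation_error")
  d <- make_imbalanced_blobs(30, 10)
  fit <- fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 5, seed = 1))
  expect_error(predict_proba(fit, data.frame(f1 = 1)), "f2",
               class = "kneecast_schema_error")
  expect_error(fit_ensemble(d$x, factor(rep("A", 40))),
               class = "kneecast_degenerate_error")
})

test_that("class-balanced sampling agrees with an independent implementation", {
  # independent reference: ranger's internal class-wise sample.fraction path,
  # which implements balanced sampling without our bootstrap code
  set.seed(12)
  train <- make_imbalanced_blobs(150, 50)
  test <- make_imbalanced_blobs(100, 100)
  mine <- fit_ensemble(train$x, train$y,
                       balanced_ensemble_config(n_trees = 200, seed = 3))
  n_min <- min(table(train$y))
  ref <- ranger::ranger(x = train$x, y = train$y, probability = TRUE,
                        num.trees = 200, mtry = 1, min.node.size = 1,
                        replace = TRUE,
                        sample.fraction = rep(n_min / length(train$y), 2),
                        seed = 3, num.threads = 1)
  cm_mine <- table(test$y, predict(mine, test$x))
  pr_ref <- predict(ref, data = test$x, num.threads = 1)$predictions
  p_ref <- colnames(pr_ref)[max.col(pr_ref, ties.method = "first")]
  cm_ref <- table(test$y, factor(p_ref, levels(test$y)))
  expect_lt(abs(oracle_balanced_accuracy(cm_mine) -
                  oracle_balanced_accuracy(cm_ref)), 0.05)
})

test_that("model archives round-trip through save/load", {
  set.seed(13)
  d <- make_imbalanced_blobs(40, 20)
  fit <- fit_ensemble(d$x, d$y, balanced_ensemble_config(n_trees = 10, seed = 1))
  f <- tempfile(fileext = ".rds")
  save_model(fit, f)
  back <- load_model(f)
  probe <- make_imbalanced_blobs(10, 10)$x
  expect_identical(predict_proba(back, probe), predict_proba(fit, probe))
  saveRDS(list(oops = 1), f)
  expect_error(load_model(f), class = "kneecast_validation_error")
})
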