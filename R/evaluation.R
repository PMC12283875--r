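# Evaluation protocol ----------------------------------------------------------
#
# Subject-grouped stratified k-fold cross-validation repeated r times,
# imbalance-aware metrics computed from per-cell confusion matrices, and the
# corrected repeated k-fold CV t-test for comparing two models on the same
# fold plan.

#' Build a subject-grouped stratified repeated fold plan
#'
#' Subjects (never individual knees) are assigned to folds, so both knees of
#' a person always share a fold and no person's data is ever split between
#' train and test. Stratification is on a subject-level label - the
#' maximum-severity class over the subject's knees - so per-fold class
#' proportions approximate the cohort's. The default protocol is 10 folds
#' repeated 25 times.
#'
#' @param subject_ids knee-level subject identifiers.
#' @param labels knee-level severity labels (same length).
#' @param k number of folds (default 10).
#' @param r number of repeats (default 25).
#' @param seed integer seed.
#' @return Object of class \code{fold_plan}: \code{subjects},
#'   \code{assignment} (subjects x repeats integer fold matrix), \code{k},
#'   \code{r}, \code{seed}.
#' @export
make_fold_plan <- function(subject_ids, labels, k = 10, r = 25, seed = 1L) {
  labels <- severity_factor(labels)
  stopifnot(length(subject_ids) == length(labels))
  subjects <- unique(subject_ids)
  if (length(subjects) < k) {
    stop_kneecast("need at least k=%d subjects, have %d", k, length(subjects),
                  class = "kneecast_config_error")
  }
  # subject-level stratification label: the subject's worst knee
  subj_label <- vapply(split(as.integer(labels), subject_ids), max, numeric(1))
  subj_label <- factor(severity_levels()[subj_label[subjects]],
                       levels = severity_levels())
  if (any(table(subj_label) > 0 & table(subj_label) < k)) {
    warning("some classes have fewer subjects than folds; stratification degraded")
  }

  set.seed(derive_seed(seed, "fold-plan"))
  assignment <- matrix(NA_integer_, length(subjects), r,
                       dimnames = list(subjects, NULL))
  for (j in seq_len(r)) {
    # shuffle within each stratum, concatenate strata, then deal one shared
    # round-robin over the whole cohort: consecutive members of a stratum land
    # in distinct folds (stratification) while fold sizes stay globally equal
    order_all <- unlist(lapply(levels(subj_label), function(cl) {
      members <- which(subj_label == cl)
      members[sample.int(length(members))]
    }), use.names = FALSE)
    assignment[order_all, j] <- rep_len(sample.int(k), length(order_all))
  }
  structure(list(subjects = subjects, assignment = assignment,
                 subject_label = subj_label, k = as.integer(k),
                 r = as.integer(r), seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d subjects, %d folds x %d repeats (seed %d)\n",
              length(x$subjects), x$k, x$r, x$seed))
  invisible(x)
}

plan_signature <- function(plan) {
  list(k = plan$k, r = plan$r, seed = plan$seed,
       n_subjects = length(plan$subjects))
}

#' Balanced accuracy from a confusion matrix
#'
#' Unweighted mean of per-class recalls (confusion diagonal over true-class
#' row totals). True classes with zero support are excluded from the mean.
#'
#' @param confusion square numeric matrix, rows = truth, columns = predicted.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  supports <- rowSums(confusion)
  if (sum(confusion) == 0) {
    stop_kneecast("balanced accuracy undefined on an all-zero confusion matrix",
                  class = "kneecast_metric_error")
  }
  keep <- supports > 0
  mean(diag(confusion)[keep] / supports[keep])
}

#' Support-weighted F1 from a confusion matrix
#'
#' Per-class F1 (harmonic mean of precision and recall, defined as 0 when
#' precision + recall is 0) averaged with weights equal to true-class supports
#' over the total count; a class with zero support has weight zero.
#'
#' @inheritParams balanced_accuracy
#' @export
weighted_f1 <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) {
    stop_kneecast("weighted F1 undefined on an all-zero confusion matrix",
                  class = "kneecast_metric_error")
  }
  supports <- rowSums(confusion)
  predicted <- colSums(confusion)
  tp <- diag(confusion)
  recall <- ifelse(supports > 0, tp / supports, 0)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  sum(supports / total * f1)
}

#' Outcome class distribution summary
#'
#' Per-class counts and percentages (one-decimal rounding), the summary
#' printed for a cohort's outcome imbalance.
#'
#' @param x severity labels, or a named vector of per-class counts.
#' @return \code{data.frame} with \code{class}, \code{n}, \code{pct}.
#' @export
class_distribution <- function(x) {
  counts <- if (is.numeric(x)) x else table(severity_factor(x))
  if (is.null(names(counts))) names(counts) <- severity_levels()
  data.frame(class = names(counts), n = as.integer(counts),
             pct = round(100 * as.numeric(counts) / sum(counts), 1),
             row.names = NULL)
}

# default learner: the balanced-forest cascade with a per-cell seed substream
cascade_learner <- function(config) {
  list(fit = function(x, y, cell_seed) {
         cfg <- config
         cfg$seed <- cell_seed
         fit_cascade(x, y, cfg)
       },
       predict = function(model, x) predict_cascade(model, x))
}

#' Run the repeated grouped stratified cross-validation protocol
#'
#' For every (repeat, fold) cell: fit the cascade on the training folds'
#' knees, predict the held-out fold, and store the 3x3 confusion matrix.
#' Per-cell weighted F1 and balanced accuracy are derived from the stored
#' confusion matrices (single source of truth). Train and test subject sets
#' are asserted disjoint in every cell. A cell whose training folds lack a
#' stage-2 class is recorded as a failure and the run continues.
#'
#' @param cohort labeled cohort (a \code{severity} column; see
#'   \code{\link{label_cohort}}).
#' @param preset predictor preset passed to \code{\link{select_predictors}}.
#' @param config \code{\link{balanced_ensemble_config}} for the cascade
#'   stages.
#' @param plan a \code{\link{make_fold_plan}} result.
#' @param learner optional override: a list with \code{fit(x, y, cell_seed)}
#'   and \code{predict(model, x)}; defaults to the balanced-forest cascade.
#' @param tag short model tag stored with the result.
#' @return Object of class \code{cv_result}: \code{per_cell} data frame
#'   (repeat, fold, n_train, n_test, wf1, ba), \code{confusions} (3x3xcells
#'   array), \code{failures}, \code{plan_signature}, \code{tag}.
#' @export
run_cv <- function(cohort, preset = "MERGED",
                   config = balanced_ensemble_config(), plan,
                   learner = NULL, tag = preset) {
  stopifnot(inherits(plan, "fold_plan"))
  if (!"severity" %in% names(cohort)) cohort <- label_cohort(cohort)
  y <- severity_factor(cohort$severity)
  features <- select_predictors(cohort, preset)
  learner <- learner %||% cascade_learner(config)
  subj <- as.character(cohort$subject_id)
  missing_subj <- setdiff(subj, plan$subjects)
  if (length(missing_subj)) {
    stop_kneecast("fold plan does not cover subject(s): %s",
                  paste(utils::head(missing_subj, 5), collapse = ", "),
                  class = "kneecast_config_error")
  }

  n_cells <- plan$k * plan$r
  per_cell <- data.frame(rep = rep(seq_len(plan$r), each = plan$k),
                         fold = rep(seq_len(plan$k), plan$r),
                         n_train = NA_integer_, n_test = NA_integer_,
                         wf1 = NA_real_, ba = NA_real_)
  confusions <- array(NA_real_, c(3, 3, n_cells),
                      dimnames = list(truth = severity_levels(),
                                      predicted = severity_levels(), NULL))
  failures <- 0L
  cell <- 0L
  for (j in seq_len(plan$r)) {
    fold_of_subj <- plan$assignment[, j]
    knee_fold <- fold_of_subj[subj]
    for (i in seq_len(plan$k)) {
      cell <- cell + 1L
      test <- knee_fold == i
      train <- !test
      stopifnot(length(intersect(subj[train], subj[test])) == 0)
      per_cell$n_train[cell] <- sum(train)
      per_cell$n_test[cell] <- sum(test)
      if (!any(test)) { failures <- failures + 1L; next }
      fit <- tryCatch(
        list(model = learner$fit(
          features[train, , drop = FALSE], y[train],
          derive_seed(config$seed, sprintf("cell-%d-%d", j, i)))),
        kneecast_degenerate_error = function(e) e)
      if (inherits(fit, "condition")) { failures <- failures + 1L; next }
      fit <- fit$model
      pred <- severity_factor(
        learner$predict(fit, features[test, , drop = FALSE]))
      cm <- table(truth = y[test], predicted = pred)
      confusions[, , cell] <- cm
      per_cell$wf1[cell] <- weighted_f1(cm)
      per_cell$ba[cell] <- balanced_accuracy(cm)
    }
  }
  structure(list(per_cell = per_cell, confusions = confusions,
                 failures = failures, plan_signature = plan_signature(plan),
                 tag = tag),
            class = "cv_result")
}

#' Summarise a cross-validation result
#'
#' Mean and SD of weighted F1 and balanced accuracy across all k*r cells, the
#' same aggregated per repeat (mean of fold means), and the pooled confusion
#' matrix over all cells.
#'
#' @param object a \code{cv_result}.
#' @param ... unused.
#' @export
summary.cv_result <- function(object, ...) {
  pc <- object$per_cell
  ok <- !is.na(pc$wf1)
  rep_means <- stats::aggregate(pc[ok, c("wf1", "ba")],
                                by = list(rep = pc$rep[ok]), FUN = mean)
  out <- list(
    tag = object$tag,
    n_cells = sum(ok), failures = object$failures,
    wf1_mean = mean(pc$wf1[ok]), wf1_sd = stats::sd(pc$wf1[ok]),
    ba_mean = mean(pc$ba[ok]), ba_sd = stats::sd(pc$ba[ok]),
    wf1_mean_by_repeat = mean(rep_means$wf1),
    wf1_sd_by_repeat = stats::sd(rep_means$wf1),
    ba_mean_by_repeat = mean(rep_means$ba),
    ba_sd_by_repeat = stats::sd(rep_means$ba),
    pooled_confusion = apply(object$confusions[, , ok, drop = FALSE], c(1, 2),
                             sum))
  class(out) <- "summary.cv_result"
  out
}

#' @export
print.summary.cv_result <- function(x, ...) {
  cat(sprintf("CV summary [%s]: %d cells (%d failed)\n", x$tag, x$n_cells,
              x$failures))
  cat(sprintf("  WF1 %.1f%% +/- %.1f%%   BA %.1f%% +/- %.1f%% (across cells)\n",
              100 * x$wf1_mean, 100 * x$wf1_sd, 100 * x$ba_mean, 100 * x$ba_sd))
  cat(sprintf("  WF1 %.1f%% +/- %.1f%%   BA %.1f%% +/- %.1f%% (across repeat means)\n",
              100 * x$wf1_mean_by_repeat, 100 * x$wf1_sd_by_repeat,
              100 * x$ba_mean_by_repeat, 100 * x$ba_sd_by_repeat))
  cat("  pooled confusion (truth x predicted):\n")
  print(x$pooled_confusion)
  invisible(x)
}

#' Corrected repeated k-fold CV t statistic (low level)
#'
#' The variance-corrected paired statistic on per-cell metric differences
#' \code{x}: \code{t = m / sqrt((1/(k r) + n2/n1) * sigma2)} with
#' \code{m = mean(x)}, \code{sigma2 = sum((x - m)^2) / (k r - 1)} and
#' \code{df = k r - 1}. The \code{n2/n1} variance-inflation term accounts for
#' the overlap of training sets across folds.
#'
#' @param x numeric vector (or k x r matrix) of per-cell differences.
#' @param k,r folds and repeats; \code{length(x)} must equal \code{k * r}.
#' @param n2_over_n1 test/train instance-count ratio; the nominal value for
#'   k-fold CV is \code{1 / (k - 1)}.
#' @return List with \code{m}, \code{sigma2}, \code{t}, \code{df}, \code{p}
#'   (two-tailed).
#' @export
corrected_ttest_stat <- function(x, k, r, n2_over_n1 = 1 / (k - 1)) {
  x <- as.numeric(x)
  if (length(x) != k * r) {
    stop_kneecast("x has %d cells, expected k*r = %d", length(x), k * r,
                  class = "kneecast_validation_error")
  }
  df <- k * r - 1
  m <- mean(x)
  sigma2 <- sum((x - m)^2) / df
  if (sigma2 == 0) {
    if (m == 0) {
      t <- 0; p <- 1
    } else {
      warning("degenerate variance (all cell differences identical, nonzero)")
      t <- sign(m) * Inf; p <- 0
    }
  } else {
    t <- m / sqrt((1 / (k * r) + n2_over_n1) * sigma2)
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(m = m, sigma2 = sigma2, t = t, df = df, p = p)
}

#' Compare two cross-validated models with the corrected CV t-test
#'
#' Paired comparison of two \code{cv_result}s evaluated on the identical fold
#' plan. Per-cell differences \code{x_ij = a_ij - b_ij} of the chosen metric
#' feed \code{\link{corrected_ttest_stat}}; significance is declared at
#' \code{alpha} (two-tailed, default 0.01).
#'
#' @param a,b \code{cv_result}s from \code{\link{run_cv}} on the same plan.
#' @param metric \code{"wf1"} or \code{"ba"}.
#' @param alpha significance level (two-tailed).
#' @param n2_over_n1 \code{"nominal"} uses \code{1/(k-1)}; \code{"exact"} uses
#'   the mean observed per-cell test/train count ratio.
#' @return Object of class \code{corrected_cv_ttest}.
#' @export
corrected_cv_ttest <- function(a, b, metric = c("wf1", "ba"), alpha = 0.01,
                               n2_over_n1 = c("nominal", "exact")) {
  metric <- match.arg(metric)
  n2_over_n1 <- match.arg(n2_over_n1)
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (!identical(a$plan_signature, b$plan_signature)) {
    stop_kneecast("cv results come from different fold plans; paired test needs identical folds",
                  class = "kneecast_pairing_error")
  }
  k <- a$plan_signature$k; r <- a$plan_signature$r
  xa <- a$per_cell[[metric]]; xb <- b$per_cell[[metric]]
  if (anyNA(xa) || anyNA(xb)) {
    stop_kneecast("cannot pair cells: failed CV cells present",
                  class = "kneecast_pairing_error")
  }
  ratio <- if (n2_over_n1 == "nominal") 1 / (k - 1) else {
    mean(a$per_cell$n_test / a$per_cell$n_train)
  }
  st <- corrected_ttest_stat(xa - xb, k, r, ratio)
  structure(c(st, list(k = k, r = r, n2_over_n1 = ratio, metric = metric,
                       alpha = alpha, significant = st$p < alpha,
                       tags = c(a$tag, b$tag))),
            class = "corrected_cv_ttest")
}

#' @export
print.corrected_cv_ttest <- function(x, ...) {
  cat(sprintf("Corrected repeated %d-fold CV t-test (%d repeats) on %s: %s vs %s\n",
              x$k, x$r, x$metric, x$tags[1], x$tags[2]))
  cat(sprintf("  mean diff %+.4f, t = %.3f, df = %d, p = %.3g (alpha = %.2g): %s\n",
              x$m, x$t, x$df, x$p, x$alpha,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
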