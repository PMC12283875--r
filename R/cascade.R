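# Two-stage ordinal cascade ---------------------------------------------------
#
# The severity prediction model: the three-class ordinal task is split along
# the KL ordering into two binary tasks. Stage 1 separates healthy (KL01)
# knees from progressed ones; only knees predicted as progressed reach stage
# 2, which separates moderate (KL2) from severe (KL34). A knee predicted KL01
# at stage 1 is final - stage 2 is never consulted for it.

STAGE1_LEVELS <- c("KL01", "PROGRESSED")
STAGE2_LEVELS <- c("KL2", "KL34")

#' Fit the two-stage severity cascade
#'
#' Stage 1 is fit on \emph{all} training rows with labels collapsed to
#' \{KL01, PROGRESSED\}; stage 2 is fit \emph{only} on the rows whose true
#' label is KL2 or KL34 (ground-truth progressed rows, not stage-1
#' predictions, so the stages are decoupled at training time). Both stages are
#' balanced bagged tree ensembles sharing the same configuration; each stage
#' draws its own deterministic seed substream from the config seed.
#'
#' @param x feature table (no missing values).
#' @param y severity labels on the levels KL01 < KL2 < KL34.
#' @param config a \code{\link{balanced_ensemble_config}} applied to both
#'   stages (3000 trees each at the default).
#' @return Object of class \code{cascade_model}: \code{stage1}, \code{stage2},
#'   \code{class_order}, \code{config}.
#' @export
fit_cascade <- function(x, y, config = balanced_ensemble_config()) {
  y <- severity_factor(y)
  if (anyNA(y)) {
    stop_kneecast("severity labels contain missing values",
                  class = "kneecast_validation_error")
  }
  counts <- table(y)
  if (counts["KL2"] + counts["KL34"] == 0) {
    stop_kneecast("no KL2 or KL34 rows: cannot train stage 2 (degenerate training set)",
                  class = "kneecast_degenerate_error")
  }
  if (counts["KL2"] == 0 || counts["KL34"] == 0) {
    stop_kneecast("stage 2 needs both KL2 and KL34 rows; have KL2=%d, KL34=%d",
                  counts["KL2"], counts["KL34"],
                  class = "kneecast_degenerate_error")
  }

  x <- as.data.frame(x)
  y1 <- factor(ifelse(y == "KL01", "KL01", "PROGRESSED"),
               levels = STAGE1_LEVELS)
  cfg1 <- config; cfg1$seed <- derive_seed(config$seed, "stage1")
  stage1 <- fit_ensemble(x, y1, cfg1)

  prog <- y %in% STAGE2_LEVELS
  y2 <- factor(as.character(y[prog]), levels = STAGE2_LEVELS)
  cfg2 <- config; cfg2$seed <- derive_seed(config$seed, "stage2")
  stage2 <- fit_ensemble(x[prog, , drop = FALSE], y2, cfg2)

  structure(list(stage1 = stage1, stage2 = stage2,
                 class_order = severity_levels(), config = config),
            class = "cascade_model")
}

#' Predict severity classes with the cascade
#'
#' Per row: stage 1 predicts KL01 vs progressed (argmax of ensemble
#' probability, i.e. a 0.5 threshold in the binary case). A KL01 prediction is
#' final. Progressed rows - and only those - are passed to stage 2, whose
#' binary output (KL2 or KL34) is the final label. Every row receives exactly
#' one label, and the final label is KL01 iff stage 1 said KL01.
#'
#' @param model a \code{cascade_model}.
#' @param newdata feature table matching the training schema.
#' @param details if \code{TRUE}, return a \code{data.frame} with the stage-1
#'   decision and the final label per row, plus the routed-row count as an
#'   attribute.
#' @return Severity factor (or the detail frame).
#' @export
predict_cascade <- function(model, newdata, details = FALSE) {
  stopifnot(inherits(model, "cascade_model"))
  newdata <- as.data.frame(newdata)
  s1 <- stats::predict(model$stage1, newdata, type = "class")
  final <- factor(rep("KL01", nrow(newdata)), levels = model$class_order)
  routed <- s1 == "PROGRESSED"
  if (any(routed)) {
    s2 <- stats::predict(model$stage2, newdata[routed, , drop = FALSE],
                         type = "class")
    final[routed] <- as.character(s2)
  }
  if (details) {
    out <- data.frame(stage1 = s1, final = final)
    attr(out, "n_routed") <- sum(routed)
    return(out)
  }
  final
}

#' @export
predict.cascade_model <- function(object, newdata, ...) {
  predict_cascade(object, newdata)
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("Two-stage ordinal severity cascade (KL01 < KL2 < KL34)\n")
  cat(sprintf("  stage 1 (KL01 vs progressed): %d trees on %d-per-class samples\n",
              x$stage1$config$n_trees, x$stage1$sample_log[1, 1]))
  cat(sprintf("  stage 2 (KL2 vs KL34):        %d trees on %d-per-class samples\n",
              x$stage2$config$n_trees, x$stage2$sample_log[1, 1]))
  invisible(x)
}
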