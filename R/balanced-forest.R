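# Class-balanced bagged tree ensemble -----------------------------------------
#
# The imbalance-aware base classifier: every tree is grown on a per-class
# balanced bootstrap (n_min draws with replacement from each class), so the
# minority outcome classes carry the same weight as the majority in every
# tree. The bootstrap indices are drawn here; tree growing and aggregation are
# delegated to ranger on exactly those samples.

#' Configuration for a balanced tree ensemble
#'
#' @param n_trees number of trees, default 3000 (the tuned setting: more trees
#'   brought no notable improvement).
#' @param mtry features considered per split; default \code{floor(sqrt(p))}.
#' @param max_depth maximum tree depth; \code{NULL} = unrestricted.
#' @param min_node_size minimum terminal-node size; default 1 (fully grown
#'   trees, the conventional random-forest classification default).
#' @param vote \code{"prob"} averages per-tree leaf class probabilities
#'   (default); \code{"hard"} averages per-tree argmax votes.
#' @param seed integer seed controlling both the balanced bootstraps and the
#'   per-split feature subsampling.
#' @return Object of class \code{balanced_ensemble_config}.
#' @export
balanced_ensemble_config <- function(n_trees = 3000, mtry = NULL,
                                     max_depth = NULL, min_node_size = 1,
                                     vote = c("prob", "hard"), seed = 1L) {
  vote <- match.arg(vote)
  if (length(n_trees) != 1 || is.na(n_trees) || n_trees < 1) {
    stop_kneecast("n_trees must be a positive integer",
                  class = "kneecast_config_error")
  }
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 max_depth = max_depth, min_node_size = min_node_size,
                 vote = vote, seed = as.integer(seed)),
            class = "balanced_ensemble_config")
}

#' Draw one class-balanced bootstrap sample
#'
#' For each class present in \code{labels}, draws \code{n_min} row indices
#' with replacement from that class, where \code{n_min} is the smallest class
#' size; the returned multiset has \code{n_min * n_classes} indices with
#' exactly equal per-class counts. Uses the current RNG state, so the draw is
#' reproducible under \code{set.seed}.
#'
#' @param labels factor (or coercible) of class labels, >= 2 classes present.
#' @return Integer vector of row indices (a multiset; duplicates permitted).
#' @export
balanced_bootstrap <- function(labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) {
    stop_kneecast("balanced bootstrap needs >= 2 classes, got %d (degenerate training set)",
                  nlevels(labels), class = "kneecast_degenerate_error")
  }
  counts <- table(labels)
  n_min <- min(counts)
  unlist(lapply(levels(labels), function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx), n_min, replace = TRUE)]
  }), use.names = FALSE)
}

#' Fit a balanced bagged tree ensemble
#'
#' Grows \code{n_trees} classification trees, each on its own
#' \code{\link{balanced_bootstrap}} sample, with per-split random feature
#' subsetting (Gini impurity). Deterministic under the config seed.
#'
#' @param x \code{data.frame} or matrix of numeric features, no missing values.
#' @param y class labels (factor or coercible), >= 2 classes present.
#' @param config a \code{\link{balanced_ensemble_config}}.
#' @return Object of class \code{balanced_ensemble} with elements
#'   \code{forest} (the fitted trees), \code{classes} (ordered label set),
#'   \code{sample_log} (an \code{n_trees x n_classes} matrix of per-tree
#'   training-sample class counts - equal across classes by construction),
#'   \code{feature_names} and \code{config}.
#' @export
fit_ensemble <- function(x, y, config = balanced_ensemble_config()) {
  stopifnot(inherits(config, "balanced_ensemble_config"))
  x <- as.data.frame(x)
  if (anyNA(x)) {
    bad <- names(x)[vapply(x, anyNA, logical(1))]
    stop_kneecast("features contain missing values in column(s): %s",
                  paste(bad, collapse = ", "),
                  class = "kneecast_validation_error")
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop_kneecast("cannot train on a single class (degenerate training set)",
                  class = "kneecast_degenerate_error")
  }
  if (nrow(x) != length(y)) {
    stop_kneecast("x has %d rows but y has %d labels", nrow(x), length(y),
                  class = "kneecast_validation_error")
  }
  p <- ncol(x)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))

  set.seed(derive_seed(config$seed, "balanced-bootstrap"))
  n <- nrow(x)
  inbag <- vector("list", config$n_trees)
  sample_log <- matrix(0L, config$n_trees, nlevels(y),
                       dimnames = list(NULL, levels(y)))
  for (t in seq_len(config$n_trees)) {
    idx <- balanced_bootstrap(y)
    inbag[[t]] <- tabulate(idx, nbins = n)
    cls_counts <- table(y[idx])
    sample_log[t, names(cls_counts)] <- as.integer(cls_counts)
  }

  forest <- ranger::ranger(x = x, y = y, probability = TRUE,
                           num.trees = config$n_trees, mtry = mtry,
                           min.node.size = config$min_node_size,
                           max.depth = config$max_depth,
                           inbag = inbag, keep.inbag = FALSE,
                           seed = derive_seed(config$seed, "tree-growth"),
                           num.threads = 1, verbose = FALSE)

  structure(list(forest = forest, classes = levels(y),
                 sample_log = sample_log, feature_names = names(x),
                 config = config),
            class = "balanced_ensemble")
}

#' @export
print.balanced_ensemble <- function(x, ...) {
  cat(sprintf("Balanced bagged tree ensemble: %d trees, classes [%s], %d features\n",
              x$config$n_trees, paste(x$classes, collapse = " < "),
              length(x$feature_names)))
  cat(sprintf("  per-tree balanced sample: %d per class\n", x$sample_log[1, 1]))
  invisible(x)
}

check_feature_schema <- function(object, newdata) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols)) {
    stop_kneecast("prediction features are missing column(s): %s",
                  paste(missing_cols, collapse = ", "),
                  class = "kneecast_schema_error")
  }
  newdata[, object$feature_names, drop = FALSE]
}

#' Per-class prediction scores
#'
#' Generic. For a \code{balanced_ensemble}, each row is the mean over trees of
#' the per-tree leaf class probabilities (or of hard per-tree votes when the
#' ensemble was configured with \code{vote = "hard"}); rows sum to 1.
#'
#' @param object a fitted model.
#' @param newdata feature table matching the training schema.
#' @param ... unused.
#' @return Numeric matrix, one row per input row, one column per class in the
#'   model's class order.
#' @export
predict_proba <- function(object, newdata, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.balanced_ensemble <- function(object, newdata, ...) {
  newdata <- check_feature_schema(object, newdata)
  if (object$config$vote == "hard") {
    all_p <- ranger::predictions(
      stats::predict(object$forest, data = newdata, predict.all = TRUE,
                     num.threads = 1))
    # all_p: rows x classes x trees; hard vote = per-tree argmax, first class
    # in the ensemble's class order winning ties
    votes <- apply(all_p, 3, max.col, ties.method = "first")
    pr <- t(apply(votes, 1, tabulate, nbins = length(object$classes))) /
      dim(all_p)[3]
    colnames(pr) <- dimnames(all_p)[[2]] %||% object$classes
  } else {
    pr <- stats::predict(object$forest, data = newdata,
                         num.threads = 1)$predictions
  }
  pr <- pr[, object$classes, drop = FALSE]
  rownames(pr) <- rownames(newdata)
  pr
}

#' Predict class labels from a balanced ensemble
#'
#' Argmax of \code{\link{predict_proba}}; exact probability ties resolve to
#' the earliest label in the ensemble's fixed class order.
#'
#' @param object a \code{balanced_ensemble}.
#' @param newdata feature table matching the training schema.
#' @param type \code{"class"} (default) or \code{"prob"}.
#' @param ... unused.
#' @export
predict.balanced_ensemble <- function(object, newdata, type = c("class", "prob"),
                                      ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, newdata)
  if (type == "prob") return(pr)
  idx <- max.col(pr, ties.method = "first")
  factor(object$classes[idx], levels = object$classes)
}

#' A constant baseline classifier
#'
#' Always predicts \code{label}. Useful as a majority-class baseline in
#' cross-validation and for exercising routing logic.
#'
#' @param label the label to predict.
#' @param classes the full class order the classifier reports over.
#' @export
constant_classifier <- function(label, classes) {
  stopifnot(label %in% classes)
  structure(list(label = label, classes = classes,
                 feature_names = character(0)),
            class = "constant_classifier")
}

#' @export
predict.constant_classifier <- function(object, newdata, type = c("class", "prob"),
                                        ...) {
  type <- match.arg(type)
  n <- nrow(as.data.frame(newdata))
  if (type == "prob") return(predict_proba(object, newdata))
  factor(rep(object$label, n), levels = object$classes)
}

#' @export
predict_proba.constant_classifier <- function(object, newdata, ...) {
  n <- nrow(as.data.frame(newdata))
  pr <- matrix(0, n, length(object$classes),
               dimnames = list(rownames(newdata), object$classes))
  pr[, object$label] <- 1
  pr
}

#' Save / load a fitted model archive
#'
#' Serialises a fitted ensemble or cascade together with its configuration and
#' sample logs as a versioned RDS archive.
#'
#' @param model a \code{balanced_ensemble} or \code{cascade_model}.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "kneecast-model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arch <- readRDS(path)
  if (!identical(arch$format, "kneecast-model")) {
    stop_kneecast("not a kneecast model archive: %s", path,
                  class = "kneecast_validation_error")
  }
  arch$model
}
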