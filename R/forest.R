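#' Gini impurity of a node
#'
#' `sum_i f_i (1 - f_i)` over the class frequencies at a node; the splitting
#' criterion used by the decision trees and the basis of the feature
#' importances reported by the package.
#'
#' @param frequencies nonnegative class frequencies summing to 1.
#' @return Impurity in `[0, 1 - 1/C]` for `C` classes.
#' @examples
#' gini_impurity(c(0.7, 0.3))  # 0.42
#' @export
gini_impurity <- function(frequencies) {
  if (any(frequencies < 0)) stop("frequencies must be >= 0")
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must sum to 1")
  sum(frequencies * (1 - frequencies))
}

#' Fit per-segment random-forest classifiers of A2 domain state
#'
#' Trains one binary random forest per contour segment (plus one for the
#' chain-level response) on the training split of a dataset.  Every forest
#' sees the full input set - all raw bead position components and the
#' per-partition features of every segment - so feature importances can
#' reveal cross-segment correlations.  Trees split on Gini impurity;
#' prediction is by majority vote.  Training is delegated to
#' \pkg{ranger} with `importance = "impurity"` (mean decrease in Gini).
#'
#' @param dataset an [a2_dataset][build_dataset()] with a train/test split
#'   (see [split_dataset()]).
#' @param n_trees trees per forest (default 100).
#' @param mtry inputs tried per split; default is the square root of the
#'   input count.
#' @param seed integer seed (forests get deterministic sub-seeds).
#' @param targets which responses to fit: `"all"` (default) fits one forest
#'   per segment plus the chain level; `"chain"` only the chain-level forest;
#'   an integer vector fits just those segments.  (At chain-level resolution
#'   the single segment response coincides with the chain response.)
#' @return An object of class `a2_forest`: list of fitted forests keyed by
#'   response name, plus configuration and the dataset's index map.
#' @export
a2_forest <- function(dataset, n_trees = 100, mtry = NULL, seed = 1L,
                      targets = "all") {
  if (is.null(dataset$split))
    stop("dataset has no train/test split; call split_dataset() first")
  resp <- colnames(dataset$responses)
  if (identical(targets, "all")) {
    want <- resp
  } else if (identical(targets, "chain")) {
    want <- "y_chain"
  } else {
    want <- paste0("y_s", as.integer(targets))
    if (!all(want %in% resp)) stop("unknown segment in targets")
  }
  train <- dataset$split == "train"
  x <- dataset$features[train, , drop = FALSE]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))

  forests <- list()
  for (k in seq_along(want)) {
    nm <- want[k]
    y <- dataset$responses[train, nm]
    if (length(unique(y)) < 2)
      stop("training response ", nm, " is single-class (all ",
           unique(y)[1], "); the sampled trajectories contain too few ",
           "unfolding events in this segment - simulate longer or at ",
           "stronger shear")
    df <- data.frame(y = factor(y, levels = c(0, 1)), x, check.names = FALSE)
    forests[[nm]] <- ranger::ranger(
      y ~ ., data = df, num.trees = n_trees, mtry = mtry,
      importance = "impurity", classification = TRUE,
      num.threads = 1L, seed = as.integer(derive_seed(seed, 20, k)),
      respect.unordered.factors = FALSE, verbose = FALSE)
  }
  structure(list(forests = forests, resolution = dataset$resolution,
                 n_trees = n_trees, mtry = mtry, seed = as.integer(seed),
                 index_map = dataset$index_map,
                 n_beads = dataset$params$n_beads,
                 feature_names = colnames(dataset$features)),
            class = "a2_forest")
}

#' @export
print.a2_forest <- function(x, ...) {
  cat(sprintf("A2-state random forests: %d-segment resolution, %d forest(s), %d trees each (mtry %d)\n",
              x$resolution, length(x$forests), x$n_trees, x$mtry))
  cat("  responses:", paste(names(x$forests), collapse = ", "), "\n")
  invisible(x)
}

#' Predict A2 domain states
#'
#' @param object an [a2_forest()].
#' @param features numeric feature matrix with the training columns.
#' @param ... unused.
#' @return Integer 0/1 matrix, one column per fitted response.
#' @export
predict.a2_forest <- function(object, features, ...) {
  df <- as.data.frame(features, check.names = FALSE)
  out <- vapply(object$forests, function(f)
    as.integer(as.character(stats::predict(f, data = df,
                                           num.threads = 1L)$predictions)),
    integer(nrow(df)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(object$forests)))
  out
}

#' Per-class recall
#'
#' Fraction of true-folded observations predicted folded, and of
#' true-unfolded observations predicted unfolded.
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return Named vector `c(folded, unfolded)`; a class absent from `truth`
#'   yields `NA` for its entry.
#' @export
per_class_recall <- function(truth, predicted) {
  if (length(truth) == 0) stop("empty test set")
  if (length(truth) != length(predicted)) stop("length mismatch")
  folded <- if (any(truth == 0)) mean(predicted[truth == 0] == 0) else NA_real_
  unfolded <- if (any(truth == 1)) mean(predicted[truth == 1] == 1) else NA_real_
  c(folded = folded, unfolded = unfolded)
}

#' Evaluate per-segment prediction performance
#'
#' Computes folded- and unfolded-class recall for every fitted forest on the
#' requested split of the dataset (test split by default, matching how
#' performance is reported).
#'
#' @param forest an [a2_forest()].
#' @param dataset the dataset it was fitted on (or a compatible one).
#' @param split `"test"` (default) or `"train"`.
#' @return A data frame with columns `response`, `segment` (`NA` for the
#'   chain level), `folded_recall`, `unfolded_recall`, `n`.
#' @export
performance <- function(forest, dataset, split = "test") {
  rows <- dataset$split == split
  if (!any(rows)) stop("empty ", split, " split")
  feats <- dataset$features[rows, , drop = FALSE]
  preds <- predict(forest, feats)
  out <- lapply(names(forest$forests), function(nm) {
    rec <- per_class_recall(dataset$responses[rows, nm], preds[, nm])
    data.frame(response = nm,
               segment = if (nm == "y_chain") NA_integer_
                         else as.integer(sub("^y_s", "", nm)),
               folded_recall = rec[["folded"]],
               unfolded_recall = rec[["unfolded"]],
               n = sum(rows))
  })
  do.call(rbind, out)
}

#' @export
summary.a2_forest <- function(object, ...) {
  cat(sprintf("A2-state random forests (%d-segment resolution)\n",
              object$resolution))
  cat(sprintf("  %d forests x %d trees, mtry = %d, %d inputs\n",
              length(object$forests), object$n_trees, object$mtry,
              length(object$feature_names)))
  imp <- feature_importance(object)
  for (nm in names(object$forests)) {
    top <- utils::head(imp$by_index[[nm]][order(-imp$by_index[[nm]]$importance), ], 3)
    cat(sprintf("  %s: top features %s\n", nm,
                paste(sprintf("%s (%.2f)", top$label, top$importance),
                      collapse = ", ")))
  }
  invisible(object)
}
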