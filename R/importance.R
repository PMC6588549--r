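#' Feature importances of fitted A2 forests
#'
#' Extracts the Gini (mean-decrease-in-impurity) importance of every model
#' input for each fitted forest, normalised to sum to 1, and aggregates the
#' raw per-bead position importances into the three reported position-sum
#' indices.
#'
#' @param forest an [a2_forest()].
#' @return An object of class `a2_importance`: `raw` (list of named numeric
#'   vectors, one per response, summing to 1) and `by_index` (list of data
#'   frames with columns `index`, `symbol`, `segment`, `label`,
#'   `importance`).
#' @export
feature_importance <- function(forest) {
  imap <- input_index_map(forest$resolution, forest$n_beads)
  fmap <- feature_index_map(forest$resolution)
  raw <- lapply(forest$forests, function(f) {
    v <- f$variable.importance
    v <- pmax(v, 0)
    v / sum(v)
  })
  by_index <- lapply(raw, function(v) aggregate_to_table1(v, imap, fmap))
  structure(list(raw = raw, by_index = by_index,
                 resolution = forest$resolution, n_beads = forest$n_beads),
            class = "a2_importance")
}

#' @export
print.a2_importance <- function(x, ...) {
  cat(sprintf("A2 importance report: %d-segment resolution, responses %s\n",
              x$resolution, paste(names(x$raw), collapse = ", ")))
  invisible(x)
}

#' Aggregate raw input importances to reported feature indices
#'
#' Raw per-bead position importances are summed into indices 1-3 (the x-, y-
#' and z-position sums); every per-segment feature keeps its own index.  The
#' total importance is conserved exactly.
#'
#' @param raw named numeric vector of raw input importances.
#' @param input_map data frame mapping input column to reported index
#'   (internal; computed from the resolution when omitted requires `fmap`).
#' @param fmap the [feature_index_map()] of the resolution.
#' @return Data frame with `index`, `symbol`, `segment`, `label` and
#'   `importance`, one row per reported index.
#' @export
aggregate_to_table1 <- function(raw, input_map, fmap) {
  miss <- setdiff(names(raw), input_map$column)
  if (length(miss) > 0)
    stop("unmapped model inputs: ", paste(utils::head(miss, 3), collapse = ", "))
  idx <- input_map$index[match(names(raw), input_map$column)]
  agg <- vapply(fmap$index, function(i) sum(raw[idx == i]), numeric(1))
  lab <- ifelse(is.na(fmap$segment), fmap$symbol,
                paste0(fmap$symbol, "_s", fmap$segment))
  data.frame(index = fmap$index, symbol = fmap$symbol,
             segment = fmap$segment, label = lab, importance = agg)
}

#' Cumulative importance of the k top-ranked reported features
#'
#' @param by_index data frame from [aggregate_to_table1()] (or any frame with
#'   `index` and `importance`).
#' @param k number of top features; ties in importance are broken in favour
#'   of the lower index.
#' @return Sum of the `k` largest per-index importances.
#' @export
top_k_cumulative <- function(by_index, k) {
  if (k < 1 || k > nrow(by_index)) stop("k out of range")
  ord <- order(-by_index$importance, by_index$index)
  sum(by_index$importance[ord][seq_len(k)])
}

#' Per-bead position-importance profile
#'
#' The distribution of one axis's raw bead-position importance along the
#' multimer contour, for one fitted response.  The profile sums to the
#' aggregated importance of the corresponding position-sum index.
#'
#' @param importance an [feature_importance()] result.
#' @param response response name (e.g. `"y_s3"` or `"y_chain"`).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return Numeric vector of length `n_beads` (bead order along the contour).
#' @export
position_profile <- function(importance, response, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  raw <- importance$raw[[response]]
  if (is.null(raw)) stop("no fitted response called ", response)
  cols <- paste0(axis, "_b", seq_len(importance$n_beads))
  out <- raw[cols]
  names(out) <- cols
  unname(out)
}

#' Rank reported features with their segment of origin
#'
#' Orders the reported feature indices by descending importance (ties broken
#' by lower index) and flags cross-segment entries: features whose segment of
#' origin differs from the predicted segment, the signature of correlated
#' segment dynamics.  The three position-sum features transcend segment
#' classification and are never flagged.
#'
#' @param by_index data frame from [aggregate_to_table1()].
#' @param target_segment the segment whose response the forest predicts
#'   (`NA` for the chain level).
#' @return The ranked data frame with added `rank` and `cross_segment`
#'   columns.
#' @export
rank_with_segment_origin <- function(by_index, target_segment = NA) {
  ord <- order(-by_index$importance, by_index$index)
  out <- by_index[ord, ]
  out$rank <- seq_len(nrow(out))
  out$cross_segment <- !is.na(out$segment) & !is.na(target_segment) &
    out$segment != target_segment
  rownames(out) <- NULL
  out
}

#' Plot position-importance profiles along the contour
#'
#' Draws the per-bead x-, y- and z-position importance distributions for one
#' fitted response: where along the multimer the forest looks when deciding
#' that response's A2 state.
#'
#' @param x an [feature_importance()] result.
#' @param response response name (default the first fitted one).
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.a2_importance <- function(x, response = names(x$raw)[1], ...) {
  prof <- vapply(c("x", "y", "z"),
                 function(ax) position_profile(x, response, ax),
                 numeric(x$n_beads))
  graphics::matplot(seq_len(x$n_beads), prof, type = "l", lty = 1,
                    col = c("#1b63a5", "#c2571a", "#3a7d44"),
                    xlab = "bead index along contour",
                    ylab = "importance",
                    main = paste("Position importance,", response), ...)
  graphics::legend("topright", legend = c("x (flow)", "y", "z (gradient)"),
                   col = c("#1b63a5", "#c2571a", "#3a7d44"), lty = 1,
                   bty = "n")
  invisible(x)
}
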