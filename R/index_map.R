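# Reported feature indexing.
#
# Indices 1-3 aggregate the raw per-bead position components (sums of the x-,
# y- and z-coordinates over all beads); the 3N individual components are what
# the classifier actually consumes, but they are reported under these three
# indices.  Indices 4 onward lay out the 17 per-partition features in blocks
# of n_segments consecutive indices, segment-major within each block, so the
# reported index count is 3 + 17 * n_segments: 20 at chain level, 88 at
# 5-segment and 173 at 10-segment resolution.

per_segment_symbols <- c("v_X", "v_Y", "v_Z", "Dr",
                         "MAX_X", "MAX_Y", "MAX_Z", "EE",
                         "RG_X", "RG_Y", "RG_Z", "RG_TOT",
                         "VFF", "LCC", "PCA_1", "PCA_2", "PCA_3")

#' Reported feature index map
#'
#' @param n_segments partition resolution (1, 5 or 10).
#' @return A data frame with columns `index`, `symbol` and `segment`
#'   (`NA` for the three position-sum indices, which transcend segment
#'   classification).
#' @examples
#' nrow(feature_index_map(5))   # 88
#' nrow(feature_index_map(10))  # 173
#' @export
feature_index_map <- function(n_segments) {
  head <- data.frame(index = 1:3,
                     symbol = c("Sr_X", "Sr_Y", "Sr_Z"),
                     segment = NA_integer_)
  nf <- length(per_segment_symbols)
  body <- data.frame(
    index = 3 + seq_len(nf * n_segments),
    symbol = rep(per_segment_symbols, each = n_segments),
    segment = rep(seq_len(n_segments), times = nf))
  rbind(head, body)
}

# map every model-input column to its reported index
input_index_map <- function(n_segments, n_beads) {
  raw <- data.frame(
    column = c(paste0("x_b", seq_len(n_beads)),
               paste0("y_b", seq_len(n_beads)),
               paste0("z_b", seq_len(n_beads))),
    index = rep(1:3, each = n_beads))
  fmap <- feature_index_map(n_segments)
  fmap <- fmap[fmap$index > 3, ]
  feat <- data.frame(column = paste0(fmap$symbol, "_s", fmap$segment),
                     index = fmap$index)
  rbind(raw, feat)
}

# model input column names, in the order the feature matrix is assembled
input_column_names <- function(n_segments, n_beads) {
  input_index_map(n_segments, n_beads)$column
}

#' Extract the full feature vector for one observation
#'
#' Computes the raw per-bead position features plus the 17 per-partition
#' conformational features for each segment at the requested resolution.  The
#' velocity and flow-displacement features use the window between the two
#' supplied consecutive sampled frames.
#'
#' @param frame_t,frame_prev consecutive [vwf_frame()]s separated by the
#'   sampling interval.
#' @param params a [sim_params()] object.
#' @param resolution 1, 5 or 10 segments.
#' @return Named numeric vector of length `3 N + 17 * resolution`, with the
#'   reported index map attached as attribute `"index_map"`.
#' @export
extract_features <- function(frame_t, frame_prev, params, resolution) {
  n <- params$n_beads
  pos_t <- array(frame_t$positions, c(1, n, 3))
  pos_p <- array(frame_prev$positions, c(1, n, 3))
  m <- featurize_positions(pos_t, pos_p, params, resolution)
  out <- m[1, ]
  names(out) <- colnames(m)
  attr(out, "index_map") <- feature_index_map(resolution)
  out
}

# Batched feature assembly: positions are (nobs, N, 3) arrays in nm.
# Returns nobs x (3N + 17 * n_segments) matrix with model-input column names.
featurize_positions <- function(pos_t, pos_prev, params, n_segments) {
  n <- params$n_beads
  stopifnot(dim(pos_t)[2] == n, dim(pos_t)[3] == 3)
  part <- partition_chain(n, n_segments)
  thr <- lcc_threshold_radii(n_segments) * params$bead_radius
  nobs <- dim(pos_t)[1]

  raw <- cbind(matrix(pos_t[, , 1], nobs, n),
               matrix(pos_t[, , 2], nobs, n),
               matrix(pos_t[, , 3], nobs, n))

  segf <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    r <- part$ranges[[s]]
    segf[[s]] <- .seg_features(pos_t, pos_prev, r[1] - 1L, r[2],
                               thr, params$sample_interval,
                               params$shear_rate)
  }
  # reorder from per-segment blocks of 17 into feature-major blocks
  feat <- matrix(0, nobs, 17 * n_segments)
  for (f in 1:17)
    for (s in seq_len(n_segments))
      feat[, (f - 1) * n_segments + s] <- segf[[s]][, f]

  out <- cbind(raw, feat)
  colnames(out) <- input_column_names(n_segments, n)
  out
}
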