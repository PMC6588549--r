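#' Partition the chain contour into equal segments
#'
#' @param n_beads total number of beads.
#' @param n_segments number of contiguous equal-length segments (1 =
#'   chain-level, 5 or 10 in the standard analyses); must divide `n_beads`.
#' @return An object of class `vwf_partitioning`: list with `n_beads`,
#'   `n_segments` and `ranges`, a list of integer vectors `c(first, last)`
#'   (1-based, inclusive) in contour order.
#' @examples
#' partition_chain(100, 5)
#' @export
partition_chain <- function(n_beads, n_segments) {
  if (n_segments < 1 || n_beads %% n_segments != 0)
    stop("n_segments must divide n_beads")
  size <- n_beads %/% n_segments
  ranges <- lapply(seq_len(n_segments),
                   function(s) c((s - 1) * size + 1, s * size))
  structure(list(n_beads = as.integer(n_beads),
                 n_segments = as.integer(n_segments),
                 segment_size = as.integer(size), ranges = ranges),
            class = "vwf_partitioning")
}

#' @export
print.vwf_partitioning <- function(x, ...) {
  cat(sprintf("Contour partitioning: %d beads in %d segment(s) of %d\n",
              x$n_beads, x$n_segments, x$segment_size))
  invisible(x)
}

seg_beads <- function(partitioning, segment) {
  r <- partitioning$ranges[[segment]]
  seq.int(r[1], r[2])
}

# LCC threshold in bead radii by partition resolution; the ratio of threshold
# (in bead radii) to beads per partition is 1/2 at every resolution.
lcc_threshold_radii <- function(n_segments) {
  switch(as.character(n_segments),
         "1" = 50, "5" = 10, "10" = 5,
         stop("no local-chain-concentration threshold defined for ",
              n_segments, "-segment resolution (use 1, 5 or 10)"))
}

# --- scalar feature operations ----------------------------------------------
# These are the reference definitions; the batched C++ path used by the
# pipeline is tested against them.

#' Maximum per-axis extent of a set of beads
#'
#' Largest coordinate difference between any two beads (not necessarily the
#' same pair on each axis).
#'
#' @param positions `k x 3` position matrix of the partition's beads.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Span in nm.
#' @export
max_axis_extent <- function(positions, axis) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("empty partition")
  diff(range(positions[, axis]))
}

#' End-to-end distance of a partition
#'
#' Euclidean distance between the first and last bead of the partition in
#' contour order.
#'
#' @param positions `k x 3` position matrix (contour order).
#' @return Distance in nm.
#' @export
end_to_end <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("end_to_end needs at least 2 beads")
  sqrt(sum((positions[nrow(positions), ] - positions[1, ])^2))
}

#' Radii of gyration of a partition
#'
#' Component `RG_axis` is the root mean squared deviation of that coordinate
#' from the partition mean; `RG_TOT` the root mean squared Euclidean distance
#' from the centre of mass, so `RG_TOT^2 = RG_X^2 + RG_Y^2 + RG_Z^2`.
#'
#' @param positions `k x 3` position matrix.
#' @return Named vector `c(RG_X, RG_Y, RG_Z, RG_TOT)` in nm.
#' @export
gyration <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1) stop("empty partition")
  d <- sweep(positions, 2, colMeans(positions))
  comp <- unname(sqrt(colMeans(d^2)))
  c(RG_X = comp[1], RG_Y = comp[2], RG_Z = comp[3],
    RG_TOT = sqrt(sum(comp^2)))
}

#' Flow-direction variation fraction
#'
#' `VFF = RG_X / (RG_X + RG_Y + RG_Z)`: the fraction of a partition's spatial
#' spread that lies along the flow direction.
#'
#' @param rg_x,rg_y,rg_z gyration components, nm.
#' @return Dimensionless value in `[0, 1]`; a degenerate point partition
#'   (all components zero) returns 0 with a warning.
#' @export
variation_fraction_flow <- function(rg_x, rg_y, rg_z) {
  s <- rg_x + rg_y + rg_z
  if (s == 0) {
    warning("all gyration components are zero; VFF undefined, returning 0")
    return(0)
  }
  rg_x / s
}

#' Local chain concentration of a partition
#'
#' Fraction of all chain beads (the partition's own included) lying within a
#' resolution-dependent threshold distance of the partition centre of mass.
#' The threshold is 50, 10 and 5 bead radii for the chain-level, 5-segment
#' and 10-segment resolutions respectively.
#'
#' @param frame a [vwf_frame()].
#' @param partitioning a [partition_chain()] object.
#' @param segment segment index within the partitioning.
#' @param params a [sim_params()] object (supplies the bead radius).
#' @return Fraction in `(0, 1]`.
#' @export
local_chain_concentration <- function(frame, partitioning, segment, params) {
  thr <- lcc_threshold_radii(partitioning$n_segments) * params$bead_radius
  idx <- seg_beads(partitioning, segment)
  com <- colMeans(frame$positions[idx, , drop = FALSE])
  d2 <- rowSums(sweep(frame$positions, 2, com)^2)
  mean(d2 <= thr^2)
}

#' Principal-axis projections on the flow direction
#'
#' Eigen-decomposes the 3x3 position covariance of the partition (1/n
#' normalisation), orders eigenvectors by descending eigenvalue, and returns
#' the absolute cosine of the angle between each principal axis and the flow
#' (x) direction.  Degenerate (tied) eigenvalues are resolved by preferring
#' alignment with x, then y, then z, so the result is deterministic.
#'
#' @param positions `k x 3` position matrix, `k >= 3`.
#' @return Named vector `c(PCA_1, PCA_2, PCA_3)`, each in `[0, 1]`.
#' @export
pca_flow_projections <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3) stop("PCA needs at least 3 beads")
  d <- sweep(positions, 2, colMeans(positions))
  cv <- crossprod(d) / nrow(positions)
  e <- eigen(cv, symmetric = TRUE)   # descending eigenvalues
  ord <- 1:3
  tol <- 1e-12 * max(1, abs(e$values[1]))
  for (a in 1:2) for (b in (a + 1):3) {
    if (abs(e$values[ord[a]] - e$values[ord[b]]) <= tol) {
      va <- abs(e$vectors[, ord[a]]); vb <- abs(e$vectors[, ord[b]])
      if (vb[1] > va[1] + 1e-12 ||
          (abs(vb[1] - va[1]) <= 1e-12 && vb[2] > va[2] + 1e-12)) {
        tmp <- ord[a]; ord[a] <- ord[b]; ord[b] <- tmp
      }
    }
  }
  out <- abs(e$vectors[1, ord])
  names(out) <- c("PCA_1", "PCA_2", "PCA_3")
  out
}

#' Centre-of-mass velocity of a partition
#'
#' Finite difference of the partition centre of mass between two consecutive
#' sampled frames, divided by the sampling interval.
#'
#' @param frame_t,frame_prev consecutive [vwf_frame()]s (`frame_prev` one
#'   sampling interval earlier).
#' @param partitioning a [partition_chain()] object.
#' @param segment segment index.
#' @param dt_s sampling interval, s.
#' @return Named vector `c(v_X, v_Y, v_Z)` in nm/s.
#' @export
com_velocity <- function(frame_t, frame_prev, partitioning, segment, dt_s) {
  if (abs((frame_t$time - frame_prev$time) - dt_s) > 1e-6 * dt_s)
    stop("frames are not consecutive at spacing dt_s")
  idx <- seg_beads(partitioning, segment)
  v <- (colMeans(frame_t$positions[idx, , drop = FALSE]) -
          colMeans(frame_prev$positions[idx, , drop = FALSE])) / dt_s
  names(v) <- c("v_X", "v_Y", "v_Z")
  v
}

#' Flow-induced displacement of a partition
#'
#' Magnitude of the centre-of-mass displacement over one sampling interval
#' caused by the undisturbed shear field alone: `|shear_rate * mean(z) * dt_s|`.
#'
#' @param frame a [vwf_frame()].
#' @param partitioning a [partition_chain()] object.
#' @param segment segment index.
#' @param shear_rate shear rate, 1/s.
#' @param dt_s sampling interval, s.
#' @return Displacement magnitude, nm.
#' @export
flow_induced_displacement <- function(frame, partitioning, segment,
                                      shear_rate, dt_s) {
  idx <- seg_beads(partitioning, segment)
  abs(shear_rate * mean(frame$positions[idx, 3]) * dt_s)
}
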