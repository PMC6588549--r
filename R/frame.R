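#' Construct a simulation frame
#'
#' A frame holds one snapshot of the chain: bead positions in laboratory
#' coordinates (x = flow, y = vorticity, z = gradient direction) and the
#' instantaneous tension carried by each A2 (FENE) spring.
#'
#' @param time frame time in seconds.
#' @param positions numeric `N x 3` matrix of bead positions, nm.
#' @param tensions numeric vector of `N/2` FENE spring tensions, pN; one per
#'   monomer, spring `i` connecting beads `2i - 1` and `2i`.
#' @return An object of class `vwf_frame`.
#' @export
vwf_frame <- function(time, positions, tensions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (n < 2 || n %% 2 != 0) stop("frame must contain an even number of beads")
  if (length(tensions) != n / 2)
    stop("expected ", n / 2, " tensions (one per FENE spring), got ",
         length(tensions))
  if (any(!is.finite(tensions)) || any(tensions < 0))
    stop("tensions must be finite and >= 0")
  if (any(!is.finite(positions))) stop("positions must be finite")
  structure(list(time = time, positions = unname(positions),
                 tensions = as.numeric(tensions)),
            class = "vwf_frame")
}

#' @export
print.vwf_frame <- function(x, ...) {
  n <- nrow(x$positions)
  cat(sprintf("vWF frame: %d beads at t = %.4g s; max A2 tension %.3g pN\n",
              n, x$time, max(x$tensions)))
  invisible(x)
}

#' Construct a trajectory
#'
#' An ordered, uniformly spaced sequence of frames from one simulated replica,
#' stored as dense arrays for efficiency.
#'
#' @param times numeric vector of frame times, s (strictly increasing, uniform
#'   spacing).
#' @param positions `n_frames x N x 3` array of bead positions, nm.
#' @param tensions `n_frames x N/2` matrix of A2 spring tensions, pN.
#' @param params the [sim_params()] used.
#' @param replica integer replica id.
#' @return An object of class `vwf_trajectory`.
#' @export
vwf_trajectory <- function(times, positions, tensions, params, replica = 1L) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  nf <- length(times)
  if (dim(positions)[1] != nf || nrow(tensions) != nf)
    stop("times, positions and tensions disagree on the number of frames")
  if (nf > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-9 * dt[1])
      stop("frame times must be uniformly spaced")
  }
  structure(list(times = times, positions = positions, tensions = tensions,
                 params = params, replica = as.integer(replica)),
            class = "vwf_trajectory")
}

#' @export
print.vwf_trajectory <- function(x, ...) {
  cat(sprintf("vWF trajectory: replica %d, %d frames x %d beads, t in [%.3g, %.3g] s\n",
              x$replica, length(x$times), dim(x$positions)[2],
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# extract frame i of a trajectory as a vwf_frame
#' Extract one frame from a trajectory
#' @param traj a `vwf_trajectory`.
#' @param i frame index.
#' @return A `vwf_frame`.
#' @export
get_frame <- function(traj, i) {
  vwf_frame(traj$times[i], traj$positions[i, , ], traj$tensions[i, ])
}
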