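#' Generate a synthetic conformation fixture
#'
#' Deterministic frame pairs with analytically known feature values and
#' exactly prescribed A2 spring tensions, so the feature, labelling and
#' forest stages can be exercised without running dynamics.  Archetypes:
#' `"rod-x"`/`"rod-y"`/`"rod-z"` (straight chain along one axis, spacing one
#' pair sigma), `"globule"` (uniform random beads in a ball of radius
#' `globule_radius`), `"two-arm-pulled"` (a V shape opening in the xz plane)
#' and `"custom"` (caller-supplied coordinates).
#'
#' @param archetype conformation archetype.
#' @param params a [sim_params()] object (bead count and length scales).
#' @param tensions prescribed spring tensions, pN (length `n_beads / 2`);
#'   default all zero.
#' @param drift displacement (nm, length-3) applied between the previous and
#'   current frame, so the centre-of-mass velocity of every partition is
#'   `drift / sample_interval`.
#' @param globule_radius radius of the globule archetype, nm.
#' @param coordinates `N x 3` matrix for `archetype = "custom"`.
#' @param seed integer seed (globule archetype only).
#' @return List with elements `frame_t` and `frame_prev` ([vwf_frame()]s one
#'   sampling interval apart).
#' @export
generate_fixture <- function(archetype = c("rod-x", "rod-y", "rod-z",
                                           "globule", "two-arm-pulled",
                                           "custom"),
                             params = sim_params(),
                             tensions = NULL,
                             drift = c(0, 0, 0),
                             globule_radius = 4 * params$bead_radius,
                             coordinates = NULL,
                             seed = 1L) {
  archetype <- match.arg(archetype)
  n <- params$n_beads
  if (is.null(tensions)) tensions <- rep(0, n / 2)
  if (length(tensions) != n / 2)
    stop("need ", n / 2, " prescribed tensions")
  sp <- params$pair_sigma

  pos <- switch(archetype,
    "rod-x" = cbind(seq_len(n) * sp, 0, 0),
    "rod-y" = cbind(0, seq_len(n) * sp, 0),
    "rod-z" = cbind(0, 0, seq_len(n) * sp),
    "globule" = {
      rs <- local_rng(seed)
      on.exit(restore_rng(rs))
      m <- matrix(stats::rnorm(3 * n), n, 3)
      m <- m / sqrt(rowSums(m^2)) * globule_radius * stats::runif(n)^(1 / 3)
      m
    },
    "two-arm-pulled" = {
      half <- n / 2
      arm1 <- cbind(-rev(seq_len(half)) * sp, 0, rev(seq_len(half)) * sp / 2)
      arm2 <- cbind(seq_len(half) * sp, 0, seq_len(half) * sp / 2)
      rbind(arm1, arm2)
    },
    "custom" = {
      if (is.null(coordinates)) stop("custom archetype needs coordinates")
      as.matrix(coordinates)
    })
  if (nrow(pos) != n) stop("fixture coordinates must have n_beads rows")

  frame_t <- vwf_frame(params$sample_interval, pos, tensions)
  frame_prev <- vwf_frame(0, sweep(pos, 2, drift), tensions)
  list(frame_t = frame_t, frame_prev = frame_prev)
}
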