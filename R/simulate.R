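#' FENE spring force
#'
#' Restoring force of a finitely extensible nonlinear elastic spring,
#' `F(r) = k r / (1 - (r / R0)^2)`.  The force is linear (`k r`) at small
#' extension and diverges as the extension approaches the maximum `R0`, which
#' models the steep force-extension response of the A2 domain near full
#' extension.
#'
#' @param r extension, nm (vectorised); must satisfy `0 <= r < R0`.
#' @param k spring constant, pN/nm.
#' @param R0 maximum extension, nm.
#' @return Force in pN, same length as `r`.
#' @examples
#' fene_force(0.5, k = 1, R0 = 1)  # 0.6667
#' @export
fene_force <- function(r, k, R0) {
  if (k < 0) stop("k must be >= 0")
  if (R0 <= 0) stop("R0 must be > 0")
  if (any(r < 0)) stop("extension must be >= 0")
  if (any(r >= R0))
    stop("FENE spring over-extended (r >= R0); the spring force diverges ",
         "at R0 - this usually signals a timestep that is too large")
  k * r / (1 - (r / R0)^2)
}

#' Ambient shear velocity
#'
#' The undisturbed flow field is a simple shear `v_x = shear_rate * z` with
#' zero y and z components.
#'
#' @param z gradient-direction coordinate, nm (vectorised).
#' @param shear_rate shear rate, 1/s.
#' @return x-velocity in nm/s.
#' @export
shear_velocity <- function(z, shear_rate) shear_rate * z

#' A2 spring tensions of a configuration
#'
#' @param positions `N x 3` bead position matrix, nm.
#' @param params a [sim_params()] object.
#' @return Numeric vector of `N/2` tensions, pN; entry `i` is the FENE force
#'   at the current extension of the spring connecting beads `2i - 1`, `2i`.
#' @export
a2_tensions <- function(positions, params) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n != params$n_beads) stop("positions do not match params$n_beads")
  i0 <- seq(1, n, by = 2)
  d <- positions[i0 + 1, , drop = FALSE] - positions[i0, , drop = FALSE]
  r <- sqrt(rowSums(d^2))
  fene_force(r, params$fene_k, params$fene_R0)
}

#' Advance one Brownian-dynamics step
#'
#' Euler-Maruyama update of the overdamped Langevin equation: deterministic
#' drift from the conservative forces (mobility times force) plus advection by
#' the undisturbed shear field at each bead's z coordinate, plus a Gaussian
#' increment with variance `2 D dt` per coordinate.
#'
#' @param frame a [vwf_frame()].
#' @param params a [sim_params()] object.
#' @param seed integer seed for the stochastic increment.
#' @param shear_on logical; disable to integrate in a quiescent fluid.
#' @return The advanced `vwf_frame` (time incremented by `dt`, tensions
#'   recomputed).
#' @export
bd_step <- function(frame, params, seed = params$seed, shear_on = TRUE) {
  rp <- reduced_params(params, shear_on = shear_on)
  s <- sim_scales(params)
  pos_red <- frame$positions / s$sigma_nm
  out <- .bd_run(pos_red, rp, 1, 0L, as.double(seed))
  vwf_frame(frame$time + params$dt,
            out$final * s$sigma_nm,
            out$tensions * s$force_pN)
}

# internal: run n_steps from a reduced-unit position matrix, optional sampling
run_segment <- function(pos_red, params, n_steps, sample_every, seed,
                        shear_on = TRUE) {
  rp <- reduced_params(params, shear_on = shear_on)
  .bd_run(pos_red, rp, as.double(n_steps), as.integer(sample_every),
          as.double(seed))
}

# initial condition: excluded-volume random walk with unit (sigma) bond steps
initial_walk <- function(params, seed) {
  n <- params$n_beads
  set.seed(as.integer(seed %% 2147483647))
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    for (try in 1:200) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- pos[i - 1, ] + u
      d2 <- rowSums((pos[1:(i - 1), , drop = FALSE] -
                       matrix(cand, i - 1, 3, byrow = TRUE))^2)
      if (all(d2 > 0.81)) break
    }
    pos[i, ] <- cand
  }
  pos
}

#' Equilibrate a chain into its rest-state globule
#'
#' Runs shear-free Brownian dynamics from an excluded-volume random-walk
#' initial condition until the total radius of gyration has plateaued: the
#' window-averaged Rg must change by less than `tol` (relative) between
#' consecutive windows of `window` steps, with at least `min_windows` windows
#' integrated.  With the default attractive pair potential the result is a
#' compact globule whose Rg is far below the contour length.
#'
#' @param params a [sim_params()] object.
#' @param seed integer seed.
#' @param tol relative Rg change declaring convergence (default 0.01).
#' @param window window size in steps (default 1e4).
#' @param min_windows minimum number of windows before convergence is allowed.
#' @param max_steps error if no plateau after this many steps.
#' @return A `vwf_frame` at time 0.
#' @export
equilibrate <- function(params, seed = params$seed, tol = 0.01,
                        window = 1e4, min_windows = 5, max_steps = 1e6) {
  s <- sim_scales(params)
  pos <- initial_walk(params, derive_seed(seed, 1))
  rg_prev <- NA_real_
  steps <- 0
  w <- 0
  sample_every <- max(1L, as.integer(window / 50))
  repeat {
    out <- run_segment(pos, params, window, sample_every,
                       derive_seed(seed, 2, w), shear_on = FALSE)
    pos <- out$final
    steps <- steps + window
    w <- w + 1
    # window-averaged total Rg
    sp <- out$sampled_positions
    rgs <- apply(sp, 1, function(m) {
      m <- matrix(m, ncol = 3)
      sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
    })
    rg <- mean(rgs)
    if (w >= min_windows && is.finite(rg_prev) &&
        abs(rg - rg_prev) / rg_prev < tol) break
    rg_prev <- rg
    if (steps >= max_steps)
      stop("equilibration did not converge within ", max_steps, " steps")
  }
  vwf_frame(0, pos * s$sigma_nm, out$tensions * s$force_pN)
}

#' Simulate an ensemble of sheared vWF chains
#'
#' Runs `n_replicas` statistically independent chains (distinct sub-seeds of
#' `seed`), each equilibrated into a globule without flow and then driven by
#' the shear field, sampling a frame every `sample_interval` seconds.
#'
#' @param params a [sim_params()] object.
#' @param n_frames number of sampled frames per replica.
#' @param n_replicas number of independent chains (default from `params`).
#' @param seed integer root seed (default from `params`).
#' @param equilibrate_first logical; set `FALSE` to start from the
#'   random-walk state directly (mainly for tests).
#' @return A list of [vwf_trajectory()] objects, one per replica.
#' @export
simulate_vwf <- function(params, n_frames, n_replicas = params$n_replicas,
                         seed = params$seed, equilibrate_first = TRUE) {
  s <- sim_scales(params)
  spf <- params$steps_per_sample
  lapply(seq_len(n_replicas), function(rep) {
    rseed <- derive_seed(seed, 10, rep)
    pos0 <- if (equilibrate_first) {
      equilibrate(params, seed = rseed)$positions / s$sigma_nm
    } else {
      initial_walk(params, derive_seed(rseed, 1))
    }
    out <- tryCatch(
      run_segment(pos0, params, as.double(n_frames) * spf, spf,
                  derive_seed(rseed, 3)),
      error = function(e)
        stop("replica ", rep, ": ", conditionMessage(e), call. = FALSE))
    vwf_trajectory(times = seq_len(n_frames) * params$sample_interval,
                   positions = out$sampled_positions * s$sigma_nm,
                   tensions = out$sampled_tensions * s$force_pN,
                   params = params, replica = rep)
  })
}
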