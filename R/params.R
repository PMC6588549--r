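#' Simulation parameters for the coarse-grained vWF model
#'
#' Defines the physical model: a chain of `n_beads` beads (two per vWF
#' monomer) in which odd-numbered bonds are FENE springs representing the
#' force-sensitive A2 domain and even-numbered bonds are stiff harmonic
#' springs representing inter-monomer disulfide links.  All beads interact
#' through a truncated Lennard-Jones potential whose attractive well collapses
#' the chain into a globule at rest; an unbounded simple shear flow
#' (`v_x = shear_rate * z`) drives unraveling.  Dynamics are overdamped
#' (Brownian) with free-draining Stokes mobility by default.
#'
#' Parameters are given in laboratory units (nm, pN, s, K); internally the
#' integrator runs in reduced units with length scale `pair_sigma`, energy
#' scale kT and time scale `zeta * pair_sigma^2 / kT`, where `zeta` is the
#' Stokes drag `6 * pi * viscosity * bead_radius`.  The default FENE constants
#' place the 11 pN unfolding force at 45% of the maximum spring extension;
#' the default well depth (1 kT) and effective medium viscosity (2 mPa s,
#' plasma-like) put the nominal shear rate of 5e5/s in the intermittent
#' globule-stretch regime in which A2 unfolding is frequent near the chain
#' centre and rare at the termini.  All of these are modelling defaults of
#' this package, exposed here precisely so they can be changed.
#'
#' @param n_beads even number of beads (default 100, i.e. 50 monomers).
#' @param bead_radius hydrodynamic bead radius in nm.
#' @param fene_k FENE spring constant, pN/nm.
#' @param fene_R0 maximum FENE extension, nm.
#' @param harmonic_k,harmonic_r0 stiffness (pN/nm) and rest length (nm) of the
#'   disulfide bonds; the default stiffness is 50x the FENE constant.
#' @param pair_epsilon Lennard-Jones well depth in units of kT.
#' @param pair_sigma Lennard-Jones length scale in nm (default one bead
#'   diameter).
#' @param pair_cutoff pair interaction cutoff in nm.  `1.12 * pair_sigma`
#'   gives a purely repulsive (WCA) chain; the default `2.5 * pair_sigma`
#'   retains the attractive well that produces the rest-state globule.
#' @param shear_rate shear rate of the ambient flow, 1/s.
#' @param temperature solvent temperature, K.
#' @param viscosity solvent viscosity, Pa s.
#' @param dt integration timestep, s.
#' @param sample_interval trajectory sampling interval, s; must be an integer
#'   multiple of `dt`.
#' @param hi_mode `"free-draining"` (default) or
#'   `"pairwise-mobility-tensor"` for Rotne-Prager-Yamakawa hydrodynamic
#'   interactions (considerably slower; intended for small systems).
#' @param n_replicas default number of independent chains simulated by
#'   [simulate_vwf()].
#' @param seed default integer seed.
#'
#' @return An object of class `vwf_sim_params`.
#' @examples
#' p <- sim_params(n_beads = 20)
#' p
#' @export
sim_params <- function(n_beads = 100,
                       bead_radius = 2.5,
                       fene_k = 0.3249,
                       fene_R0 = 60,
                       harmonic_k = 50 * fene_k,
                       harmonic_r0 = 2 * bead_radius,
                       pair_epsilon = 1,
                       pair_sigma = 2 * bead_radius,
                       pair_cutoff = 2.5 * pair_sigma,
                       shear_rate = 5e5,
                       temperature = 300,
                       viscosity = 2e-3,
                       dt = 5.6e-10,
                       sample_interval = 2.24e-7,
                       hi_mode = c("free-draining", "pairwise-mobility-tensor"),
                       n_replicas = 22,
                       seed = 1L) {
  hi_mode <- match.arg(hi_mode)
  if (n_beads < 2 || n_beads %% 2 != 0)
    stop("n_beads must be even and >= 2 (two beads per monomer)")
  if (fene_R0 <= 0) stop("fene_R0 must be > 0")
  if (fene_k < 0 || harmonic_k < 0) stop("spring constants must be >= 0")
  if (bead_radius <= 0 || pair_sigma <= 0) stop("length scales must be > 0")
  if (pair_epsilon < 0) stop("pair_epsilon must be >= 0")
  if (shear_rate < 0) stop("shear_rate must be >= 0")
  if (temperature <= 0 || viscosity <= 0)
    stop("temperature and viscosity must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  ratio <- sample_interval / dt
  if (sample_interval < dt || abs(ratio - round(ratio)) > 1e-6)
    stop("sample_interval must be a multiple of dt and >= dt")

  p <- list(n_beads = as.integer(n_beads), bead_radius = bead_radius,
            fene_k = fene_k, fene_R0 = fene_R0,
            harmonic_k = harmonic_k, harmonic_r0 = harmonic_r0,
            pair_epsilon = pair_epsilon, pair_sigma = pair_sigma,
            pair_cutoff = pair_cutoff,
            shear_rate = shear_rate, temperature = temperature,
            viscosity = viscosity, dt = dt,
            sample_interval = sample_interval,
            steps_per_sample = as.integer(round(ratio)),
            hi_mode = hi_mode, n_replicas = as.integer(n_replicas),
            seed = as.integer(seed))
  class(p) <- "vwf_sim_params"
  p
}

# --- reduced-unit scales -----------------------------------------------------

kB_pN_nm <- 1.380649e-2  # Boltzmann constant, pN nm / K

#' @export
print.vwf_sim_params <- function(x, ...) {
  s <- sim_scales(x)
  cat("Coarse-grained vWF simulation parameters\n")
  cat(sprintf("  %d beads (%d monomers), bead radius %.3g nm\n",
              x$n_beads, x$n_beads %/% 2, x$bead_radius))
  cat(sprintf("  FENE: k = %.4g pN/nm, R0 = %.4g nm; harmonic: k = %.4g pN/nm, r0 = %.3g nm\n",
              x$fene_k, x$fene_R0, x$harmonic_k, x$harmonic_r0))
  cat(sprintf("  pair LJ: eps = %.3g kT, sigma = %.3g nm, cutoff = %.3g nm\n",
              x$pair_epsilon, x$pair_sigma, x$pair_cutoff))
  cat(sprintf("  shear rate %.4g /s  (reduced %.4g), T = %g K, dt = %.3g s (reduced %.3g)\n",
              x$shear_rate, x$shear_rate * s$tau, x$temperature,
              x$dt, x$dt / s$tau))
  cat(sprintf("  sampling every %.3g s (%d steps), mobility: %s\n",
              x$sample_interval, x$steps_per_sample, x$hi_mode))
  invisible(x)
}

#' Unit scales of a parameter set
#'
#' Returns the reduced-unit scales implied by a [sim_params()] object:
#' `sigma_nm` (length), `kT_pN_nm` (energy), `force_pN` (force, kT/sigma),
#' `tau_s` (time, `zeta sigma^2 / kT`) and the bead diffusivity `D_nm2_s`.
#'
#' @param params a `vwf_sim_params` object.
#' @return A named list of scales.
#' @export
sim_scales <- function(params) {
  kT <- kB_pN_nm * params$temperature            # pN nm
  zeta <- 6 * pi * params$viscosity * params$bead_radius * 1e-9  # kg/s
  sigma_m <- params$pair_sigma * 1e-9
  kT_J <- kT * 1e-21                             # pN nm -> J
  tau <- zeta * sigma_m^2 / kT_J                 # s
  list(sigma_nm = params$pair_sigma,
       kT_pN_nm = kT,
       force_pN = kT / params$pair_sigma,
       tau_s = tau,
       D_nm2_s = (kT_J / zeta) * 1e18)
}

# reduced-unit parameter list handed to the C++ integrator; noise = FALSE
# integrates the deterministic drift alone (contract tests)
reduced_params <- function(params, shear_on = TRUE, noise = TRUE) {
  s <- sim_scales(params)
  sig <- params$pair_sigma
  list(n = params$n_beads,
       fene_k = params$fene_k * sig^2 / s$kT_pN_nm,
       fene_R0 = params$fene_R0 / sig,
       harm_k = params$harmonic_k * sig^2 / s$kT_pN_nm,
       harm_r0 = params$harmonic_r0 / sig,
       eps = params$pair_epsilon,
       cutoff = params$pair_cutoff / sig,
       shear = if (shear_on) params$shear_rate * s$tau_s else 0,
       dt = params$dt / s$tau_s,
       hi = params$hi_mode == "pairwise-mobility-tensor",
       a = params$bead_radius / sig,
       noise = noise)
}

# deterministic sub-seed derivation; kept well below 2^31
derive_seed <- function(root, stage, index = 0) {
  ((as.double(root) %% 50021) * 40009 + stage * 100003 + index * 7919) %%
    2147483647
}
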