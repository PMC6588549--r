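# small parameter sets used across test files

tiny_params <- function(n_beads = 8, ...) {
  sim_params(n_beads = n_beads, ...)
}

# interaction-free parameters: ideal beads diffusing (optionally in shear)
free_params <- function(n_beads = 2, shear_rate = 0, ...) {
  sim_params(n_beads = n_beads, fene_k = 0, harmonic_k = 0, pair_epsilon = 0,
             shear_rate = shear_rate, ...)
}

# a synthetic trajectory whose frames are iid random conformations: mixes
# instantly, so observation-level decorrelation properties are exact
iid_trajectory <- function(n_frames = 100, n_beads = 10, seed = 1,
                           params = sim_params(n_beads = n_beads)) {
  set.seed(seed)
  pos <- array(rnorm(n_frames * n_beads * 3, sd = 20),
               c(n_frames, n_beads, 3))
  ten <- matrix(abs(rnorm(n_frames * n_beads / 2, sd = 4)),
                n_frames, n_beads / 2)
  vwf_trajectory(times = seq_len(n_frames) * params$sample_interval,
                 positions = pos, tensions = ten, params = params,
                 replica = 1L)
}

# separable toy dataset built on the iid trajectory; responses derive from
# the synthetic tensions, so forests have a learnable signal
make_toy_dataset <- function(n = 400, n_beads = 10, seed = 1) {
  tr <- iid_trajectory(n_frames = n + 1, n_beads = n_beads, seed = seed)
  obs <- sample_observations(tr, stride = 1)
  ds <- build_dataset(obs, 5, label_config(unfold_threshold = 4))
  split_dataset(ds, 0.7, seed = seed)
}
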