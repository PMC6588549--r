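---
title: "Predicting A2 domain state from macromolecular conformation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting A2 domain state from macromolecular conformation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

von Willebrand Factor (vWF) is a long multimeric blood protein that acts as a
mechanosensor: under elevated shear it unravels from a compact globule, and
once unraveled the force-sensitive A2 domain of individual monomers can
unfold, exposing the ADAMTS13 cleavage site that regulates multimer size.
`a2forest` implements a complete in-silico version of the question "can the
instantaneous folded/unfolded state of sub-monomer A2 domains be predicted
from macromolecular conformation alone?": a coarse-grained Brownian-dynamics
simulator generates sheared vWF conformations with known per-domain tensions,
conformational features are extracted at three contour resolutions, and
per-segment random forests are trained to predict A2 state, with
Gini-importance analysis revealing which large-scale motions accompany
unfolding.

## The physical model

A multimer of 50 monomers is a chain of `N = 100` beads.  Monomer `i`
consists of beads `2i - 1` and `2i` joined by a FENE spring that stands in
for the A2 domain:

$$F(r) = \frac{k\,r}{1 - (r/R_0)^2},$$

linear at small extension and divergent at the maximum extension $R_0$,
which mimics the steep force-extension response of the domain approaching
full extension.  Adjacent monomers are joined by stiff harmonic springs
(disulfide bonds) with stiffness 50 times the FENE constant.  All beads
interact through a truncated Lennard-Jones potential whose attractive well
collapses the chain into a globule at rest.  The ambient flow is unbounded
simple shear, $v_x = \dot\gamma z$ (x = flow, y = vorticity, z = gradient);
dynamics are overdamped Euler-Maruyama with free-draining Stokes mobility
and fluctuation-dissipation-consistent noise (variance $2 D \Delta t$ per
coordinate).  A pairwise Rotne-Prager-Yamakawa mobility is available behind
`hi_mode = "pairwise-mobility-tensor"` for small systems; it is a dense
$O(N^3)$ path and is not used in the production analyses.

The A2 state is defined by tension thresholding: a domain is *unfolded* at
the instant its FENE tension exceeds 11 pN (the centre of the 7-15 pN range
measured in single-molecule pulling experiments), *folded* otherwise, with
ties folded.  This instantaneous threshold rule is deliberately simple; it
ignores the activated (barrier-crossing) character of real unfolding.

## Parameters, units and calibration

User-facing parameters are physical (nm, pN, s, K); internally the
integrator runs in reduced units (length = `pair_sigma`, energy = kT, time
$\tau = \zeta \sigma^2 / k_BT$ with $\zeta = 6\pi\eta a$), and `sim_scales()`
exposes the mapping.  Defaults:

| parameter | default | why |
|---|---|---|
| `n_beads` | 100 | 50 monomers, mid-physiological multimer size |
| `bead_radius` | 2.5 nm | sets the Stokes drag and the LCC length unit |
| `fene_R0` | 60 nm | order of the unfolded A2 contour length |
| `fene_k` | 0.3249 pN/nm | places F = 11 pN at 0.45 R0 |
| `harmonic_k` | 50 x `fene_k` | "stiff" disulfide bond |
| `pair_epsilon` | 1.0 kT | collapses the rest-state chain; see below |
| `pair_sigma`, `pair_cutoff` | 5 nm, 12.5 nm | bead diameter; 2.5 sigma cutoff |
| `shear_rate` | 5e5 /s | strong-shear condition of the study |
| `viscosity` | 2e-3 Pa s | plasma-like effective medium; see below |
| `dt` | 5.6e-10 s | about 1e-3 tau, stable for all stiff modes present |
| `sample_interval` | 2.24e-7 s | 400 steps; velocity-feature window |
| `unfold_threshold` | 11 pN | centre of the experimental unfolding range |

The spring constants and $R_0$ follow published force-extension fits only in
order of magnitude; they are modelling defaults, not measured values, and are
deliberately exposed in `sim_params()`.  The cohesion and drag defaults were
*calibrated once* so that the nominal shear rate of $5\times10^5\,/s$ sits in
the regime the study describes: with stronger cohesion (2 kT) or a watery
medium the free-draining globule essentially never unravels at this shear
rate, whereas the defaults give intermittent globule-stretch dynamics, an
ensemble tension profile that is quasi-parabolic along the contour (the
central quintile carries roughly twice the tension of the terminal ones),
frequent mid-chain unfolding and rare terminal unfolding.  The calibration
was judged on steady-state statistics (long runs with the initial transient
discarded), since the collapsed-globule transient under-represents
unraveled states.  These qualitative facts - not any
prediction-performance number - were the calibration criteria, and the
values have been frozen since.

## Features

The chain is partitioned along its contour into 1, 5 or 10 equal segments
(100, 20 or 10 beads).  For each segment the 17 per-partition features are:
centre-of-mass velocity components (finite difference over one sampling
interval), the flow-induced displacement $|\dot\gamma \bar z \Delta t_s|$,
per-axis maximum spans, end-to-end distance, gyration components and total
($RG_{TOT}^2 = RG_X^2+RG_Y^2+RG_Z^2$), the flow-variation fraction
$VFF = RG_X/(RG_X+RG_Y+RG_Z)$, the local chain concentration (fraction of
*all* beads within 50/10/5 bead radii of the partition COM at chain-level /
5-segment / 10-segment resolution - the threshold-to-partition-size ratio is
1/2 at every resolution), and the absolute cosines between the three
principal axes of the partition's position covariance and the flow
direction.  In addition every raw bead coordinate is an input (300 features
for N = 100); for reporting these are aggregated into three position-sum
indices, so the reported index count is `3 + 17 * n_segments` (20, 88, 173)
while the model consumes `3N + 17 * n_segments` inputs.

Numerical choices: the covariance uses 1/n normalisation; eigenvector signs
are arbitrary, so projections are reported as absolute cosines; degenerate
(tied) eigenvalues are ordered preferring alignment with x, then y, then z,
which makes symmetric configurations deterministic.  A partition with zero
spatial extent returns VFF = 0 with a warning.  The batched C++ feature path
is tested against independent scalar R implementations of every operation
and against closed-form fixture conformations (rods, globules, prescribed
drifts) to 1e-8 or better.

## Dataset construction

Frames are sampled every `sample_interval`; observations take every
`stride`-th frame paired with its predecessor (for the velocity window) and
are pooled over replicas.  The pool is balanced at the *chain* level - half
the rows have no unfolded domain, half at least one - and split 70/30,
stratified by the chain-level label.  Per-segment imbalance is deliberately
preserved: terminal segments contribute very few unfolded rows, which is
exactly the failure mode the per-segment recall analysis exposes.

On decorrelation: the globule-stretch dynamics are episodic, so the chain's
radius-of-gyration autocorrelation time is much longer than any stride a
desk-scale run can afford.  The stride-based decorrelation contract is
verified exactly on fast-mixing synthetic trajectories; for the production
pipeline the achieved lag-1 autocorrelation is recorded in the run manifest
rather than forced below a threshold.  Residual serial correlation means
train and test rows are not fully independent, which can flatter recall
estimates relative to the fully decorrelated ideal; the per-segment
orderings (terminal versus central performance) are insensitive to this.

## Forests and importance

One binary random forest is trained per (resolution, segment) plus one for
the chain level, each seeing the full input set so that importances can
reveal cross-segment structure.  Trees split on Gini impurity
$\sum_i f_i(1-f_i)$; prediction is majority vote; training is delegated to
`ranger` (100 trees, `mtry = sqrt(p)`, bootstrap on, single-threaded for
determinism) with `importance = "impurity"`, i.e. mean decrease in Gini -
matching the splitting criterion; permutation importance is intentionally
not used.  Performance is reported as per-class recall (folded and unfolded
separately) on the test split, which is the honest view under strong
per-segment imbalance.  Raw importances are normalised to sum to one,
aggregated onto the reported feature indices (position components summed
into the three position-sum indices; totals conserved exactly), ranked with
ties broken toward the lower index, and annotated with each feature's
segment of origin so cross-segment entries - the signature of correlated
segment dynamics - are flagged.  Per-bead, per-axis position-importance
profiles along the contour are available from `position_profile()`.

## Scale of the shipped analyses

The desk-scale study conditions used by the test suite and the acceptance
script are 8 replicas of 18,000 sampled frames (about 4 ms of physical time
per replica), stride 4 (about 36,000 pooled observations), 20,000 balanced
rows, and 100-tree forests; forests are fitted for the chain level and for
the terminal/central segments that the reported comparisons use.  A
full-size run (22 replicas, 200,000 observations, forests for every
segment) is a configuration change in `experiment_config()`, not a code
change.

```{r, eval = FALSE}
library(a2forest)
cfg <- experiment_config(n_replicas = 8, n_frames = 18000, stride = 4,
                         n_total = 20000, seed = 1)
ex <- run_experiment(cfg)
ex$performance[["5"]]
top_k_cumulative(ex$importance[["5"]]$by_index[["y_s3"]], 14)
```

## What the generator does and does not emulate

It emulates: collapse to a rest-state globule, shear-driven intermittent
unraveling and tumbling, a centre-peaked internal tension profile,
instantaneous threshold unfolding, and non-interacting replicas.  It does
not emulate: hydrodynamic interactions in production (free-draining
default), walls or complex flow fields, atomistic A2 structure, activated
unfolding kinetics, ADAMTS13 cleavage, or measurement noise of any
experimental imaging modality.  Passing tests therefore certify the
pipeline's statistical machinery and the simulator's stated physics, not
quantitative agreement with laboratory vWF data.

## Known limitations

- The cohesion/drag calibration stands in for unpublished model constants;
  absolute tensions and unfolding rates inherit that uncertainty.
- Free-draining mobility omits hydrodynamic shielding, which shifts the
  globule-stretch transition; the RPY option exists but is too slow for
  production ensembles.
- Serial correlation between observations (discussed above).
- Threshold labelling ignores unfolding/refolding hysteresis.
- Terminal segments can have so few unfolded training rows that a
  single-class training set occurs for very short runs; `a2_forest()`
  refuses to fit such a response and says so.
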