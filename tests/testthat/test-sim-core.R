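test_that("FENE force has the right limits, values and monotonicity", {
  expect_equal(fene_force(0, k = 1, R0 = 1), 0)
  expect_equal(fene_force(0.5, k = 1, R0 = 1), 0.5 / (1 - 0.25),
               tolerance = 1e-12)  # 0.6667
  # diverges approaching R0
  expect_gt(fene_force(1 - 1e-9, k = 1, R0 = 1), 1e6)
  expect_error(fene_force(1, k = 1, R0 = 1), "over-extended")
  expect_error(fene_force(1.5, k = 1, R0 = 1), "over-extended")
  # strictly increasing
  r <- seq(0, 0.99, length.out = 200)
  expect_true(all(diff(fene_force(r, k = 2.3, R0 = 1)) > 0))
  # linear regime: within 1% of k*r for r < 0.05 R0
  r <- seq(1e-4, 0.05, length.out = 50) * 60
  expect_true(all(abs(fene_force(r, k = 0.3249, R0 = 60) / (0.3249 * r) - 1)
                  < 0.01))
})

test_that("shear velocity is gamma_dot * z in x only", {
  expect_equal(shear_velocity(0, 5e5), 0)
  expect_equal(shear_velocity(7.3, 0), 0)
  expect_equal(shear_velocity(2, 3), 6)
})

test_that("a2_tensions delegates to the FENE law, one value per monomer", {
  p <- sim_params(n_beads = 100)
  pos <- matrix(0, 100, 3)
  pos[, 1] <- rep(seq_len(50) * 20, each = 2)   # coincident pairs
  expect_equal(a2_tensions(pos, p), rep(0, 50))
  expect_length(a2_tensions(pos, p), 50)
  pos[2, ] <- pos[1, ] + c(30, 0, 0)            # one pair at extension 30 nm
  ten <- a2_tensions(pos, p)
  expect_equal(ten[1], fene_force(30, p$fene_k, p$fene_R0))
  expect_equal(ten[-1], rep(0, 49))
})

test_that("internal forces cancel pairwise and over-extension errors", {
  p <- tiny_params()
  set.seed(4)
  pos <- matrix(rnorm(24, sd = 0.4), 8, 3) + cbind(seq_len(8) * 1.1, 0, 0)
  f <- a2forest:::.bd_forces(pos, a2forest:::reduced_params(p))
  expect_equal(colSums(f$forces), rep(0, 3), tolerance = 1e-10)
  # tensions match the scalar law
  expect_equal(as.vector(f$tensions) * sim_scales(p)$force_pN,
               a2_tensions(pos * p$pair_sigma, p), tolerance = 1e-10)
  # over-extended spring is a domain error
  pos[2, 1] <- pos[1, 1] + a2forest:::reduced_params(p)$fene_R0 + 0.1
  expect_error(a2forest:::.bd_forces(pos, a2forest:::reduced_params(p)),
               "over-extended")
})

test_that("deterministic drift: pure shear advection is exact", {
  # noise off, no interactions: one step displaces x by gamma_dot * z * dt
  p <- free_params(n_beads = 2, shear_rate = 5e5)
  s <- sim_scales(p)
  z0 <- c(100, -40) / s$sigma_nm
  pos <- cbind(0, 0, z0)
  dimnames(pos) <- NULL
  rp <- a2forest:::reduced_params(p, noise = FALSE)
  out <- a2forest:::.bd_run(pos, rp, 1, 0L, 1)
  expect_equal(out$final[, 1], rp$shear * z0 * rp$dt, tolerance = 1e-12)
  expect_equal(out$final[, 2:3], pos[, 2:3])
  # quiescent fluid, no forces, no noise: nothing moves
  rp0 <- a2forest:::reduced_params(free_params(2), noise = FALSE,
                                   shear_on = FALSE)
  out0 <- a2forest:::.bd_run(pos, rp0, 50, 0L, 1)
  expect_equal(out0$final, pos)
})

test_that("free-bead diffusion satisfies the Einstein relation within 5%", {
  # 200 ideal beads x 3 seeds, 1e5 steps; D = 1 in reduced units
  p <- free_params(n_beads = 200)
  rp <- a2forest:::reduced_params(p, shear_on = FALSE)
  ratio <- vapply(1:3, function(sd0) {
    out <- a2forest:::.bd_run(matrix(0, 200, 3), rp, 1e5, 0L, sd0 * 977)
    mean(rowSums(out$final^2)) / (6 * 1e5 * rp$dt)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("trajectories are bit-identical under a fixed seed", {
  p <- tiny_params()
  pos <- a2forest:::initial_walk(p, 3)
  rp <- a2forest:::reduced_params(p)
  o1 <- a2forest:::.bd_run(pos, rp, 500, 100L, 99)
  o2 <- a2forest:::.bd_run(pos, rp, 500, 100L, 99)
  expect_identical(o1$final, o2$final)
  expect_identical(o1$sampled_positions, o2$sampled_positions)
  # and through the frame-level interface
  fr <- vwf_frame(0, pos * p$pair_sigma, a2_tensions(pos * p$pair_sigma, p))
  expect_identical(bd_step(fr, p, seed = 5), bd_step(fr, p, seed = 5))
})

test_that("equilibration yields a compact globule; repulsive variant swells", {
  p <- sim_params(n_beads = 30)
  contour <- 15 * 1.12 * p$pair_sigma + 14 * p$harmonic_r0
  rg_tot <- function(fr) {
    sqrt(mean(rowSums(sweep(fr$positions, 2, colMeans(fr$positions))^2)))
  }
  # purely repulsive chain: truncate the pair potential at the LJ minimum
  prep <- sim_params(n_beads = 30, pair_cutoff = 2^(1 / 6) * p$pair_sigma)
  rg_att <- numeric(3); rg_rep <- numeric(3)
  for (i in 1:3) {
    rg_att[i] <- rg_tot(equilibrate(p, seed = 100 + i, window = 5e3))
    rg_rep[i] <- rg_tot(equilibrate(prep, seed = 100 + i, window = 5e3))
  }
  expect_lt(mean(rg_att), 0.2 * contour)
  expect_gt(mean(rg_rep), mean(rg_att))
  # determinism
  e1 <- equilibrate(p, seed = 77, window = 2e3)
  e2 <- equilibrate(p, seed = 77, window = 2e3)
  expect_identical(e1$positions, e2$positions)
})

test_that("simulate_vwf produces valid uniformly sampled replicas", {
  p <- sim_params(n_beads = 20, n_replicas = 2)
  trs <- simulate_vwf(p, n_frames = 25, seed = 8, equilibrate_first = FALSE)
  expect_length(trs, 2)
  for (tr in trs) {
    expect_s3_class(tr, "vwf_trajectory")
    expect_equal(dim(tr$positions), c(25, 20, 3))
    expect_equal(ncol(tr$tensions), 10)   # one tension per monomer
    expect_equal(diff(tr$times), rep(p$sample_interval, 24))
    expect_true(all(tr$tensions >= 0))
  }
  # replicas are distinct (independent sub-seeds)
  expect_false(identical(trs[[1]]$positions, trs[[2]]$positions))
})

test_that("shear stretches the ensemble relative to the quiescent case", {
  p_sh <- sim_params(n_beads = 20, n_replicas = 2)
  p_no <- sim_params(n_beads = 20, n_replicas = 2, shear_rate = 0)
  ext_x <- function(trs) {
    mean(vapply(trs, function(tr)
      mean(apply(tr$positions[, , 1], 1, function(v) diff(range(v)))),
      numeric(1)))
  }
  t_sh <- simulate_vwf(p_sh, n_frames = 150, seed = 21)
  t_no <- simulate_vwf(p_no, n_frames = 150, seed = 21)
  expect_gt(ext_x(t_sh), ext_x(t_no))
})

test_that("pairwise-mobility (RPY) integration runs and is deterministic", {
  p <- sim_params(n_beads = 6, hi_mode = "pairwise-mobility-tensor")
  pos <- a2forest:::initial_walk(p, 2)
  rp <- a2forest:::reduced_params(p)
  expect_true(rp$hi)
  o1 <- a2forest:::.bd_run(pos, rp, 50, 0L, 13)
  o2 <- a2forest:::.bd_run(pos, rp, 50, 0L, 13)
  expect_identical(o1$final, o2$final)
  expect_false(identical(o1$final, pos))
})
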