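test_that("chain partitioning gives equal contiguous contour ranges", {
  p5 <- partition_chain(100, 5)
  expect_equal(p5$segment_size, 20)
  expect_equal(p5$ranges[[3]], c(41, 60))
  p10 <- partition_chain(100, 10)
  expect_equal(p10$segment_size, 10)
  p1 <- partition_chain(100, 1)
  expect_equal(p1$ranges[[1]], c(1, 100))
  expect_error(partition_chain(100, 3), "divide")
  # ranges are disjoint, ordered, cover all beads
  covered <- unlist(lapply(p10$ranges, function(r) seq(r[1], r[2])))
  expect_equal(covered, 1:100)
})

test_that("max extent matches the brute-force pairwise oracle", {
  expect_equal(max_axis_extent(matrix(c(3, 1, 2), 1, 3), 1), 0)
  expect_equal(max_axis_extent(cbind(c(0, 5), 0, 0), 1), 5)
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rnorm(60, sd = 10), 20, 3)
    for (ax in 1:3) {
      oracle <- max(abs(outer(m[, ax], m[, ax], "-")))
      expect_equal(max_axis_extent(m, ax), oracle)
    }
  }
  expect_error(max_axis_extent(matrix(numeric(0), 0, 3), 1), "empty")
})

test_that("end-to-end distance uses first and last contour beads only", {
  m <- rbind(c(0, 0, 0), matrix(rnorm(30), 10, 3), c(3, 4, 0))
  expect_equal(end_to_end(m), 5)
  expect_equal(end_to_end(rbind(c(1, 2, 3), c(5, 5, 5), c(1, 2, 3))), 0)
  expect_error(end_to_end(matrix(1:3, 1)), "2 beads")
})

test_that("gyration components satisfy the Pythagorean identity", {
  m0 <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_equal(unname(gyration(m0)), rep(0, 4))
  mx <- cbind(rnorm(10), 0, 0)
  g <- gyration(mx)
  expect_equal(unname(g[2:3]), c(0, 0))
  expect_equal(g[["RG_TOT"]], g[["RG_X"]])
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rnorm(45, sd = 3), 15, 3)
    g <- gyration(m)
    expect_equal(g[["RG_TOT"]]^2,
                 g[["RG_X"]]^2 + g[["RG_Y"]]^2 + g[["RG_Z"]]^2,
                 tolerance = 1e-9)
    # direct |r - com| oracle
    direct <- sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
    expect_equal(g[["RG_TOT"]], direct, tolerance = 1e-12)
  }
})

test_that("flow-variation fraction follows its defining ratio", {
  expect_equal(variation_fraction_flow(2, 2, 2), 1 / 3)
  expect_equal(variation_fraction_flow(4, 0, 0), 1)
  expect_equal(variation_fraction_flow(3, 2, 1), 0.5)
  expect_warning(v0 <- variation_fraction_flow(0, 0, 0), "degenerate|undefined")
  expect_equal(v0, 0)
})

test_that("local chain concentration counts all beads within threshold", {
  p <- sim_params()
  # thresholds are 50 / 10 / 5 bead radii; ratio to partition size is 1/2
  for (res in c(1, 5, 10)) {
    thr <- a2forest:::lcc_threshold_radii(res)
    expect_equal(thr / (100 / res), 1 / 2)
  }
  expect_error(a2forest:::lcc_threshold_radii(4), "threshold")
  # compact globule entirely inside 50 a: chain-level LCC = 1
  fx <- generate_fixture("globule", p, globule_radius = 3 * p$bead_radius)
  expect_equal(local_chain_concentration(fx$frame_t, partition_chain(100, 1),
                                         1, p), 1)
  # constructed geometry: 20-bead segment isolated far from the other 80
  pos <- matrix(0, 100, 3)
  pos[1:20, 1] <- rnorm(20, sd = 2)          # tight cluster at origin
  pos[21:100, 1] <- 1e4 + rnorm(80, sd = 2)  # far away
  fr <- vwf_frame(0, pos, rep(0, 50))
  expect_equal(local_chain_concentration(fr, partition_chain(100, 5), 1, p),
               0.2)
})

test_that("principal-axis projections agree with an SVD oracle", {
  rod <- cbind(seq_len(20), 0, 0)
  expect_equal(unname(pca_flow_projections(rod)), c(1, 0, 0),
               tolerance = 1e-12)
  rod_y <- cbind(0, seq_len(20), 0)
  expect_equal(pca_flow_projections(rod_y)[["PCA_1"]], 0, tolerance = 1e-12)
  set.seed(99)
  for (i in 1:8) {
    m <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 2, 0.5))
    got <- pca_flow_projections(m)
    sv <- svd(sweep(m, 2, colMeans(m)))
    expect_equal(unname(got), abs(sv$v[1, ]), tolerance = 1e-8)
    expect_true(all(got >= 0 & got <= 1))
    # projections invariant to bead order
    expect_equal(got, pca_flow_projections(m[sample(20), ]))
  }
})

test_that("COM velocity equals the mean of per-bead finite differences", {
  p <- sim_params(n_beads = 20)
  part <- partition_chain(20, 5)
  set.seed(41)
  pos <- matrix(rnorm(60, sd = 10), 20, 3)
  same <- vwf_frame(p$sample_interval, pos, rep(0, 10))
  prev <- vwf_frame(0, pos, rep(0, 10))
  expect_equal(unname(com_velocity(same, prev, part, 2, p$sample_interval)),
               c(0, 0, 0))
  # uniform translation d over dt_s
  d <- c(3, -1, 2)
  tr <- vwf_frame(p$sample_interval, sweep(pos, 2, -d), rep(0, 10))
  expect_equal(unname(com_velocity(tr, prev, part, 4, p$sample_interval)),
               d / p$sample_interval)
  # arbitrary motion: linearity of the COM
  pos2 <- pos + matrix(rnorm(60), 20, 3)
  ft <- vwf_frame(p$sample_interval, pos2, rep(0, 10))
  idx <- 5:8  # segment 2
  oracle <- colMeans((pos2[idx, ] - pos[idx, ]) / p$sample_interval)
  expect_equal(unname(com_velocity(ft, prev, part, 2, p$sample_interval)),
               oracle)
  expect_error(com_velocity(ft, prev, part, 2, p$sample_interval * 3),
               "consecutive")
})

test_that("flow-induced displacement is |gamma_dot * mean z * dt|", {
  p <- sim_params(n_beads = 10)
  part <- partition_chain(10, 1)
  pos <- cbind(0, 0, rep(3, 10))
  fr <- vwf_frame(0, pos, rep(0, 5))
  expect_equal(flow_induced_displacement(fr, part, 1, 2, 0.5), 3)
  expect_equal(flow_induced_displacement(fr, part, 1, 0, 0.5), 0)
  pos0 <- cbind(rnorm(10), rnorm(10), 0)
  expect_equal(flow_induced_displacement(vwf_frame(0, pos0, rep(0, 5)),
                                         part, 1, 5e5, 1e-7), 0)
})

test_that("reported feature index counts and layout match the table", {
  expect_equal(nrow(feature_index_map(1)), 20)
  expect_equal(nrow(feature_index_map(5)), 88)
  expect_equal(nrow(feature_index_map(10)), 173)
  fm5 <- feature_index_map(5)
  # MAX_X occupies indices 24-28 at 5-segment resolution
  expect_equal(fm5$index[fm5$symbol == "MAX_X"], 24:28)
  fm10 <- feature_index_map(10)
  expect_equal(fm10$index[fm10$symbol == "PCA_3"], 164:173)
  expect_equal(fm10$index[fm10$symbol == "v_X"], 4:13)
  # bijection: indices are exactly 1..count
  expect_equal(fm10$index, 1:173)
  # every model input maps to exactly one reported index
  im <- a2forest:::input_index_map(5, 100)
  expect_equal(nrow(im), 300 + 17 * 5)
  expect_equal(sum(im$index %in% 1:3), 300)
})

test_that("full feature vectors have the right size and raw content", {
  p <- sim_params()
  set.seed(7)
  pos <- matrix(rnorm(300, sd = 25), 100, 3)
  ft <- vwf_frame(p$sample_interval, pos, rep(0, 50))
  fp <- vwf_frame(0, pos - 1, rep(0, 50))
  for (res in c(1, 5, 10)) {
    fv <- extract_features(ft, fp, p, res)
    expect_length(fv, 300 + 17 * res)
    expect_equal(nrow(attr(fv, "index_map")), 3 + 17 * res)
  }
  fv <- extract_features(ft, fp, p, 5)
  expect_equal(unname(fv[paste0("x_b", 1:100)]), pos[, 1])
  expect_equal(unname(fv[["z_b42"]]), pos[42, 3])
})

test_that("batch features agree with scalar reference operations", {
  p <- sim_params()
  part <- partition_chain(100, 5)
  set.seed(55)
  pos <- matrix(rnorm(300, sd = 15), 100, 3)
  prev <- pos - matrix(rnorm(300, sd = 1), 100, 3)
  ft <- vwf_frame(p$sample_interval, pos, rep(0, 50))
  fp <- vwf_frame(0, prev, rep(0, 50))
  fv <- extract_features(ft, fp, p, 5)
  for (s in 1:5) {
    seg <- pos[(20 * s - 19):(20 * s), ]
    g <- gyration(seg)
    expect_equal(fv[[paste0("RG_TOT_s", s)]], g[["RG_TOT"]], tolerance = 1e-9)
    expect_equal(fv[[paste0("MAX_Y_s", s)]], max_axis_extent(seg, 2),
                 tolerance = 1e-9)
    expect_equal(fv[[paste0("EE_s", s)]], end_to_end(seg), tolerance = 1e-9)
    expect_equal(fv[[paste0("VFF_s", s)]],
                 variation_fraction_flow(g[["RG_X"]], g[["RG_Y"]], g[["RG_Z"]]),
                 tolerance = 1e-9)
    expect_equal(fv[[paste0("LCC_s", s)]],
                 local_chain_concentration(ft, part, s, p), tolerance = 1e-12)
    expect_equal(unname(fv[paste0(c("PCA_1", "PCA_2", "PCA_3"), "_s", s)]),
                 unname(pca_flow_projections(seg)), tolerance = 1e-8)
    expect_equal(unname(fv[paste0(c("v_X", "v_Y", "v_Z"), "_s", s)]),
                 unname(com_velocity(ft, fp, part, s, p$sample_interval)),
                 tolerance = 1e-6)
    expect_equal(fv[[paste0("Dr_s", s)]],
                 flow_induced_displacement(ft, part, s, p$shear_rate,
                                           p$sample_interval),
                 tolerance = 1e-9)
  }
})

test_that("shape features are invariant under rigid translation", {
  p <- sim_params()
  set.seed(77)
  pos <- matrix(rnorm(300, sd = 15), 100, 3)
  ft <- vwf_frame(p$sample_interval, pos, rep(0, 50))
  fp <- vwf_frame(0, pos, rep(0, 50))
  shift <- c(120, -55, 80)
  ft2 <- vwf_frame(p$sample_interval, sweep(pos, 2, -shift), rep(0, 50))
  fp2 <- vwf_frame(0, sweep(pos, 2, -shift), rep(0, 50))
  a <- extract_features(ft, fp, p, 5)
  b <- extract_features(ft2, fp2, p, 5)
  inv <- grep("^(MAX|EE|RG|PCA|VFF|LCC)", names(a), value = TRUE)
  expect_equal(a[inv], b[inv], tolerance = 1e-9)
})

test_that("fixture archetypes reproduce their closed-form feature values", {
  p <- sim_params()
  rod <- generate_fixture("rod-x", p)
  fv <- extract_features(rod$frame_t, rod$frame_prev, p, 1)
  expect_equal(fv[["VFF_s1"]], 1)
  expect_equal(fv[["PCA_1_s1"]], 1)
  expect_equal(fv[["RG_Y_s1"]], 0)
  expect_equal(fv[["RG_Z_s1"]], 0)
  expect_equal(fv[["MAX_X_s1"]], 99 * p$pair_sigma)
  expect_equal(fv[["EE_s1"]], 99 * p$pair_sigma)
  # prescribed drift sets every partition's COM velocity
  d <- c(10, 4, -6)
  g <- generate_fixture("globule", p, drift = d, seed = 3)
  fv <- extract_features(g$frame_t, g$frame_prev, p, 5)
  for (s in 1:5)
    expect_equal(unname(fv[paste0(c("v_X", "v_Y", "v_Z"), "_s", s)]),
                 d / p$sample_interval, tolerance = 1e-6)
})
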