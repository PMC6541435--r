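# Two-node overlap simulator: configuration validation, ground-truth
# bookkeeping, and the spatial/temporal structure it is supposed to plant.

test_that("configuration invariants are enforced", {
  expect_error(overlap_sim_config(node_size = 10, overlap_fraction = 0.15),
               "not an integer")
  expect_error(overlap_sim_config(n_voxels = 150, node_size = 100),
               "exceed")
  expect_error(overlap_sim_config(weight_low = 5, weight_high = 2),
               "weight_low")
  # equal weight bounds are allowed (constant weights)
  expect_s3_class(overlap_sim_config(weight_low = 7, weight_high = 7),
                  "overlap_sim_config")
})

test_that("node supports have the configured size and overlap, and data is
           the exact outer product of the stored truth", {
  sim <- simulate_overlap(tiny_overlap_cfg())
  tr <- sim$truth
  expect_length(sim$data, 5L)
  expect_equal(dim(sim$data[[1]]), c(60L, 500L))
  expect_length(tr$supports[[1]], 20L)
  expect_length(tr$supports[[2]], 20L)
  expect_length(tr$overlap, 5L) # 20 * 0.25
  # reconstruction: data minus recorded noise (zero here: map noise is part
  # of the stored subject maps) equals T %*% t(M) exactly
  for (s in c(1L, 3L)) {
    expect_identical(sim$data[[s]],
                     tr$timecourses[[s]] %*% tr$subject_maps[[s]])
    expect_equal(tr$subject_maps[[s]],
                 tr$group_maps + tr$map_noise[[s]])
  }
  # netmats are symmetric with unit diagonal
  expect_equal(tr$tnet[[1]], t(tr$tnet[[1]]))
  expect_equal(diag(tr$snet[[2]]), c(1, 1))
})

test_that("noise-free constant-weight maps reproduce the closed-form
           spatial correlation of the two weight vectors", {
  cfg <- overlap_sim_config(n_voxels = 10000, n_subjects = 2,
                            n_timepoints = 30, node_size = 100,
                            overlap_fraction = 0.25, background_scale = 0,
                            weight_low = 7, weight_high = 7,
                            map_noise_scale = 0, seed = 5)
  sim <- simulate_overlap(cfg)
  # oracle: direct Pearson correlation of two independently constructed
  # 10000-length weight vectors with the same support geometry
  v1 <- v2 <- numeric(10000)
  v1[1:100] <- 7
  v2[76:175] <- 7
  expect_equal(sim$truth$snet[[1]][1, 2], cor(v1, v2), tolerance = 1e-12)
  expect_equal(cor(v1, v2), 0.2424, tolerance = 1e-3)
})

test_that("zero overlap with no background or noise gives exactly zero
           spatial correlation", {
  cfg <- overlap_sim_config(n_voxels = 500, n_subjects = 2,
                            n_timepoints = 30, node_size = 20,
                            overlap_fraction = 0, background_scale = 0,
                            map_noise_scale = 0, seed = 1)
  sim <- simulate_overlap(cfg)
  # disjoint supports, zero elsewhere: correlation is the (slightly
  # negative) value implied by the two disjoint indicator supports
  v1 <- v2 <- numeric(500)
  v1[sim$truth$supports[[1]]] <- sim$truth$node_weights[[1]]
  v2[sim$truth$supports[[2]]] <- sim$truth$node_weights[[2]]
  expect_equal(sim$truth$snet[[1]][1, 2], cor(v1, v2), tolerance = 1e-12)
  expect_length(sim$truth$overlap, 0L)
})

test_that("realised temporal correlation is monotone in the shared-signal
           weight and positive spatial edges come with positive overlap", {
  r_t <- vapply(c(0, 0.3, 0.8165, 2), function(w) {
    sim <- simulate_overlap(tiny_overlap_cfg(shared_signal_weight = w))
    mean(vapply(sim$truth$tnet, function(m) m[1, 2], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r_t) > 0))
  sim <- simulate_overlap(tiny_overlap_cfg())
  expect_true(all(vapply(sim$truth$snet, function(m) m[1, 2], numeric(1)) > 0))
})

test_that("the same seed reproduces bit-identical output and repeats
           differ", {
  a <- simulate_overlap(tiny_overlap_cfg(), 2)
  b <- simulate_overlap(tiny_overlap_cfg(), 2)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$group_maps, b$truth$group_maps)
  c2 <- simulate_overlap(tiny_overlap_cfg(), 1)
  expect_false(identical(a$truth$group_maps, c2$truth$group_maps))
})
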