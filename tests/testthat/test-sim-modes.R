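# Parcel-based mode simulator: atlas, warps, node maps, timecourses, HRF
# and the assembled noise model.

test_that("atlas parcels tile the voxel line and the symmetric limit gives
           equal widths", {
  cfg <- tiny_modes_cfg()
  set.seed(1)
  atlas <- generate_atlas(cfg)
  expect_equal(sum(atlas$widths), cfg$n_voxels)
  expect_true(all(atlas$widths >= 1L))
  expect_length(atlas$parcel_of_voxel, cfg$n_voxels)
  expect_equal(atlas$starts[1], 1L)
  expect_true(all(atlas$weights > 0))
  # concentration -> infinity: all widths equal n_voxels / n_parcels
  set.seed(1)
  atlas_inf <- generate_atlas(tiny_modes_cfg(parcel_width_conc = 1e12))
  expect_true(all(atlas_inf$widths == cfg$n_voxels / cfg$n_parcels))
  # determinism
  set.seed(9); a1 <- generate_atlas(cfg)
  set.seed(9); a2 <- generate_atlas(cfg)
  expect_identical(a1, a2)
})

test_that("warps are identity at zero amplitude, bounded by the average
           parcel size, and monotone (invertible)", {
  cfg <- tiny_modes_cfg()
  set.seed(2)
  atlas <- generate_atlas(cfg)
  warps0 <- generate_warps(tiny_modes_cfg(warp_amplitude = 0), atlas)
  expect_true(all(vapply(warps0, function(w) all(w == 0), logical(1))))
  maps <- matrix(rnorm(2 * cfg$n_voxels), 2)
  expect_equal(apply_warp(maps, warps0[[1]]), maps)

  set.seed(3)
  warps <- generate_warps(cfg, atlas)
  avg <- mean(atlas$widths)
  for (w in warps) {
    expect_lte(max(abs(w)), avg + 1e-9)
    # voxel mapping v + d(v) strictly monotone
    expect_true(all(diff(seq_along(w) + w) > 0))
  }
})

test_that("node maps honour sign, jitter and warp settings and modes share
           parcels under the defaults", {
  cfg <- tiny_modes_cfg(neg_region_prob = 0, subject_jitter = 0,
                        warp_amplitude = 0)
  set.seed(4)
  atlas <- generate_atlas(cfg)
  warps <- generate_warps(cfg, atlas)
  nm <- generate_node_maps(cfg, atlas, warps)
  expect_true(all(nm$group_maps >= 0))
  for (s in seq_len(cfg$n_subjects)) {
    expect_equal(nm$subject_maps[[s]], nm$group_maps)
  }
  # default config: at least one pair of modes shares a parcel (oracle:
  # stored mode -> parcel assignments)
  sim <- simulate_modes(tiny_modes_cfg())
  shared <- combn(length(sim$truth$mode_parcels), 2, function(ij) {
    length(intersect(sim$truth$mode_parcels[[ij[1]]],
                     sim$truth$mode_parcels[[ij[2]]]))
  })
  expect_true(any(shared > 0))
})

test_that("timecourse sparsification boundaries and stored netmats behave
           as specified", {
  cfg <- tiny_modes_cfg(sparsify_threshold = -Inf)
  set.seed(5)
  tcs <- generate_timecourses(cfg)
  x <- tcs$series[[1]][[1]]
  expect_true(all(x != 0))
  expect_equal(tcs$tnet_run[[1]][[1]], cor(x), tolerance = 1e-12)
  expect_error(
    {
      set.seed(5)
      generate_timecourses(tiny_modes_cfg(sparsify_threshold = Inf))
    },
    "zeroes mode")
  # huge Wishart dof concentrates covariances at the identity
  set.seed(6)
  tcs_id <- generate_timecourses(tiny_modes_cfg(
    wishart_dof_group = 1e6, wishart_dof_subject = 1e6,
    wishart_dof_run = 1e6, sparsify_threshold = -Inf))
  offdiag <- edge_vector(cor(tcs_id$series[[1]][[1]]))
  expect_lt(max(abs(offdiag)), 0.2)
  expect_error(modes_sim_config(wishart_dof_group = 3, n_modes = 4),
               "at least n_modes")
})

test_that("HRF convolution matches a brute-force time-domain sum and
           degenerates correctly", {
  set.seed(7)
  x <- matrix(rnorm(40), 20, 2)
  expect_equal(hrf_convolve(x, 1), x, tolerance = 1e-12)
  kern <- c(0.2, 0.5, 0.3, -0.1)
  out <- hrf_convolve(x, kern)
  brute <- matrix(0, 20, 2)
  for (j in 1:2) {
    for (t in 1:20) {
      for (tau in seq_along(kern)) {
        if (t - tau + 1 >= 1) {
          brute[t, j] <- brute[t, j] + kern[tau] * x[t - tau + 1, j]
        }
      }
    }
  }
  expect_equal(out, brute, tolerance = 1e-10)
  expect_error(hrf_convolve(x, c(1, NA)), "non-finite")
  expect_error(hrf_convolve(x, rep(1, 25)), "shorter")
  # different subject kernels decorrelate identical neural input
  cfg <- tiny_modes_cfg()
  set.seed(8)
  k1 <- sample_hrf(cfg)
  k2 <- sample_hrf(cfg)
  expect_false(isTRUE(all.equal(k1, k2)))
  xl <- matrix(rnorm(200), 100, 2)
  y1 <- hrf_convolve(xl, k1)
  y2 <- hrf_convolve(xl, k2)
  expect_lt(cor(y1[, 1], y2[, 1]), 1)
})

test_that("assembled data honours the noise model and reconstructs from the
           stored components", {
  cfg <- tiny_modes_cfg(nonlin_strength = 0, structured_noise_var = 0,
                        unstructured_noise_var = 0)
  set.seed(9)
  tc <- matrix(rnorm(120 * 4), 120, 4)
  maps <- matrix(rnorm(4 * 400), 4, 400)
  asm <- assemble_data(tc, maps, cfg)
  expect_identical(asm$data, tc %*% maps)

  # realised noise variance fractions match the configuration within 5%
  cfg2 <- tiny_modes_cfg(nonlin_strength = 0.05)
  set.seed(10)
  asm2 <- assemble_data(tc, maps, cfg2)
  sv <- var(as.vector(asm2$signal))
  expect_equal(var(as.vector(asm2$structured)) / sv,
               cfg2$structured_noise_var, tolerance = 0.05)
  expect_equal(var(as.vector(asm2$unstructured)) / sv,
               cfg2$unstructured_noise_var, tolerance = 0.05)
  # reconstruction from stored components and noise
  expect_equal(asm2$data, asm2$signal + asm2$structured + asm2$unstructured,
               tolerance = 1e-12)
  # heavy-tail limit: t noise with huge dof is empirically Gaussian
  set.seed(11)
  big <- assemble_data(matrix(rnorm(3000), 1500, 2),
                       matrix(rnorm(400), 2, 200),
                       tiny_modes_cfg(t_dof = 1e6, structured_noise_var = 0))
  z <- as.vector(big$unstructured)
  kurt <- mean((z - mean(z))^4) / var(z)^2
  expect_equal(kurt, 3, tolerance = 0.1)
  expect_error(modes_sim_config(nonlin_strength = -1), "nonlin_strength")
})

test_that("the full mode simulation is deterministic under a fixed seed and
           its ground truth is coherent", {
  cfg <- tiny_modes_cfg()
  a <- simulate_modes(cfg, 1)
  b <- simulate_modes(cfg, 1)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$group_maps, b$truth$group_maps)
  tr <- a$truth
  # truth netmats: symmetric, unit diagonal, PSD
  for (m in list(tr$tnet[[1]], tr$snet[[2]])) {
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, cfg$n_modes))
    expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # stored pre-HRF tnet equals the correlation of the emitted series
  expect_equal(tr$tnet[[1]],
               cor(do.call(rbind, tr$neural[[1]])), tolerance = 1e-12)
  # reconstruction: nonlinearity(signal) + stored noise reproduces the data
  rec <- hrf_convolve(tr$neural[[2]][[1]], tr$hrf[[2]]) %*% tr$subject_maps[[2]]
  cc <- 1 / cfg$nonlin_strength
  rec <- cc * tanh(rec / cc)
  rec <- rec + tr$noise[[2]][[1]]$structured + tr$noise[[2]][[1]]$unstructured
  expect_equal(a$data[[2]][[1]], rec, tolerance = 1e-10)
  # zero warp and zero jitter leave no between-subject spatial variance
  cfg0 <- tiny_modes_cfg(warp_amplitude = 0, subject_jitter = 0)
  sim0 <- simulate_modes(cfg0, 1)
  edges <- vapply(sim0$truth$snet, edge_vector,
                  numeric(cfg0$n_modes * (cfg0$n_modes - 1) / 2))
  expect_equal(max(apply(edges, 1, var)), 0, tolerance = 1e-20)
})
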