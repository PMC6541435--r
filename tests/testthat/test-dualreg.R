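# Dual regression stages: closed-form oracles, operator identities and the
# stage-3/4 plumbing.

test_that("stage 1 returns the exact coefficients for orthonormal designs
           and matches the normal equations on a 3-voxel toy", {
  set.seed(1)
  # zero-mean orthonormal map rows
  G <- t(qr.Q(qr(scale(matrix(rnorm(20), 10, 2), scale = FALSE))))
  A <- matrix(rnorm(14), 7, 2)
  Y <- A %*% G
  expect_equal(dr_stage1(Y, G), A, tolerance = 1e-10)

  # explicit normal equations on the demeaned system
  G3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  Y3 <- matrix(c(2, 3, 5), 1, 3)
  Gd <- G3 - rowMeans(G3)
  Yd <- Y3 - rowMeans(Y3)
  oracle <- solve(Gd %*% t(Gd), Gd %*% t(Yd))
  expect_equal(as.numeric(dr_stage1(Y3, G3)), as.numeric(oracle),
               tolerance = 1e-12)
})

test_that("stage 1 rejects collinear designs, naming the offending pair", {
  m <- matrix(rnorm(30), 1, 30)
  maps <- rbind(m, 2 * m, rnorm(30))
  expect_error(dr_stage1(matrix(rnorm(150), 5, 30), maps),
               "pair \\(1, 2\\)")
  expect_error(dr_stage1(matrix(rnorm(60), 2, 30),
                         rbind(m, numeric(30))), "all-zero")
})

test_that("stage 2 equals per-voxel least squares and its left factor is
           the inverse timeseries covariance", {
  set.seed(2)
  T_ <- 40; V <- 50; k <- 3
  ts <- matrix(rnorm(T_ * k), T_, k)
  Y <- ts %*% matrix(rnorm(k * V), k, V) + matrix(rnorm(T_ * V, sd = 0.3), T_, V)

  maps <- dr_stage2(Y, ts, normalise = TRUE)
  # oracle: independent per-voxel normal-equation solve
  tsd <- scale(ts)
  Yd <- scale(Y, scale = FALSE)
  oracle <- vapply(seq_len(V), function(v) {
    solve(crossprod(tsd), crossprod(tsd, Yd[, v]))[, 1]
  }, numeric(k))
  expect_lt(max(abs(maps - oracle)), 1e-8)

  # with zero-mean unit-variance timeseries, the map-forming operator's
  # left factor is the inverse covariance of the timeseries
  left <- solve(crossprod(tsd))
  expect_equal(maps, (T_ - 1) * left %*% (cov(tsd, Yd)), tolerance = 1e-8)

  # orthonormal columns reproduce the maps exactly
  tso <- qr.Q(qr(scale(matrix(rnorm(T_ * 2), T_, 2), scale = FALSE)))
  tso <- scale(tso, scale = FALSE)
  M <- matrix(rnorm(2 * V), 2, V)
  expect_equal(dr_stage2(tso %*% M, tso, normalise = FALSE), M,
               tolerance = 1e-9)
  expect_error(dr_stage2(Y, cbind(ts, ts[, 1])), "rank-deficient")
})

test_that("stage 4 with unthresholded stage-2 maps spans the stage-1
           subspace", {
  sim <- simulate_overlap(tiny_overlap_cfg())
  g <- group_ica(sim$data, 2, seed = 1)
  Y <- sim$data[[1]]
  ts1 <- dr_stage1(Y, g$group_maps)
  maps2 <- dr_stage2(Y, ts1)
  ts4 <- dr_stage4(Y, maps2)
  cc <- cancor(ts1, ts4)$cor
  expect_true(all(cc > 1 - 1e-8))
})

test_that("stage-3 thresholding keeps |z| >= 2 including the boundary and
           flags all-zero maps", {
  fake_fit <- structure(list(mu = 0, sigma = 1, converged = TRUE,
                             prop = c(0.9, 0.05, 0.05)),
                        class = "ggm_fit")
  maps <- rbind(c(2, 1.999, -2, 0.5, -5), rep(0.1, 5))
  out <- stage3_threshold(maps, list(fake_fit, fake_fit))
  expect_equal(out[1, ], c(2, 0, -2, 0, -5))
  expect_equal(out[2, ], rep(0, 5))
  expect_equal(attr(out, "all_zero"), c(FALSE, TRUE))
  bad <- structure(list(mu = 0, sigma = 0, converged = TRUE),
                   class = "ggm_fit")
  expect_error(stage3_threshold(maps, list(bad, bad)), "zero background")
  warn_fit <- structure(list(mu = 0, sigma = 1, converged = FALSE),
                        class = "ggm_fit")
  expect_warning(stage3_threshold(maps, list(fake_fit, warn_fit)),
                 "did not converge")
})

test_that("thresholding separates a planted sparse signal from a Gaussian
           background", {
  set.seed(31)
  planted <- sample.int(10000, 50)
  map <- rnorm(10000, 0.5, 2)
  map[planted] <- 20
  fit <- fit_ggm(map)
  out <- stage3_threshold(rbind(map), list(fit))
  survivors <- which(out[1, ] != 0)
  # every planted voxel survives (background z at weight 20 is ~9.75)
  expect_true(all(planted %in% survivors))
  # surviving background voxels are limited to the expected two-sided
  # Gaussian tail mass beyond |z| = 2
  false_pos <- length(setdiff(survivors, planted)) / (10000 - 50)
  expect_lt(false_pos, 0.07)
})

test_that("thresholding is near-idempotent on well-separated maps", {
  set.seed(32)
  map <- rnorm(5000)
  map[1:120] <- map[1:120] + 12
  fit1 <- fit_ggm(map)
  thr1 <- stage3_threshold(rbind(map), list(fit1))
  # reapply with a refit on the thresholded output: the surviving set is
  # stable (less than 1% of entries change)
  fit2 <- suppressWarnings(fit_ggm(thr1[1, ]))
  thr2 <- stage3_threshold(thr1, list(fit2))
  changed <- mean((thr2[1, ] != 0) != (thr1[1, ] != 0))
  expect_lt(changed, 0.01)
})

test_that("dual_regression wires the four stages together", {
  sim <- simulate_overlap(tiny_overlap_cfg())
  g <- group_ica(sim$data, 2, seed = 1)
  dr <- suppressWarnings(dual_regression(sim$data[[1]], g$group_maps,
                                         thresholded = TRUE))
  expect_s3_class(dr, "dualreg")
  expect_equal(dim(dr$stage1_timeseries), dim(dr$stage4_timeseries))
  expect_equal(dim(dr$stage2_maps), dim(dr$stage3_maps))
  expect_length(dr$ggm_fits, 2L)
  # stage-3 maps are stage-2 maps with a subset of entries zeroed (after
  # the recorded affine background rescaling)
  z1 <- (dr$stage2_maps[1, ] - dr$ggm_fits[[1]]$mu) / dr$ggm_fits[[1]]$sigma
  expect_equal(dr$stage3_maps[1, ][dr$stage3_maps[1, ] != 0],
               z1[abs(z1) >= 2], tolerance = 1e-12)
  plain <- dual_regression(sim$data[[1]], g$group_maps, thresholded = FALSE)
  expect_null(plain$stage3_maps)
  expect_null(plain$stage4_timeseries)
})
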