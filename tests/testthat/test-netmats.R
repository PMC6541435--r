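# Network matrices, Fisher transform and edge vectorisation.

test_that("temporal netmats match hand-computed and degenerate cases", {
  ts <- cbind(c(1, 2, 3, 4), c(1, 3, 2, 4))
  nm <- temporal_netmat(ts)
  expect_equal(nm[1, 2], 0.8, tolerance = 1e-12)
  dup <- temporal_netmat(cbind(ts, ts[, 1]))
  expect_equal(dup[1, 3], 1)
  set.seed(1)
  long <- temporal_netmat(matrix(rnorm(2 * 10000), ncol = 2))
  expect_lt(abs(long[1, 2]), 0.05)
  expect_error(temporal_netmat(cbind(1:5, rep(2, 5))), "mode\\(s\\) 2")
  expect_error(temporal_netmat(matrix(1:4, 2, 2)), "3 timepoints")
})

test_that("spatial netmats match a direct Pearson oracle for constructed
           supports", {
  v1 <- v2 <- numeric(200)
  v1[1:20] <- 1
  v2[50:69] <- 1
  nm <- spatial_netmat(rbind(v1, v2))
  expect_equal(nm[1, 2], cor(v1, v2), tolerance = 1e-15)
  expect_lt(nm[1, 2], 0) # disjoint supports are slightly anticorrelated
  ident <- spatial_netmat(rbind(v1, v1))
  expect_equal(ident[1, 2], 1)
  expect_error(spatial_netmat(rbind(v1, numeric(200))), "all-zero")
})

test_that("netmats agree with a naive double-loop Pearson to 1e-12", {
  set.seed(2)
  ts <- matrix(rnorm(50 * 6), 50, 6)
  nm <- temporal_netmat(ts)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(nm[i, j], cor(ts[, i], ts[, j]), tolerance = 1e-12)
  }
  maps <- matrix(rnorm(5 * 80), 5, 80)
  sm <- spatial_netmat(maps)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(sm[i, j], cor(maps[i, ], maps[j, ]), tolerance = 1e-12)
  }
})

test_that("fisher_z is the monotone atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-15)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("edge vectorisation is the row-major upper triangle and round
           trips", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- 0
  vals <- c(12, 13, 14, 23, 24, 34)
  k <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    k <- k + 1
    m[i, j] <- m[j, i] <- vals[k]
  }
  diag(m) <- 1
  expect_equal(edge_vector(m), vals)
  # 50 modes give 1225 edges
  big <- diag(50)
  expect_length(edge_vector(big), 1225L)
  # round trip through the index map
  idx <- threshdr:::edge_index(4)
  rebuilt <- diag(4)
  ev <- edge_vector(m)
  for (e in seq_len(nrow(idx))) {
    rebuilt[idx[e, 1], idx[e, 2]] <- rebuilt[idx[e, 2], idx[e, 1]] <- ev[e]
  }
  expect_equal(rebuilt, m)
})
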