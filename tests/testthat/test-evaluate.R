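# Component matching, accuracy metrics, the positive-edge subset and the
# pooled temporal-spatial association.

test_that("matching recovers identity, permutation and sign by
           construction", {
  set.seed(1)
  maps <- matrix(rnorm(4 * 100), 4, 100)
  m_id <- match_components(maps, maps)
  expect_equal(m_id$permutation, 1:4)
  expect_equal(m_id$signs, rep(1, 4))
  expect_equal(m_id$matched_r, rep(1, 4), tolerance = 1e-12)
  expect_false(any(m_id$excluded))

  est <- maps[c(3, 1, 4, 2), ]
  est[2, ] <- -est[2, ]
  m <- match_components(est, maps)
  # truth mode i is estimated mode perm[i]
  expect_equal(m$permutation, c(2L, 4L, 1L, 3L))
  expect_equal(m$signs, c(-1, 1, 1, 1))
  expect_error(match_components(rbind(maps, 0), rbind(maps, rnorm(100))),
               "degenerate")
})

test_that("the inclusion rule excludes modes below the group-average
           correlation threshold", {
  set.seed(2)
  maps <- matrix(rnorm(3 * 200), 3, 200)
  est <- maps
  est[3, ] <- rnorm(200) # unrelated mode
  m <- match_components(est, maps)
  expect_true(m$excluded[3])
  expect_false(any(m$excluded[1:2]))
  expect_equal(m$include_threshold, 0.5)
})

test_that("accuracy metrics are exact on perfect estimates and near zero on
           noise", {
  sim <- simulate_overlap(tiny_overlap_cfg())
  truth <- sim$truth
  match <- match_components(truth$group_maps, truth$group_maps)
  perfect <- lapply(seq_along(sim$data), function(s) {
    list(ts = truth$timecourses[[s]], maps = truth$subject_maps[[s]])
  })
  rep1 <- accuracy_metrics(perfect, truth, match)
  expect_equal(mean(rep1$ts_accuracy), 1, tolerance = 1e-12)
  expect_equal(mean(rep1$map_accuracy), 1, tolerance = 1e-12)
  expect_equal(unname(rep1$tnet_edge_accuracy), 1, tolerance = 1e-12)
  expect_equal(max(abs(rep1$tnet_bias)), 0, tolerance = 1e-12)
  expect_equal(max(abs(rep1$snet_bias)), 0, tolerance = 1e-12)

  set.seed(3)
  noise <- lapply(seq_along(sim$data), function(s) {
    list(ts = matrix(rnorm(length(truth$timecourses[[s]])), ncol = 2),
         maps = matrix(rnorm(length(truth$subject_maps[[s]])), nrow = 2))
  })
  rep0 <- accuracy_metrics(noise, truth, match)
  expect_lt(abs(mean(rep0$ts_accuracy)), 2 / sqrt(length(sim$data) * 60))
  expect_error(accuracy_metrics(perfect[1:2], truth, match), "3 subjects")
})

test_that("metrics are invariant to global rescaling of the estimates", {
  sim <- simulate_overlap(tiny_overlap_cfg())
  truth <- sim$truth
  match <- match_components(truth$group_maps, truth$group_maps)
  base <- lapply(seq_along(sim$data), function(s) {
    list(ts = truth$timecourses[[s]] + rnorm(120, sd = 0.2),
         maps = truth$subject_maps[[s]])
  })
  scaled <- lapply(base, function(r) list(ts = 3.7 * r$ts, maps = 0.2 * r$maps))
  r1 <- accuracy_metrics(base, truth, match)
  r2 <- accuracy_metrics(scaled, truth, match)
  expect_equal(r1$ts_accuracy, r2$ts_accuracy, tolerance = 1e-12)
  expect_equal(r1$map_accuracy, r2$map_accuracy, tolerance = 1e-12)
})

test_that("the positive-edge subset applies the n_edges x n_repeats
           Bonferroni family", {
  k <- 15; n_sub <- 30; n_rep <- 10
  make_truth <- function(edge_mean) {
    snet <- lapply(seq_len(n_sub), function(s) {
      m <- diag(k)
      m[1, 2] <- m[2, 1] <- edge_mean + rnorm(1, sd = 0.01)
      m
    })
    structure(list(snet = snet, tnet = snet), class = "ground_truth")
  }
  set.seed(4)
  truths <- replicate(n_rep, make_truth(0.3), simplify = FALSE)
  subset <- suppressWarnings(positive_edge_subset(truths))
  expect_equal(subset$n_comparisons, k * (k - 1) / 2 * n_rep) # 1050
  # the planted edge is edge 1 in row-major order and always survives:
  # its t statistic ~ 0.3 / (0.01 / sqrt(30)) vastly exceeds the
  # Bonferroni-corrected critical value
  expect_equal(nrow(subset$surviving), n_rep)
  expect_true(all(subset$surviving$edge == 1L))

  # disjoint modes: all true spatial edges at the disjoint-support value,
  # none significantly positive
  zero_truths <- replicate(3, {
    snet <- lapply(1:10, function(s) {
      m <- diag(3)
      m[upper.tri(m)] <- rnorm(3, -0.05, 0.01)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      m
    })
    structure(list(snet = snet), class = "ground_truth")
  }, simplify = FALSE)
  expect_equal(nrow(suppressWarnings(
    positive_edge_subset(zero_truths))$surviving), 0L)
})

test_that("the pooled temporal-spatial association and its outlier filter
           behave as documented", {
  set.seed(5)
  nm <- function(vals) {
    m <- diag(3)
    m[upper.tri(m)] <- vals
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  tnets <- lapply(1:6, function(s) nm(runif(3, -0.5, 0.5)))
  expect_equal(tnet_snet_association(tnets, tnets)$r, 1, tolerance = 1e-12)
  snets <- lapply(1:6, function(s) nm(runif(3, -0.5, 0.5)))
  out <- tnet_snet_association(tnets, snets, exclude_below = -0.2)
  expect_lte(out$n, 18)
  expect_true(all(abs(out$r) <= 1))
  expect_error(tnet_snet_association(tnets[1:2], snets), "same length")
})
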