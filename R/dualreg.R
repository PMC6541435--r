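#' Dual regression stage 1: spatial regression for node timeseries
#'
#' For each timepoint, the voxel vector is regressed on all group maps
#' jointly: maps are demeaned across voxels and the data are demeaned per
#' timepoint across voxels. The result estimates the component timecourses,
#' whose covariance mixes the true temporal covariance with any true spatial
#' covariance suppressed by the spatial-independence constraint of the group
#' decomposition.
#'
#' @param Y timepoints x voxels data matrix.
#' @param maps modes x voxels design maps (group maps for stage 1,
#'   thresholded subject maps for stage 4).
#' @return timepoints x modes coefficient matrix.
#' @seealso [dr_stage2()], [dr_stage4()], [dual_regression()]
#' @export
dr_stage1 <- function(Y, maps) {
  maps <- rbind(maps)
  stopifnot(is.matrix(Y), ncol(Y) == ncol(maps))
  zero <- which(apply(maps, 1L, function(m) all(m == 0)))
  if (length(zero)) {
    stop_config("all-zero map(s) in the design: mode %s",
                paste(zero, collapse = ", "))
  }
  G <- maps - rowMeans(maps)
  gram <- check_design(G, what = "design map")
  Yd <- demean_rows(Y)
  t(solve(gram, G %*% t(Yd)))
}

#' Dual regression stage 2: temporal regression for subject maps
#'
#' Applies the pseudo-inverse of the (demeaned, optionally unit-variance)
#' stage-1 timeseries to the data, i.e. a joint multiple temporal regression
#' per voxel. With unit-variance timeseries the map-forming operator's left
#' factor is the inverse of the timeseries covariance matrix, which is how
#' inflated stage-1 temporal correlations negatively weight the estimated
#' spatial maps.
#'
#' @param Y timepoints x voxels data matrix (demeaned per voxel internally).
#' @param ts timepoints x modes stage-1 timeseries.
#' @param normalise variance-normalise the timeseries before regression
#'   (default `TRUE`; demeaning always happens).
#' @return modes x voxels subject map matrix.
#' @export
dr_stage2 <- function(Y, ts, normalise = TRUE) {
  ts <- cbind(ts)
  stopifnot(is.matrix(Y), nrow(Y) == nrow(ts))
  tsd <- standardise_cols(ts, scale = normalise, label = "timeseries")
  gram <- crossprod(tsd)
  kap <- kappa(gram, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    stop_config("rank-deficient timeseries (condition number %.3g)", kap)
  }
  solve(gram, crossprod(tsd, demean_cols(Y)))
}

#' Dual regression stage 4: spatial regression on thresholded maps
#'
#' Identical contract to [dr_stage1()] with the stage-3 thresholded subject
#' maps as the design; the resulting timeseries are the recommended input
#' for temporal network matrices.
#'
#' @inheritParams dr_stage1
#' @param maps modes x voxels thresholded maps from [stage3_threshold()].
#' @return timepoints x modes timeseries matrix.
#' @export
dr_stage4 <- function(Y, maps) {
  dr_stage1(Y, maps)
}

#' Thresholded dual regression for one subject
#'
#' Runs dual regression stages 1-2 against a set of group maps and, when
#' `thresholded = TRUE`, the two extra stages of thresholded dual
#' regression: Gaussian/Gamma mixture-model thresholding of the stage-2
#' subject maps (stage 3) and a final spatial regression of the data against
#' the thresholded maps (stage 4).
#'
#' @param Y timepoints x voxels data for one subject (concatenate runs along
#'   time beforehand), or a list of run matrices which is row-bound.
#' @param group_maps modes x voxels group map matrix (e.g.
#'   `group_ica()$group_maps`).
#' @param thresholded run stages 3-4 as well (default `TRUE`).
#' @param normalise variance-normalise stage-1 timeseries before stage 2.
#' @param ... passed to [fit_ggm()] (e.g. `max_iter`).
#' @return an object of class `dualreg`: `stage1_timeseries`,
#'   `stage2_maps`, and with `thresholded = TRUE` also `ggm_fits` (one
#'   [fit_ggm()] object per mode), `stage3_maps` and `stage4_timeseries`.
#' @examples
#' sim <- simulate_overlap(overlap_sim_config(
#'   n_voxels = 400, n_subjects = 6, n_timepoints = 80, node_size = 20))
#' g <- group_ica(sim$data, n_modes = 2, seed = 1)
#' dr <- dual_regression(sim$data[[1]], g$group_maps)
#' dr
#' @export
dual_regression <- function(Y, group_maps, thresholded = TRUE,
                            normalise = TRUE, ...) {
  if (is.list(Y)) Y <- do.call(rbind, Y)
  ts1 <- dr_stage1(Y, group_maps)
  maps2 <- dr_stage2(Y, ts1, normalise = normalise)
  out <- list(stage1_timeseries = ts1, stage2_maps = maps2,
              ggm_fits = NULL, stage3_maps = NULL, stage4_timeseries = NULL,
              thresholded = isTRUE(thresholded))
  if (thresholded) {
    fits <- lapply(seq_len(nrow(maps2)),
                   function(j) fit_ggm(maps2[j, ], ...))
    maps3 <- stage3_threshold(maps2, fits)
    out$ggm_fits <- fits
    out$stage3_maps <- maps3
    out$stage4_timeseries <- dr_stage4(Y, maps3)
  }
  structure(out, class = "dualreg")
}

#' @export
print.dualreg <- function(x, ...) {
  k <- ncol(x$stage1_timeseries)
  cat(sprintf("Dual regression result: %d modes, %d timepoints, %d voxels\n",
              k, nrow(x$stage1_timeseries), ncol(x$stage2_maps)))
  if (x$thresholded) {
    surv <- colSums(t(x$stage3_maps) != 0)
    cat(sprintf("  thresholded: %s voxels survive per mode (median %d)\n",
                paste(range(surv), collapse = "-"),
                as.integer(stats::median(surv))))
  } else {
    cat("  stages 1-2 only (thresholded = FALSE)\n")
  }
  invisible(x)
}

#' Fit the full (thresholded) ICA dual-regression pipeline
#'
#' The central estimator: group spatial ICA on the concatenated data,
#' followed by per-subject (thresholded) dual regression, and temporal /
#' spatial network matrices per subject. Temporal netmats come from stage-4
#' timeseries when `thresholded = TRUE` (recommended for node-based
#' analyses) and stage-1 otherwise; spatial netmats come from stage-3
#' thresholded maps when thresholding is on and stage-2 maps otherwise.
#' Stage-1/stage-2 netmats are always retained for comparison.
#'
#' @param data list of per-subject timepoints x voxels matrices, or a nested
#'   list (subjects of runs; runs are concatenated along time within
#'   subject but enter the group ICA separately).
#' @param n_modes decomposition dimensionality.
#' @param thresholded run mixture-model thresholding and stage 4.
#' @param seed seed for the ICA restarts.
#' @param normalise variance-normalise stage-1 timeseries before stage 2.
#' @param ... passed to [group_ica()].
#' @return an object of class `ica_dr`: `ica` (the [group_ica()] fit),
#'   `subjects` (list of [dual_regression()] results), `tnet`/`snet` (lists
#'   of the recommended temporal and spatial netmats per subject),
#'   `tnet_stage1`/`snet_stage2` (the plain-pipeline netmats), and the call
#'   parameters.
#' @export
ica_dr <- function(data, n_modes, thresholded = TRUE, seed = 1L,
                   normalise = TRUE, ...) {
  nested <- is.list(data) && any(vapply(data, is.list, logical(1)))
  fit <- group_ica(data, n_modes = n_modes, seed = seed, ...)
  subj_data <- if (nested) lapply(data, function(r) do.call(rbind, r)) else data
  subjects <- lapply(subj_data, dual_regression, group_maps = fit$group_maps,
                     thresholded = thresholded, normalise = normalise)
  tnet1 <- lapply(seq_along(subjects), function(s) {
    temporal_netmat(subjects[[s]]$stage1_timeseries, subject = s,
                    stage = "stage1")
  })
  snet2 <- lapply(seq_along(subjects), function(s) {
    spatial_netmat(subjects[[s]]$stage2_maps, subject = s, stage = "stage2")
  })
  if (thresholded) {
    tnet <- lapply(seq_along(subjects), function(s) {
      temporal_netmat(subjects[[s]]$stage4_timeseries, subject = s,
                      stage = "stage4")
    })
    snet <- lapply(seq_along(subjects), function(s) {
      spatial_netmat(subjects[[s]]$stage3_maps, subject = s, stage = "stage3")
    })
  } else {
    tnet <- tnet1
    snet <- snet2
  }
  structure(list(ica = fit, subjects = subjects,
                 tnet = tnet, snet = snet,
                 tnet_stage1 = tnet1, snet_stage2 = snet2,
                 n_modes = as.integer(n_modes),
                 thresholded = isTRUE(thresholded), seed = seed),
            class = "ica_dr")
}

#' @export
print.ica_dr <- function(x, ...) {
  cat(sprintf("ICA dual regression fit (%s pipeline)\n",
              if (x$thresholded) "thresholded, 4-stage" else "plain, 2-stage"))
  cat(sprintf("  %d subjects, %d modes x %d voxels\n",
              length(x$subjects), x$n_modes, ncol(x$ica$group_maps)))
  cat(sprintf("  mean temporal edge %.3f, mean spatial edge %.3f\n",
              mean(vapply(x$tnet, function(m) mean(edge_vector(m)), numeric(1))),
              mean(vapply(x$snet, function(m) mean(edge_vector(m)), numeric(1)))))
  invisible(x)
}

#' @export
summary.ica_dr <- function(object, ...) {
  edges_t <- vapply(object$tnet, function(m) mean(edge_vector(m)), numeric(1))
  edges_s <- vapply(object$snet, function(m) mean(edge_vector(m)), numeric(1))
  edges_t1 <- vapply(object$tnet_stage1, function(m) mean(edge_vector(m)), numeric(1))
  edges_s2 <- vapply(object$snet_stage2, function(m) mean(edge_vector(m)), numeric(1))
  out <- list(
    n_subjects = length(object$subjects),
    n_modes = object$n_modes,
    thresholded = object$thresholded,
    mean_temporal_edge = mean(edges_t),
    mean_spatial_edge = mean(edges_s),
    mean_temporal_edge_stage1 = mean(edges_t1),
    mean_spatial_edge_stage2 = mean(edges_s2),
    tnet_snet_r = tnet_snet_association(object$tnet_stage1, object$snet_stage2)$r
  )
  class(out) <- "summary.ica_dr"
  out
}

#' @export
print.summary.ica_dr <- function(x, ...) {
  cat(sprintf("ICA-DR summary: %d subjects, %d modes (%s)\n", x$n_subjects,
              x$n_modes, if (x$thresholded) "thresholded" else "plain"))
  cat(sprintf("  mean temporal edge: %.4f (stage 1: %.4f)\n",
              x$mean_temporal_edge, x$mean_temporal_edge_stage1))
  cat(sprintf("  mean spatial edge:  %.4f (stage 2: %.4f)\n",
              x$mean_spatial_edge, x$mean_spatial_edge_stage2))
  cat(sprintf("  pooled stage1-Tnet vs stage2-Snet correlation: %.4f\n",
              x$tnet_snet_r))
  invisible(x)
}

#' @export
coef.ica_dr <- function(object, ...) object$ica$group_maps

#' @export
plot.ica_dr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  mt <- Reduce(`+`, lapply(x$tnet, unclass)) / length(x$tnet)
  ms <- Reduce(`+`, lapply(x$snet, unclass)) / length(x$snet)
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(mt, zlim = c(-1, 1), col = pal, axes = FALSE,
                  main = "mean temporal netmat")
  graphics::image(ms, zlim = c(-1, 1), col = pal, axes = FALSE,
                  main = "mean spatial netmat")
  invisible(x)
}
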