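# End-to-end simulation studies: the overlap-bias demonstration on the
# two-node simulator and the thresholding benchmark on the parcel-based
# simulator.

# Scale-free underestimation diagnostic: ratio of estimated to true group-map
# weight, averaged over overlap voxels vs non-overlap node voxels.
overlap_weight_ratios <- function(est_group_maps, truth, match) {
  ov <- truth$overlap
  ratios <- vapply(seq_along(match$permutation), function(j) {
    g <- match$signs[j] * est_group_maps[match$permutation[j], ]
    tr <- truth$group_maps[j, ]
    non <- setdiff(truth$supports[[j]], ov)
    c(overlap = mean(g[ov]) / mean(tr[ov]),
      non_overlap = mean(g[non]) / mean(tr[non]))
  }, numeric(2))
  rowMeans(ratios)
}

slim_truth <- function(truth) {
  structure(list(tnet = truth$tnet, tnet_bold = truth$tnet_bold,
                 snet = truth$snet, seed = truth$seed),
            class = "ground_truth")
}

#' Overlap-bias study on the two-node simulator
#'
#' Runs the full pipeline — simulation, group spatial ICA, (thresholded)
#' dual regression, netmats, evaluation — across repeats and summarises the
#' systematic biases that spatial overlap induces: inflated stage-1 temporal
#' edges, negatively biased stage-2 spatial edges, a negative pooled
#' association between the two, and underestimated group-map weights in the
#' overlap region, together with the stage-3/4 corrections when
#' `thresholded = TRUE`.
#'
#' @param config an [overlap_sim_config()].
#' @param n_repeats number of independent repeats (default
#'   `config$n_repeats`).
#' @param thresholded also run stages 3-4.
#' @param verbose print per-repeat progress.
#' @return an object of class `overlap_bias_study`: `summary` (one row per
#'   repeat), `truths` (slim ground-truth records), `reports_plain` /
#'   `reports_thresholded` (per-repeat [accuracy_metrics()] reports),
#'   `matches`, and the config.
#' @export
overlap_bias_study <- function(config, n_repeats = config$n_repeats,
                               thresholded = TRUE, verbose = FALSE) {
  stopifnot(inherits(config, "overlap_sim_config"))
  rows <- vector("list", n_repeats)
  truths <- vector("list", n_repeats)
  reports_plain <- vector("list", n_repeats)
  reports_thresh <- vector("list", n_repeats)
  matches <- vector("list", n_repeats)

  for (r in seq_len(n_repeats)) {
    if (verbose) message(sprintf("repeat %d/%d", r, n_repeats))
    sim <- simulate_overlap(config, r)
    fit <- ica_dr(sim$data, n_modes = 2L, thresholded = thresholded,
                  seed = sim$truth$seed)
    match <- match_components(
      fit$ica$group_maps, sim$truth$group_maps,
      est_subject_maps = lapply(fit$subjects, `[[`, "stage2_maps"),
      true_subject_maps = sim$truth$subject_maps)
    res_plain <- lapply(fit$subjects, function(d) {
      list(ts = d$stage1_timeseries, maps = d$stage2_maps)
    })
    rep_plain <- accuracy_metrics(res_plain, sim$truth, match)
    rep_thresh <- NULL
    if (thresholded) {
      res_thr <- lapply(fit$subjects, function(d) {
        list(ts = d$stage4_timeseries, maps = d$stage3_maps)
      })
      rep_thresh <- accuracy_metrics(res_thr, sim$truth, match)
    }
    ratios <- overlap_weight_ratios(fit$ica$group_maps, sim$truth, match)
    assoc <- tnet_snet_association(fit$tnet_stage1, fit$snet_stage2)

    rows[[r]] <- data.frame(
      repeat_index = r,
      true_temporal_edge = mean(rep_plain$true_tnet_edges),
      stage1_temporal_edge = mean(rep_plain$est_tnet_edges),
      stage4_temporal_edge = if (thresholded) mean(rep_thresh$est_tnet_edges) else NA_real_,
      true_spatial_edge = mean(rep_plain$true_snet_edges),
      stage2_spatial_edge = mean(rep_plain$est_snet_edges),
      stage3_spatial_edge = if (thresholded) mean(rep_thresh$est_snet_edges) else NA_real_,
      tnet_snet_r = assoc$r,
      weight_ratio_overlap = ratios["overlap"],
      weight_ratio_non_overlap = ratios["non_overlap"],
      ts_accuracy = mean(rep_plain$ts_accuracy),
      map_accuracy = mean(rep_plain$map_accuracy)
    )
    truths[[r]] <- slim_truth(sim$truth)
    reports_plain[[r]] <- rep_plain
    reports_thresh[[r]] <- rep_thresh
    matches[[r]] <- match
    rm(sim, fit)
    gc(FALSE)
  }
  structure(list(summary = do.call(rbind, rows), truths = truths,
                 reports_plain = reports_plain,
                 reports_thresholded = if (thresholded) reports_thresh,
                 matches = matches, config = config,
                 thresholded = thresholded),
            class = "overlap_bias_study")
}

#' @export
print.overlap_bias_study <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Overlap-bias study: %d repeats of the two-node simulator\n",
              nrow(s)))
  cat(sprintf("  temporal edge: truth %.3f | stage 1 %.3f%s\n",
              mean(s$true_temporal_edge), mean(s$stage1_temporal_edge),
              if (x$thresholded) sprintf(" | stage 4 %.3f",
                                         mean(s$stage4_temporal_edge)) else ""))
  cat(sprintf("  spatial edge:  truth %.3f | stage 2 %.3f%s\n",
              mean(s$true_spatial_edge), mean(s$stage2_spatial_edge),
              if (x$thresholded) sprintf(" | stage 3 %.3f",
                                         mean(s$stage3_spatial_edge)) else ""))
  cat(sprintf("  pooled Tnet-Snet correlation: %.3f (negative in %d/%d repeats)\n",
              mean(s$tnet_snet_r), sum(s$tnet_snet_r < 0), nrow(s)))
  cat(sprintf("  group-map weight ratio est/truth: overlap %.3f vs non-overlap %.3f\n",
              mean(s$weight_ratio_overlap), mean(s$weight_ratio_non_overlap)))
  invisible(x)
}

#' Thresholding benchmark on the parcel-based simulator
#'
#' Runs plain and thresholded ICA dual regression on repeats of the
#' parcel-based simulation and compares their accuracy: metrics (i)-(iv)
#' from [accuracy_metrics()], edge biases, and the positive-spatial-edge
#' subset analysis with Bonferroni correction over
#' `n_edges x n_repeats` comparisons.
#'
#' @param config a [modes_sim_config()]; for large studies set
#'   `record_noise = FALSE`.
#' @param n_repeats number of repeats (default `config$n_repeats`).
#' @param verbose print per-repeat progress.
#' @return an object of class `modes_benchmark`: `summary` (one row per
#'   repeat with the aggregated metrics for both pipelines), per-repeat
#'   reports, `subset` (the [positive_edge_subset()] analysis including
#'   mean-|bias| summaries per pipeline), `matches`, and the config.
#' @export
modes_benchmark_study <- function(config, n_repeats = config$n_repeats,
                                  verbose = FALSE) {
  stopifnot(inherits(config, "modes_sim_config"))
  rows <- vector("list", n_repeats)
  truths <- vector("list", n_repeats)
  reports_plain <- vector("list", n_repeats)
  reports_thresh <- vector("list", n_repeats)
  matches <- vector("list", n_repeats)

  for (r in seq_len(n_repeats)) {
    if (verbose) message(sprintf("repeat %d/%d", r, n_repeats))
    sim <- simulate_modes(config, r)
    fit <- ica_dr(sim$data, n_modes = config$n_modes, thresholded = TRUE,
                  seed = sim$truth$seed)
    match <- match_components(
      fit$ica$group_maps, sim$truth$group_maps,
      est_subject_maps = lapply(fit$subjects, `[[`, "stage2_maps"),
      true_subject_maps = sim$truth$subject_maps)
    res_plain <- lapply(fit$subjects, function(d) {
      list(ts = d$stage1_timeseries, maps = d$stage2_maps)
    })
    res_thr <- lapply(fit$subjects, function(d) {
      list(ts = d$stage4_timeseries, maps = d$stage3_maps)
    })
    rep_plain <- accuracy_metrics(res_plain, sim$truth, match)
    rep_thresh <- accuracy_metrics(res_thr, sim$truth, match)
    assoc <- tnet_snet_association(fit$tnet_stage1, fit$snet_stage2)

    inc <- rep_plain$included_edges
    rows[[r]] <- data.frame(
      repeat_index = r,
      n_modes_included = sum(!match$excluded),
      ts_accuracy_plain = mean(rep_plain$ts_accuracy),
      ts_accuracy_thresholded = mean(rep_thresh$ts_accuracy),
      map_accuracy_plain = mean(rep_plain$map_accuracy),
      map_accuracy_thresholded = mean(rep_thresh$map_accuracy),
      tnet_edge_accuracy_plain = mean(rep_plain$tnet_edge_accuracy[inc], na.rm = TRUE),
      tnet_edge_accuracy_thresholded = mean(rep_thresh$tnet_edge_accuracy[inc], na.rm = TRUE),
      snet_edge_accuracy_plain = mean(rep_plain$snet_edge_accuracy[inc], na.rm = TRUE),
      snet_edge_accuracy_thresholded = mean(rep_thresh$snet_edge_accuracy[inc], na.rm = TRUE),
      tnet_bias_plain = mean(rep_plain$tnet_bias[inc, ]),
      tnet_bias_thresholded = mean(rep_thresh$tnet_bias[inc, ]),
      snet_bias_plain = mean(rep_plain$snet_bias[inc, ]),
      snet_bias_thresholded = mean(rep_thresh$snet_bias[inc, ]),
      tnet_snet_r = assoc$r
    )
    truths[[r]] <- slim_truth(sim$truth)
    reports_plain[[r]] <- rep_plain
    reports_thresh[[r]] <- rep_thresh
    matches[[r]] <- match
    rm(sim, fit)
    gc(FALSE)
  }

  # edges incident to excluded (poorly matched) modes leave the subset
  # analysis along with the edge-level metrics
  masked_bias <- function(reports) {
    lapply(reports, function(rep) {
      b <- rep$tnet_bias
      b[!rep$included_edges, ] <- NA_real_
      b
    })
  }
  subset <- if (n_repeats >= 2L) {
    positive_edge_subset(truths, biases = list(
      plain = masked_bias(reports_plain),
      thresholded = masked_bias(reports_thresh)))
  }
  structure(list(summary = do.call(rbind, rows), truths = truths,
                 reports_plain = reports_plain,
                 reports_thresholded = reports_thresh,
                 matches = matches, subset = subset, config = config),
            class = "modes_benchmark")
}

#' @export
print.modes_benchmark <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Thresholding benchmark: %d repeats of the parcel-based simulator\n",
              nrow(s)))
  cat(sprintf("  (i)   timeseries accuracy:   plain %.3f | thresholded %.3f\n",
              mean(s$ts_accuracy_plain), mean(s$ts_accuracy_thresholded)))
  cat(sprintf("  (ii)  map accuracy:          plain %.3f | thresholded %.3f\n",
              mean(s$map_accuracy_plain), mean(s$map_accuracy_thresholded)))
  cat(sprintf("  (iii) temporal edge accuracy: plain %.3f | thresholded %.3f\n",
              mean(s$tnet_edge_accuracy_plain),
              mean(s$tnet_edge_accuracy_thresholded)))
  cat(sprintf("  (iv)  spatial edge accuracy:  plain %.3f | thresholded %.3f\n",
              mean(s$snet_edge_accuracy_plain),
              mean(s$snet_edge_accuracy_thresholded)))
  if (!is.null(x$subset) && !is.null(x$subset$bias_summary)) {
    b <- x$subset$bias_summary
    cat(sprintf("  positive-edge subset |bias|: plain %.4f | thresholded %.4f (%d cells)\n",
                b$plain["mean_abs_bias"], b$thresholded["mean_abs_bias"],
                nrow(x$subset$surviving)))
  }
  invisible(x)
}
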