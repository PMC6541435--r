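# Matching estimated components to ground truth and accuracy metrics.

#' Match estimated components to ground-truth modes
#'
#' Resolves the sign and permutation indeterminacy of ICA by an optimal
#' assignment (Hungarian algorithm) maximising the total absolute spatial
#' correlation between estimated and true maps. The per-mode sign is the
#' sign of the matched correlation. Modes whose group-average matched
#' correlation falls below `include_threshold` are flagged excluded and
#' their incident edges are dropped from edge-level accuracy metrics.
#'
#' @param est_maps modes x voxels estimated (group) maps.
#' @param true_maps modes x voxels ground-truth (group) maps.
#' @param est_subject_maps,true_subject_maps optional lists of per-subject
#'   maps; when supplied, the group-average matched correlation is the mean
#'   across subjects of the matched subject-map correlations, otherwise the
#'   group-map matched correlation is used.
#' @param include_threshold minimum group-average matched correlation for a
#'   mode to be included (default 0.5).
#' @return an object of class `match_result`: `permutation` (estimated mode
#'   index for each truth mode), `signs`, `matched_r`, `group_avg_r`,
#'   `excluded` (logical per truth mode).
#' @export
match_components <- function(est_maps, true_maps,
                             est_subject_maps = NULL,
                             true_subject_maps = NULL,
                             include_threshold = 0.5) {
  est_maps <- rbind(est_maps)
  true_maps <- rbind(true_maps)
  stopifnot(nrow(est_maps) == nrow(true_maps),
            ncol(est_maps) == ncol(true_maps))
  for (m in list(est_maps, true_maps)) {
    if (any(apply(m, 1L, stats::sd) < .Machine$double.eps^0.5)) {
      stop_config("degenerate all-zero or constant map in input")
    }
  }
  C <- stats::cor(t(true_maps), t(est_maps))
  perm <- as.integer(clue::solve_LSAP(abs(C), maximum = TRUE))
  matched_r <- C[cbind(seq_along(perm), perm)]
  signs <- ifelse(matched_r < 0, -1, 1)

  group_avg <- abs(matched_r)
  if (!is.null(est_subject_maps) && !is.null(true_subject_maps)) {
    stopifnot(length(est_subject_maps) == length(true_subject_maps))
    per_subj <- vapply(seq_along(est_subject_maps), function(s) {
      vapply(seq_along(perm), function(i) {
        stats::cor(signs[i] * est_subject_maps[[s]][perm[i], ],
                   true_subject_maps[[s]][i, ])
      }, numeric(1))
    }, numeric(length(perm)))
    group_avg <- rowMeans(rbind(per_subj))
  }
  structure(list(permutation = perm, signs = signs, matched_r = matched_r,
                 group_avg_r = group_avg,
                 excluded = group_avg < include_threshold,
                 include_threshold = include_threshold),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("Component matching: %d modes, %d excluded (group-average r < %.2f)\n",
              length(x$permutation), sum(x$excluded), x$include_threshold))
  cat(sprintf("  matched |r|: %s\n",
              paste(sprintf("%.2f", abs(x$matched_r)), collapse = " ")))
  invisible(x)
}

# Pick the truth timecourses estimated timeseries should be compared to:
# post-HRF BOLD timecourses where the simulator has an HRF stage, otherwise
# the raw node timecourses; runs are concatenated along time.
truth_timecourses <- function(truth) {
  src <- truth$bold_tc %||% truth$timecourses
  lapply(src, function(ts) if (is.list(ts)) do.call(rbind, ts) else ts)
}

#' Accuracy metrics against ground truth
#'
#' Computes the four accuracy metrics for a set of per-subject estimates:
#' (i) per subject/mode correlation between estimated and true timeseries,
#' (ii) per subject/mode correlation between estimated and true maps,
#' (iii) per-edge cross-subject correlation between estimated and true
#' temporal edges, and (iv) the same for spatial edges, plus the bias
#' (estimated minus truth) distributions for temporal and spatial edges.
#' Edge-level metrics use Fisher-z edges by default and drop edges incident
#' to excluded (poorly matched) modes.
#'
#' @param results list with one element per subject, each a list with `ts`
#'   (timepoints x modes estimated timeseries) and `maps` (modes x voxels
#'   estimated maps), in estimated-mode order.
#' @param truth a `ground_truth` bundle from [simulate_overlap()] or
#'   [simulate_modes()].
#' @param match a [match_components()] result aligning estimated to true
#'   modes.
#' @param use_fisher compute (iii)/(iv) on Fisher-z transformed edges.
#' @return an object of class `eval_report`: `ts_accuracy` and
#'   `map_accuracy` (subjects x modes), `tnet_edge_accuracy` and
#'   `snet_edge_accuracy` (per edge, `NA` for excluded edges),
#'   `tnet_bias`/`snet_bias` (edges x subjects, raw correlation units),
#'   `edge_index`, `included_edges`, and `excluded_modes`.
#' @export
accuracy_metrics <- function(results, truth, match, use_fisher = TRUE) {
  S <- length(results)
  if (S < 3L) stop_config("need at least 3 subjects for edge-level metrics, got %d", S)
  k <- length(match$permutation)
  perm <- match$permutation
  signs <- match$signs
  true_ts <- truth_timecourses(truth)
  # temporal-edge truth at the BOLD level where the simulator has an HRF
  # stage (matching what the estimated timeseries can at best recover);
  # the pre-HRF neural netmat stays available as truth$tnet
  true_tnet <- truth$tnet_bold %||% truth$tnet

  ts_acc <- matrix(NA_real_, S, k)
  map_acc <- matrix(NA_real_, S, k)
  n_edges <- k * (k - 1L) / 2L
  est_t_edges <- matrix(NA_real_, n_edges, S)
  est_s_edges <- matrix(NA_real_, n_edges, S)
  true_t_edges <- matrix(NA_real_, n_edges, S)
  true_s_edges <- matrix(NA_real_, n_edges, S)

  for (s in seq_len(S)) {
    ts_al <- sweep(results[[s]]$ts[, perm, drop = FALSE], 2L, signs, "*")
    maps_al <- sweep(results[[s]]$maps[perm, , drop = FALSE], 1L, signs, "*")
    for (i in seq_len(k)) {
      ts_acc[s, i] <- stats::cor(ts_al[, i], true_ts[[s]][, i])
      map_acc[s, i] <- stats::cor(maps_al[i, ], truth$subject_maps[[s]][i, ])
    }
    est_t_edges[, s] <- edge_vector(stats::cor(ts_al))
    est_s_edges[, s] <- edge_vector(stats::cor(t(maps_al)))
    true_t_edges[, s] <- edge_vector(true_tnet[[s]])
    true_s_edges[, s] <- edge_vector(truth$snet[[s]])
  }

  idx <- edge_index(k)
  included <- !(match$excluded[idx[, 1L]] | match$excluded[idx[, 2L]])
  edge_acc <- function(est, true) {
    vapply(seq_len(n_edges), function(e) {
      if (!included[e]) return(NA_real_)
      a <- est[e, ]
      b <- true[e, ]
      if (use_fisher) {
        a <- fisher_z(pmin(pmax(a, -1 + 1e-12), 1 - 1e-12))
        b <- fisher_z(pmin(pmax(b, -1 + 1e-12), 1 - 1e-12))
      }
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
  }

  structure(list(
    ts_accuracy = ts_acc, map_accuracy = map_acc,
    tnet_edge_accuracy = edge_acc(est_t_edges, true_t_edges),
    snet_edge_accuracy = edge_acc(est_s_edges, true_s_edges),
    tnet_bias = est_t_edges - true_t_edges,
    snet_bias = est_s_edges - true_s_edges,
    est_tnet_edges = est_t_edges, est_snet_edges = est_s_edges,
    true_tnet_edges = true_t_edges, true_snet_edges = true_s_edges,
    edge_index = idx, included_edges = included,
    excluded_modes = which(match$excluded), use_fisher = use_fisher
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  inc <- x$included_edges
  cat("Accuracy report\n")
  cat(sprintf("  (i)   timeseries accuracy: mean r = %.3f\n",
              mean(x$ts_accuracy)))
  cat(sprintf("  (ii)  map accuracy:        mean r = %.3f\n",
              mean(x$map_accuracy)))
  cat(sprintf("  (iii) temporal edge accuracy: mean r = %.3f over %d edges\n",
              mean(x$tnet_edge_accuracy[inc], na.rm = TRUE), sum(inc)))
  cat(sprintf("  (iv)  spatial edge accuracy:  mean r = %.3f over %d edges\n",
              mean(x$snet_edge_accuracy[inc], na.rm = TRUE), sum(inc)))
  cat(sprintf("  mean temporal edge bias %.4f; mean spatial edge bias %.4f\n",
              mean(x$tnet_bias[inc, ]), mean(x$snet_bias[inc, ])))
  if (length(x$excluded_modes)) {
    cat(sprintf("  excluded modes: %s\n",
                paste(x$excluded_modes, collapse = ", ")))
  }
  invisible(x)
}

#' Edges with significantly positive ground-truth spatial correlation
#'
#' For every repeat and edge, a one-tailed t-test of the true spatial edge
#' values across subjects against zero; the family-wise Bonferroni
#' correction spans `n_edges * n_repeats` comparisons. Used to isolate the
#' subset of edges where absolute bias in estimated temporal edges can be
#' assessed against a genuinely positive spatial overlap.
#'
#' @param truths list of `ground_truth` bundles, one per repeat (>= 2
#'   repeats, >= 3 subjects).
#' @param biases optional named list of methods, each a list (per repeat) of
#'   edges x subjects bias matrices (estimated minus truth); summaries are
#'   restricted to the surviving (repeat, edge) cells.
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return an object of class `positive_edge_subset`: `table` (one row per
#'   repeat x edge with the t statistic, p-value and survival flag),
#'   `n_comparisons`, `surviving` (repeat/edge pairs), and `bias_summary`
#'   (per method: mean bias and mean absolute bias on the subset).
#' @export
positive_edge_subset <- function(truths, biases = NULL, alpha = 0.05) {
  stopifnot(is.list(truths), length(truths) >= 2L)
  S <- length(truths[[1]]$snet)
  if (S < 3L) stop_config("need at least 3 subjects")
  k <- nrow(truths[[1]]$snet[[1]])
  n_edges <- k * (k - 1L) / 2L
  n_repeats <- length(truths)
  n_comp <- n_edges * n_repeats

  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    edges <- vapply(truths[[r]]$snet, edge_vector, numeric(n_edges))
    edges <- rbind(edges)  # n_edges x S
    stat <- p <- rep(NA_real_, n_edges)
    for (e in seq_len(n_edges)) {
      x <- edges[e, ]
      if (stats::sd(x) == 0) {
        warning(sprintf("repeat %d edge %d has zero variance; excluded", r, e),
                call. = FALSE)
        next
      }
      tt <- stats::t.test(x, alternative = "greater", mu = 0)
      stat[e] <- unname(tt$statistic)
      p[e] <- tt$p.value
    }
    rows[[r]] <- data.frame(repeat_index = r, edge = seq_len(n_edges),
                            t = stat, p = p,
                            significant = !is.na(p) & p * n_comp < alpha)
  }
  tab <- do.call(rbind, rows)

  bias_summary <- NULL
  if (!is.null(biases)) {
    bias_summary <- lapply(biases, function(method) {
      vals <- unlist(lapply(seq_len(n_repeats), function(r) {
        keep <- tab$significant[tab$repeat_index == r]
        as.vector(method[[r]][keep, , drop = FALSE])
      }))
      vals <- vals[is.finite(vals)]  # excluded-mode edges arrive as NA
      c(mean_bias = mean(vals), mean_abs_bias = mean(abs(vals)),
        n = length(vals))
    })
  }

  structure(list(table = tab, n_comparisons = n_comp,
                 surviving = tab[tab$significant,
                                 c("repeat_index", "edge"), drop = FALSE],
                 bias_summary = bias_summary, alpha = alpha),
            class = "positive_edge_subset")
}

#' @export
print.positive_edge_subset <- function(x, ...) {
  cat(sprintf("Positive-spatial-edge subset: %d of %d (repeat, edge) cells survive Bonferroni (alpha %.2f / %d)\n",
              nrow(x$surviving), x$n_comparisons, x$alpha, x$n_comparisons))
  if (!is.null(x$bias_summary)) {
    for (m in names(x$bias_summary)) {
      s <- x$bias_summary[[m]]
      cat(sprintf("  %s: mean bias %+.4f, mean |bias| %.4f (n = %d)\n",
                  m, s["mean_bias"], s["mean_abs_bias"], s["n"]))
    }
  }
  invisible(x)
}

#' Pooled association between temporal and spatial edges
#'
#' Pearson correlation over all (edge, subject) pairs between temporal and
#' spatial edge values. Under group spatial ICA followed by dual regression
#' this association is negative when true spatial overlap exists, because
#' suppressed spatial correlation is re-expressed in the stage-1 temporal
#' edges and inversely weighted into the stage-2 maps.
#'
#' @param tnets,snets lists of temporal and spatial netmats over subjects
#'   (matching lengths and mode counts).
#' @param exclude_below optional spatial-edge floor: pairs with spatial edge
#'   below this value are removed before pooling (outlier rule; e.g.
#'   `-0.2`).
#' @return list with `r` (pooled correlation), `n` (pairs used) and
#'   `exclude_below`.
#' @export
tnet_snet_association <- function(tnets, snets, exclude_below = NULL) {
  if (length(tnets) != length(snets)) {
    stop_config("tnets and snets must have the same length (got %d and %d)",
                length(tnets), length(snets))
  }
  t_edges <- unlist(lapply(tnets, edge_vector))
  s_edges <- unlist(lapply(snets, edge_vector))
  if (length(t_edges) != length(s_edges)) {
    stop_config("temporal and spatial netmats have mismatched mode counts")
  }
  keep <- rep(TRUE, length(t_edges))
  if (!is.null(exclude_below)) keep <- s_edges >= exclude_below
  list(r = stats::cor(t_edges[keep], s_edges[keep]), n = sum(keep),
       exclude_below = exclude_below)
}
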