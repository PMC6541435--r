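#' Group spatial ICA via temporal concatenation
#'
#' Temporally demeans each subject (per voxel), concatenates subjects along
#' time, reduces the concatenated data to `n_modes` principal components, and
#' unmixes so that the estimated spatial maps are maximally independent
#' across voxels (FastICA, logcosh contrast). Because of the spatial
#' independence constraint, the sample correlations between the estimated
#' group maps are suppressed towards zero by construction, whatever the true
#' spatial overlap between the underlying modes.
#'
#' Dimension reduction uses the standard two-level scheme for temporal
#' concatenation: each subject is first reduced by SVD to `subject_dim`
#' spatial basis rows (scaled right-singular vectors, which preserve the
#' subject's voxel covariance), the reduced rows are stacked, and the group
#' PCA/whitening is computed from the stack. With `subject_dim` well above
#' the effective data rank this is numerically equivalent to PCA of the full
#' concatenated matrix while avoiding its cost.
#'
#' @param data list of timepoints x voxels matrices (one per subject/run),
#'   or a nested list (subjects of runs) which is flattened.
#' @param n_modes number of components; the PCA dimension equals it.
#' @param seed integer seed controlling the ICA restarts.
#' @param subject_dim per-subject reduction dimension; default
#'   `min(T - 1, max(2 * n_modes + 2, 20))`.
#' @param restarts number of FastICA restarts from random rotations; the run
#'   with the best (largest) logcosh contrast is kept.
#' @param maxit,tol FastICA iteration cap and convergence tolerance.
#' @param var_norm if `TRUE`, voxel timeseries are variance-normalised before
#'   concatenation (off by default).
#' @return an object of class `group_ica`: `group_maps` (n_modes x voxels,
#'   rows demeaned across voxels, unit variance, heavier tail positive,
#'   ordered by explained variance), `mixing` (the estimated mixing of
#'   whitened group PCs into components), `whitening` (voxel-space whitening
#'   of the reduced stack), `pca_dim`, `explained_variance`, and
#'   `diagnostics` (per-restart contrast values, iterations, convergence).
#' @examples
#' sim <- simulate_overlap(overlap_sim_config(
#'   n_voxels = 400, n_subjects = 6, n_timepoints = 80, node_size = 20))
#' g <- group_ica(sim$data, n_modes = 2, seed = 1)
#' round(cor(t(g$group_maps)), 3) # off-diagonal ~ 0 by construction
#' @export
group_ica <- function(data, n_modes, seed = 1L, subject_dim = NULL,
                      restarts = 10L, maxit = 500L, tol = 1e-6,
                      var_norm = FALSE) {
  if (is.list(data) && any(vapply(data, is.list, logical(1)))) {
    data <- unlist(data, recursive = FALSE)
  }
  stopifnot(is.list(data), length(data) >= 1L, is_count(n_modes))
  V <- ncol(data[[1]])
  if (!all(vapply(data, ncol, integer(1)) == V)) {
    stop_config("all subjects must share the same voxel count")
  }
  total_t <- sum(vapply(data, nrow, integer(1)))
  if (total_t < n_modes) {
    stop_config("total timepoints (%d) must be at least n_modes (%d)",
                total_t, n_modes)
  }

  # per-subject demean (and optional variance normalisation), then SVD
  # reduction to a compact spatial basis
  reduced <- lapply(data, function(Y) {
    Y <- demean_cols(Y)
    if (var_norm) {
      s <- sqrt(colMeans(Y^2))
      s[s < .Machine$double.eps^0.5] <- 1
      Y <- sweep(Y, 2L, s, "/")
    }
    d <- min(nrow(Y) - 1L, subject_dim %||% max(2L * n_modes + 2L, 20L))
    cp <- tcrossprod(Y)
    eg <- eigen(cp, symmetric = TRUE)
    keep <- seq_len(min(d, sum(eg$values > max(eg$values) * 1e-12)))
    # rows are sqrt(eigenvalue)-scaled right-singular vectors: D V'
    crossprod(eg$vectors[, keep, drop = FALSE], Y)
  })
  R <- do.call(rbind, reduced)

  # group PCA of the stacked reduced data; eigen of R R' keeps cost at
  # (stack rows)^2 x voxels
  gr <- tcrossprod(R)
  eg <- eigen(gr, symmetric = TRUE)
  pos <- sum(eg$values > max(eg$values) * 1e-10)
  if (pos < n_modes) {
    stop_config("rank-deficient data: only %d non-degenerate dimensions for %d modes",
                pos, n_modes)
  }
  idx <- seq_len(n_modes)
  evals <- eg$values[idx]
  # whitened spatial PCs: n_modes x voxels with identity covariance across voxels
  white <- diag(1 / sqrt(evals), n_modes) %*%
    crossprod(eg$vectors[, idx, drop = FALSE], R)
  white <- white * sqrt(V)
  explained <- evals / sum(eg$values)

  # FastICA on voxels-as-samples with random-rotation restarts
  set.seed(as.integer(seed %% .Machine$integer.max))
  X <- t(white)
  best <- NULL
  diag_runs <- vector("list", restarts)
  for (rs in seq_len(restarts)) {
    R0 <- qr.Q(qr(matrix(stats::rnorm(n_modes^2), n_modes)))
    fit <- tryCatch(
      ica::icafast(X, nc = n_modes, center = TRUE, maxit = maxit, tol = tol,
                   Rmat = R0, alg = "par", fun = "logcosh"),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag_runs[[rs]] <- list(contrast = -Inf, iter = NA_integer_,
                              converged = FALSE)
      next
    }
    S <- fit$S
    S <- sweep(S, 2L, sqrt(colMeans(S^2)), "/")
    # negentropy proxy: squared deviation of E[log cosh] from the Gaussian value
    contrast <- sum((colMeans(log(cosh(S))) - 0.3746)^2)
    converged <- fit$iter < maxit
    diag_runs[[rs]] <- list(contrast = contrast, iter = fit$iter,
                            converged = converged)
    if (is.null(best) || contrast > best$contrast) {
      best <- list(fit = fit, contrast = contrast, converged = converged)
    }
  }
  if (is.null(best)) {
    stop_config("ICA failed in all %d restarts", restarts)
  }
  if (!best$converged && !any(vapply(diag_runs, `[[`, logical(1), "converged"))) {
    stop(structure(class = c("ica_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "ICA did not converge in any of %d restarts (maxit %d, tol %g)",
                     restarts, maxit, tol),
                     call = NULL, diagnostics = diag_runs)))
  }

  maps <- t(best$fit$S)                       # n_modes x voxels sources
  # order by explained variance of the back-projection (icafast's vafs)
  ord <- order(best$fit$vafs, decreasing = TRUE)
  maps <- maps[ord, , drop = FALSE]
  mixing <- best$fit$M[, ord, drop = FALSE]
  # sign convention: heavier tail positive (positive skew)
  skews <- apply(maps, 1L, function(m) mean(((m - mean(m)) / stats::sd(m))^3))
  flip <- ifelse(skews < 0, -1, 1)
  maps <- maps * flip
  mixing <- sweep(mixing, 2L, flip, "*")
  maps <- maps - rowMeans(maps)
  maps <- sweep(maps, 1L, apply(maps, 1L, stats::sd), "/")

  structure(list(
    group_maps = maps, mixing = mixing,
    whitening = white, pca_dim = n_modes,
    explained_variance = explained,
    diagnostics = list(restarts = diag_runs,
                       best_contrast = best$contrast,
                       converged = best$converged,
                       seed = as.integer(seed %% .Machine$integer.max))
  ), class = "group_ica")
}

#' @export
print.group_ica <- function(x, ...) {
  cat(sprintf("Group spatial ICA: %d components x %d voxels\n",
              nrow(x$group_maps), ncol(x$group_maps)))
  cat(sprintf("  PCA explained variance: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " ")))
  cat(sprintf("  converged: %s (best contrast %.4g over %d restarts)\n",
              x$diagnostics$converged, x$diagnostics$best_contrast,
              length(x$diagnostics$restarts)))
  invisible(x)
}

#' @export
coef.group_ica <- function(object, ...) object$group_maps
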