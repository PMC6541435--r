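#' Configuration for the parcel-based mode simulator
#'
#' Builds a validated configuration for [simulate_modes()], which generates a
#' multi-subject, multi-run resting-state dataset from overlapping spatial
#' modes built on a 1-D parcel atlas: subject-specific warps emulate residual
#' misalignment, mode timecourses are correlated and sparsified "neural"
#' series convolved with subject-specific HRFs, and the BOLD signal passes
#' through a weak saturating nonlinearity before structured and heavy-tailed
#' unstructured noise is added. The 1-D voxel line is sufficient for every
#' downstream estimator, which treats maps as vectors.
#'
#' @param n_voxels,n_subjects,n_runs,n_timepoints,n_repeats study dimensions;
#'   `n_timepoints` is per run.
#' @param n_parcels number of contiguous atlas parcels tiling the voxel line.
#' @param n_modes number of spatial modes (non-binary node maps).
#' @param parcel_width_conc symmetric Dirichlet concentration for parcel
#'   widths (larger = more equal widths).
#' @param parcel_weight_shape,parcel_weight_scale Gamma parameters for the
#'   per-parcel amplitude in the atlas.
#' @param regions_rate Poisson rate; each mode has `1 + Poisson(rate)`
#'   contiguous regions.
#' @param parcels_beta,parcels_scale the total parcel budget per mode is
#'   `2 + round(Beta(parcels_beta) * parcels_scale)` (at least one parcel per
#'   region).
#' @param region_conc Dirichlet concentration dividing a mode's parcel budget
#'   across its regions.
#' @param neg_region_prob probability that a non-primary region is
#'   anticorrelated (negative weights); the first region is always positive.
#' @param node_weight_shape,node_weight_scale Gamma parameters for per-parcel
#'   mode weights.
#' @param subject_jitter standard deviation of the multiplicative log-normal
#'   jitter applied to subject mode weights.
#' @param warp_smooth boxcar width (voxels) smoothing the Gaussian noise that
#'   forms the warp gradient.
#' @param warp_amplitude maximum voxel displacement in units of the average
#'   parcel size; 0 gives identity warps.
#' @param tr nominal repetition time (seconds per sample).
#' @param freq_cutoff low-pass emphasis of the neural spectra in Hz; power
#'   falls off above `freq_cutoff` (default 0.1 Hz).
#' @param wishart_dof_group,wishart_dof_subject,wishart_dof_run degrees of
#'   freedom of the Wishart draws composing group-, subject- and run-level
#'   mode covariances (each must be >= `n_modes`; larger = less variation).
#' @param sparsify_threshold neural samples below this value (in SD units)
#'   are set to zero; `-Inf` disables sparsification.
#' @param hrf_coef_mean,hrf_coef_spread mean and spread of the Gaussian draw
#'   of subject HRF basis coefficients (canonical double-gamma HRF plus its
#'   temporal and dispersion derivatives).
#' @param hrf_duration HRF kernel length in seconds.
#' @param nonlin_strength strength s >= 0 of the saturating nonlinearity
#'   `x -> c tanh(x / c)` with `c = 1/s`; 0 gives the identity.
#' @param structured_noise_rank number of confound outer products.
#' @param structured_noise_var,unstructured_noise_var noise variances as
#'   fractions of the (post-nonlinearity) signal variance.
#' @param t_dof degrees of freedom of the Student-t unstructured noise.
#' @param record_noise if `TRUE`, noise realisations are stored in the
#'   ground-truth bundle so the emitted data can be reconstructed exactly;
#'   disable for large runs (reconstruction then requires re-simulation from
#'   the recorded seed).
#' @param seed integer root seed.
#' @return an object of class `modes_sim_config`.
#' @seealso [simulate_modes()], [modes_benchmark_study()]
#' @export
modes_sim_config <- function(n_voxels = 10000, n_subjects = 30, n_runs = 2,
                             n_timepoints = 600, n_repeats = 10,
                             n_parcels = 100, n_modes = 15,
                             parcel_width_conc = 5,
                             parcel_weight_shape = 5, parcel_weight_scale = 0.2,
                             regions_rate = 2,
                             parcels_beta = c(2, 4), parcels_scale = 12,
                             region_conc = 1.5, neg_region_prob = 0.25,
                             node_weight_shape = 3, node_weight_scale = 1,
                             subject_jitter = 0.35,
                             warp_smooth = 20, warp_amplitude = 1,
                             tr = 1, freq_cutoff = 0.1,
                             wishart_dof_group = 25,
                             wishart_dof_subject = 100,
                             wishart_dof_run = 200,
                             sparsify_threshold = 1,
                             hrf_coef_mean = c(1, 0.2, 0.1),
                             hrf_coef_spread = 0.1, hrf_duration = 32,
                             nonlin_strength = 0.05,
                             structured_noise_rank = 10,
                             structured_noise_var = 0.2,
                             t_dof = 8, unstructured_noise_var = 0.5,
                             record_noise = TRUE, seed = 1L) {
  for (nm in c("n_voxels", "n_subjects", "n_runs", "n_timepoints", "n_repeats",
               "n_parcels", "n_modes", "structured_noise_rank")) {
    if (!is_count(get(nm))) stop_config("`%s` must be a positive count", nm)
  }
  if (n_parcels > n_voxels) stop_config("n_parcels must not exceed n_voxels")
  if (n_modes > n_parcels) stop_config("n_modes must not exceed n_parcels")
  for (nm in c("wishart_dof_group", "wishart_dof_subject", "wishart_dof_run")) {
    if (get(nm) < n_modes) {
      stop_config("`%s` (%g) must be at least n_modes (%d)", nm, get(nm), n_modes)
    }
  }
  if (nonlin_strength < 0) stop_config("`nonlin_strength` must be >= 0")
  if (t_dof <= 2) stop_config("`t_dof` must exceed 2 (finite variance)")
  for (nm in c("parcel_width_conc", "parcel_weight_shape", "parcel_weight_scale",
               "regions_rate", "parcels_scale", "region_conc",
               "node_weight_shape", "node_weight_scale", "tr", "freq_cutoff",
               "hrf_duration")) {
    if (get(nm) <= 0) stop_config("`%s` must be positive", nm)
  }
  for (nm in c("neg_region_prob", "subject_jitter", "warp_amplitude",
               "hrf_coef_spread", "structured_noise_var",
               "unstructured_noise_var")) {
    if (get(nm) < 0) stop_config("`%s` must be >= 0", nm)
  }
  if (neg_region_prob > 1) stop_config("`neg_region_prob` must be <= 1")
  stopifnot(length(parcels_beta) == 2L, all(parcels_beta > 0),
            length(hrf_coef_mean) == 3L, warp_smooth >= 1)
  structure(as.list(environment()), class = "modes_sim_config")
}

#' @export
print.modes_sim_config <- function(x, ...) {
  cat("Parcel-based mode simulator configuration\n")
  cat(sprintf("  %d voxels, %d parcels, %d modes\n",
              x$n_voxels, x$n_parcels, x$n_modes))
  cat(sprintf("  %d subjects x %d runs x %d timepoints, %d repeats, seed %d\n",
              x$n_subjects, x$n_runs, x$n_timepoints, x$n_repeats, x$seed))
  cat(sprintf("  warp amplitude %.2f parcel widths; subject jitter %.2f\n",
              x$warp_amplitude, x$subject_jitter))
  cat(sprintf("  noise: structured rank %d (%.0f%% of signal var), t(%g) (%.0f%%)\n",
              x$structured_noise_rank, 100 * x$structured_noise_var,
              x$t_dof, 100 * x$unstructured_noise_var))
  invisible(x)
}

#' Generate a contiguous parcel atlas on the voxel line
#'
#' Parcel widths are proportional to a symmetric Dirichlet draw, rounded to
#' integer voxel counts that sum exactly to `n_voxels` (largest-remainder
#' method, ties broken by parcel index); per-parcel amplitudes are Gamma.
#' Draws where any parcel rounds to width zero are redrawn a bounded number
#' of times.
#'
#' @param config a [modes_sim_config()] object. Uses the current RNG state;
#'   seed via `set.seed()` or use [simulate_modes()] for end-to-end seeding.
#' @return an object of class `sim_atlas`: integer `widths` and `starts`
#'   (1-based first voxel of each parcel), `parcel_of_voxel` (length
#'   `n_voxels`), and positive `weights` per parcel.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "modes_sim_config"))
  P <- config$n_parcels
  V <- config$n_voxels
  widths <- NULL
  for (try in 1:25) {
    p <- rdirichlet1(P, config$parcel_width_conc)
    w <- round_to_total(p, V)
    if (all(w >= 1L)) {
      widths <- w
      break
    }
  }
  if (is.null(widths)) {
    stop_config("atlas generation failed: a parcel rounded to width 0 in 25 draws (increase parcel_width_conc or n_voxels)")
  }
  starts <- c(1L, 1L + cumsum(widths)[-P])
  structure(list(
    widths = widths, starts = as.integer(starts),
    parcel_of_voxel = rep.int(seq_len(P), widths),
    weights = stats::rgamma(P, shape = config$parcel_weight_shape,
                            scale = config$parcel_weight_scale)
  ), class = "sim_atlas")
}

#' @export
print.sim_atlas <- function(x, ...) {
  cat(sprintf("1-D parcel atlas: %d parcels over %d voxels (widths %d-%d)\n",
              length(x$widths), length(x$parcel_of_voxel),
              min(x$widths), max(x$widths)))
  invisible(x)
}

#' Generate per-subject 1-D warp fields
#'
#' The warp gradient is boxcar-smoothed Gaussian noise squashed through
#' `tanh` so it stays in (-1, 1), which keeps the voxel mapping
#' `v -> v + d(v)` strictly monotone and hence invertible. The cumulative
#' displacement is rescaled so the maximum absolute displacement does not
#' exceed `warp_amplitude` times the average parcel size.
#'
#' @param config a [modes_sim_config()] object.
#' @param atlas the [generate_atlas()] result (supplies the average parcel
#'   size).
#' @return list of `n_subjects` numeric displacement vectors (voxels), each
#'   of length `n_voxels`; all-zero when `warp_amplitude = 0`.
#' @export
generate_warps <- function(config, atlas) {
  stopifnot(inherits(config, "modes_sim_config"), inherits(atlas, "sim_atlas"))
  V <- config$n_voxels
  max_disp <- config$warp_amplitude * mean(atlas$widths)
  lapply(seq_len(config$n_subjects), function(s) {
    if (config$warp_amplitude == 0) return(numeric(V))
    width <- max(1L, as.integer(round(config$warp_smooth)))
    noise <- stats::rnorm(V + width)
    sm <- stats::filter(noise, rep(1 / width, width), sides = 1)
    sm <- as.numeric(sm[(width + 1):(V + width)])
    g <- tanh(sm / stats::sd(sm))
    d0 <- cumsum(g)
    s_max <- min(max_disp / max(abs(d0)), 1 / max(abs(g)))
    s_max * d0
  })
}

#' Resample a map stack through a warp field
#'
#' Linear interpolation of each map row at the warped coordinates
#' `v + d(v)`, with edge clamping.
#'
#' @param maps modes x voxels matrix.
#' @param warp displacement vector of length `n_voxels`.
#' @return warped maps, same dimensions.
#' @export
apply_warp <- function(maps, warp) {
  maps <- rbind(maps)
  V <- ncol(maps)
  stopifnot(length(warp) == V)
  if (all(warp == 0)) return(maps)
  coords <- pmin(pmax(seq_len(V) + warp, 1), V)
  t(apply(maps, 1L, function(m) {
    stats::approx(seq_len(V), m, xout = coords, rule = 2)$y
  }))
}

#' Generate overlapping group and subject mode maps from an atlas
#'
#' Each mode is a weighted sum of parcels grouped into contiguous regions:
#' the region count is `1 + Poisson(regions_rate)`, the parcel budget a
#' scaled Beta draw, the split across regions Dirichlet, and per-parcel
#' weights Gamma; non-primary regions are negated with probability
#' `neg_region_prob`. Subject maps share the group parcel identities but
#' jitter the weights (multiplicative log-normal) and are then resampled
#' through the subject's warp.
#'
#' @param config a [modes_sim_config()] object.
#' @param atlas a [generate_atlas()] result.
#' @param warps per-subject warps from [generate_warps()].
#' @return list with `group_maps` (modes x voxels), `subject_maps` (list of
#'   modes x voxels), `group_weights`/`subject_weights` (modes x parcels),
#'   and `mode_parcels` (parcel index set per mode).
#' @export
generate_node_maps <- function(config, atlas, warps) {
  stopifnot(inherits(config, "modes_sim_config"), inherits(atlas, "sim_atlas"))
  P <- config$n_parcels
  k <- config$n_modes
  W <- matrix(0, nrow = k, ncol = P)
  mode_parcels <- vector("list", k)
  for (j in seq_len(k)) {
    for (try in 1:25) {
      n_regions <- 1L + stats::rpois(1L, config$regions_rate)
      budget <- max(n_regions,
                    2L + as.integer(round(stats::rbeta(1, config$parcels_beta[1],
                                                       config$parcels_beta[2]) *
                                            config$parcels_scale)))
      counts <- round_to_total(rdirichlet1(n_regions, config$region_conc), budget)
      counts <- pmax(counts, 1L)
      while (sum(counts) > budget) {
        i <- which.max(counts)
        counts[i] <- counts[i] - 1L
      }
      if (max(counts) > P) next
      signs <- c(1, ifelse(stats::runif(n_regions - 1L) < config$neg_region_prob,
                           -1, 1))
      w <- numeric(P)
      for (r in seq_len(n_regions)) {
        start <- sample.int(P - counts[r] + 1L, 1L)
        idx <- seq.int(start, length.out = counts[r])
        w[idx] <- w[idx] + signs[r] *
          stats::rgamma(counts[r], shape = config$node_weight_shape,
                        scale = config$node_weight_scale)
      }
      if (any(w != 0)) {
        W[j, ] <- w
        mode_parcels[[j]] <- which(w != 0)
        break
      }
    }
    if (is.null(mode_parcels[[j]])) stop_config("mode %d drew zero parcels repeatedly", j)
  }

  paint <- function(weights) {
    vox_amp <- atlas$weights[atlas$parcel_of_voxel]
    t(apply(weights, 1L, function(w) w[atlas$parcel_of_voxel] * vox_amp))
  }
  group_maps <- paint(W)

  subject_weights <- vector("list", config$n_subjects)
  subject_maps <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    jit <- matrix(exp(stats::rnorm(k * P, sd = config$subject_jitter)),
                  nrow = k, ncol = P)
    Ws <- W * jit
    subject_weights[[s]] <- Ws
    subject_maps[[s]] <- apply_warp(paint(Ws), warps[[s]])
  }
  list(group_maps = group_maps, subject_maps = subject_maps,
       group_weights = W, subject_weights = subject_weights,
       mode_parcels = mode_parcels)
}

#' Generate correlated, sparsified neural timecourses
#'
#' Per mode, a random low-frequency-biased spectrum (power falling off above
#' `freq_cutoff` Hz) is realised to a time series. Inter-mode correlations
#' are induced by a covariance composed of group-, subject- and run-level
#' Wishart draws; the series are then standardised and sparsified by zeroing
#' samples below `sparsify_threshold` (in SD units).
#'
#' @param config a [modes_sim_config()] object.
#' @return list with `series` (nested list: subject, then run, each a
#'   timepoints x modes matrix), the realised `cov_group`, `cov_subject`
#'   (list) and `cov_run` (nested list) matrices, and `tnet_run` (realised
#'   correlation of the emitted series per subject/run).
#' @export
generate_timecourses <- function(config) {
  stopifnot(inherits(config, "modes_sim_config"))
  k <- config$n_modes
  T_ <- config$n_timepoints
  nf <- floor(T_ / 2)
  f <- (seq_len(nf)) / (T_ * config$tr)              # Hz
  envelope <- 1 / (1 + (f / config$freq_cutoff)^2)   # low-frequency bias
  tgrid <- seq_len(T_)
  ang <- 2 * pi * outer(tgrid, seq_len(nf) / T_)
  Cmat <- cos(ang)
  Smat <- sin(ang)

  cov_group <- stats::rWishart(1L, config$wishart_dof_group,
                               diag(k) / config$wishart_dof_group)[, , 1L]
  cov_subject <- vector("list", config$n_subjects)
  cov_run <- vector("list", config$n_subjects)
  series <- vector("list", config$n_subjects)
  tnet_run <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    cov_subject[[s]] <- stats::rWishart(
      1L, config$wishart_dof_subject,
      cov_group / config$wishart_dof_subject)[, , 1L]
    cov_run[[s]] <- vector("list", config$n_runs)
    series[[s]] <- vector("list", config$n_runs)
    tnet_run[[s]] <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      sig <- stats::rWishart(1L, config$wishart_dof_run,
                             cov_subject[[s]] / config$wishart_dof_run)[, , 1L]
      cov_run[[s]][[r]] <- sig
      corr <- stats::cov2cor(sig)

      amp <- matrix(abs(stats::rnorm(nf * k)) * envelope, nrow = nf, ncol = k)
      phase <- matrix(stats::runif(nf * k, 0, 2 * pi), nrow = nf, ncol = k)
      x <- Cmat %*% (amp * cos(phase)) - Smat %*% (amp * sin(phase))
      x <- standardise_cols(x, label = "mode timecourse")
      x <- x %*% chol(corr)
      x <- standardise_cols(x, label = "mode timecourse")
      x[x < config$sparsify_threshold] <- 0
      zero <- which(colSums(x != 0) == 0L)
      if (length(zero)) {
        stop_config("sparsification threshold %.3g zeroes mode(s) %s entirely",
                    config$sparsify_threshold, paste(zero, collapse = ", "))
      }
      series[[s]][[r]] <- x
      tnet_run[[s]][[r]] <- stats::cor(x)
    }
  }
  list(series = series, cov_group = cov_group, cov_subject = cov_subject,
       cov_run = cov_run, tnet_run = tnet_run)
}

# Canonical double-gamma HRF basis: the HRF itself plus temporal and
# dispersion derivatives, sampled at `tr` over `duration` seconds, columns
# scaled to unit norm.
hrf_basis <- function(tr = 1, duration = 32) {
  t <- seq(0, duration, by = tr)
  canonical <- function(rate) {
    stats::dgamma(t, shape = 6, rate = rate) -
      stats::dgamma(t, shape = 16, rate = rate) / 6
  }
  h <- canonical(1)
  td <- c(0, diff(h)) / tr
  dd <- (canonical(1.01) - canonical(0.99)) / 0.02
  b <- cbind(h, td, dd)
  sweep(b, 2L, sqrt(colSums(b^2)), "/")
}

#' Draw a subject-specific HRF kernel
#'
#' A random combination of the canonical double-gamma HRF and its temporal
#' and dispersion derivatives, with Gaussian coefficients around
#' `hrf_coef_mean`, renormalised to peak magnitude 1.
#'
#' @param config a [modes_sim_config()] object.
#' @return numeric kernel sampled at `tr`.
#' @export
sample_hrf <- function(config) {
  stopifnot(inherits(config, "modes_sim_config"))
  basis <- hrf_basis(config$tr, config$hrf_duration)
  for (try in 1:25) {
    coefs <- config$hrf_coef_mean + stats::rnorm(3L, sd = config$hrf_coef_spread)
    kern <- as.numeric(basis %*% coefs)
    if (max(abs(kern)) > 1e-8) return(kern / max(abs(kern)))
  }
  stop_config("degenerate HRF draw")
}

#' Convolve mode timecourses with an HRF kernel
#'
#' Causal convolution of each column with the kernel, truncated to the input
#' length.
#'
#' @param neural timepoints x modes matrix.
#' @param kernel numeric HRF kernel (finite, much shorter than the series).
#' @return matrix of the same dimensions as `neural`.
#' @export
hrf_convolve <- function(neural, kernel) {
  neural <- cbind(neural)
  if (!all(is.finite(kernel))) stop_config("non-finite HRF kernel")
  if (length(kernel) >= nrow(neural)) {
    stop_config("HRF kernel (%d samples) must be shorter than the series (%d)",
                length(kernel), nrow(neural))
  }
  T_ <- nrow(neural)
  apply(neural, 2L, function(x) {
    stats::convolve(x, rev(kernel), type = "open")[seq_len(T_)]
  })
}

#' Assemble BOLD data from timecourses, maps and the noise model
#'
#' Voxelwise signal is the outer product of the (HRF-convolved) timecourses
#' and subject maps passed through the weak saturating nonlinearity
#' `x -> c tanh(x/c)`, `c = 1/nonlin_strength`. Structured noise is a sum of
#' `structured_noise_rank` outer products of Gaussian maps and timecourses;
#' unstructured noise is i.i.d. Student-t. Noise variances are calibrated to
#' the configured fractions of the realised signal variance.
#'
#' @param tc timepoints x modes (post-HRF) timecourse matrix.
#' @param maps modes x voxels subject map matrix.
#' @param config a [modes_sim_config()] object.
#' @return list with `data` (timepoints x voxels), `signal`, and (when
#'   `config$record_noise`) `structured` and `unstructured` noise matrices.
#' @export
assemble_data <- function(tc, maps, config) {
  stopifnot(inherits(config, "modes_sim_config"),
            ncol(tc) == nrow(maps))
  sig <- tc %*% maps
  if (config$nonlin_strength > 0) {
    cc <- 1 / config$nonlin_strength
    sig <- cc * tanh(sig / cc)
  }
  sig_var <- stats::var(as.vector(sig))
  T_ <- nrow(sig)
  V <- ncol(sig)

  structured <- NULL
  if (config$structured_noise_var > 0 && sig_var > 0) {
    r <- config$structured_noise_rank
    U <- matrix(stats::rnorm(T_ * r), T_, r)
    Vmat <- matrix(stats::rnorm(r * V), r, V)
    B <- U %*% Vmat
    B <- B * sqrt(config$structured_noise_var * sig_var / stats::var(as.vector(B)))
    structured <- B
  }
  unstructured <- NULL
  if (config$unstructured_noise_var > 0 && sig_var > 0) {
    s <- sqrt(config$unstructured_noise_var * sig_var /
                (config$t_dof / (config$t_dof - 2)))
    unstructured <- matrix(s * stats::rt(T_ * V, df = config$t_dof), T_, V)
  }
  data <- sig
  if (!is.null(structured)) data <- data + structured
  if (!is.null(unstructured)) data <- data + unstructured
  out <- list(data = data, signal = sig)
  if (isTRUE(config$record_noise)) {
    out$structured <- structured
    out$unstructured <- unstructured
  }
  out
}

#' Simulate one repeat of the parcel-based mode dataset
#'
#' Runs the full generative chain: atlas, subject warps, overlapping node
#' maps, correlated sparsified neural timecourses, subject HRF convolution,
#' saturating outer-product signal, and structured plus Student-t noise.
#'
#' @param config a [modes_sim_config()] object.
#' @param repeat_index which repeat (1-based); each repeat derives its own
#'   seed from `config$seed`.
#' @return an object of class `modes_sim`: `data` (list over subjects of
#'   lists over runs of timepoints x voxels matrices) and `truth`, a
#'   `ground_truth` bundle holding the atlas, warps, group and subject maps
#'   and weights, neural and BOLD timecourses, HRF kernels, realised
#'   covariances, per-subject true temporal netmats (`tnet` from the
#'   emitted pre-HRF series and `tnet_bold` from the post-HRF BOLD
#'   timecourses, runs concatenated) and spatial netmats (`snet`), per-run
#'   true netmats, noise records (if enabled) and seeds.
#' @export
simulate_modes <- function(config, repeat_index = 1L) {
  stopifnot(inherits(config, "modes_sim_config"))
  if (!is_count(repeat_index)) stop_config("`repeat_index` must be a positive count")
  rep_seed <- derive_seeds(config$seed, max(config$n_repeats, repeat_index))[repeat_index]
  set.seed(rep_seed)

  atlas <- generate_atlas(config)
  warps <- generate_warps(config, atlas)
  maps <- generate_node_maps(config, atlas, warps)
  tcs <- generate_timecourses(config)

  S <- config$n_subjects
  hrfs <- vector("list", S)
  bold_tc <- vector("list", S)
  data <- vector("list", S)
  noise <- if (config$record_noise) vector("list", S) else NULL
  tnet <- vector("list", S)
  tnet_bold <- vector("list", S)
  snet <- vector("list", S)

  for (s in seq_len(S)) {
    hrfs[[s]] <- sample_hrf(config)
    bold_tc[[s]] <- vector("list", config$n_runs)
    data[[s]] <- vector("list", config$n_runs)
    if (config$record_noise) noise[[s]] <- vector("list", config$n_runs)
    for (r in seq_len(config$n_runs)) {
      tc <- hrf_convolve(tcs$series[[s]][[r]], hrfs[[s]])
      bold_tc[[s]][[r]] <- tc
      asm <- assemble_data(tc, maps$subject_maps[[s]], config)
      data[[s]][[r]] <- asm$data
      if (config$record_noise) {
        noise[[s]][[r]] <- list(structured = asm$structured,
                                unstructured = asm$unstructured)
      }
    }
    tnet[[s]] <- stats::cor(do.call(rbind, tcs$series[[s]]))
    tnet_bold[[s]] <- stats::cor(do.call(rbind, bold_tc[[s]]))
    snet[[s]] <- stats::cor(t(maps$subject_maps[[s]]))
  }

  truth <- structure(list(
    atlas = atlas, warps = warps,
    group_maps = maps$group_maps, subject_maps = maps$subject_maps,
    group_weights = maps$group_weights, subject_weights = maps$subject_weights,
    mode_parcels = maps$mode_parcels,
    neural = tcs$series, bold_tc = bold_tc, hrf = hrfs,
    cov_group = tcs$cov_group, cov_subject = tcs$cov_subject,
    cov_run = tcs$cov_run, tnet_run = tcs$tnet_run,
    tnet = tnet, tnet_bold = tnet_bold, snet = snet, noise = noise,
    seed = rep_seed, config = config
  ), class = "ground_truth")

  structure(list(data = data, truth = truth, config = config,
                 repeat_index = as.integer(repeat_index)),
            class = "modes_sim")
}

#' @export
print.modes_sim <- function(x, ...) {
  cat(sprintf("Parcel-based mode simulation (repeat %d, seed %d)\n",
              x$repeat_index, x$truth$seed))
  cat(sprintf("  %d subjects x %d runs, each %d x %d (timepoints x voxels), %d modes\n",
              length(x$data), length(x$data[[1]]),
              nrow(x$data[[1]][[1]]), ncol(x$data[[1]][[1]]),
              x$config$n_modes))
  shared <- sum(utils::combn(length(x$truth$mode_parcels), 2, function(ij) {
    length(intersect(x$truth$mode_parcels[[ij[1]]],
                     x$truth$mode_parcels[[ij[2]]])) > 0
  }))
  cat(sprintf("  %d mode pairs share at least one parcel\n", shared))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth bundle\n")
  cat(sprintf("  %d subjects; %d modes x %d voxels; seed %d\n",
              length(x$subject_maps), nrow(x$group_maps),
              ncol(x$group_maps), x$seed))
  invisible(x)
}
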