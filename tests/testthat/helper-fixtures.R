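# Shared fixtures. Everything is generated in code; the heavyweight
# simulation studies used by several acceptance checks are computed once per
# test run and cached here.

# A small overlap-simulator configuration for fast unit tests.
tiny_overlap_cfg <- function(...) {
  overlap_sim_config(n_voxels = 500, n_subjects = 5, n_timepoints = 60,
                     node_size = 20, n_repeats = 2, seed = 42, ...)
}

# A small mode-simulator configuration for fast unit tests.
tiny_modes_cfg <- function(...) {
  modes_sim_config(n_voxels = 400, n_subjects = 3, n_runs = 2,
                   n_timepoints = 120, n_parcels = 20, n_modes = 4,
                   n_repeats = 2, seed = 42, ...)
}

# Exactly identifiable data: orthogonal zero-mean timecourses crossed with
# disjoint node maps, no noise.
identifiable_data <- function(n_subjects = 4, n_timepoints = 80,
                              n_voxels = 2000, seed = 7) {
  set.seed(seed)
  # sparse disjoint supports: with only 2% of voxels active per mode the
  # sources are near-independent, so the ICA optimum coincides with truth
  maps <- matrix(0, 2, n_voxels)
  maps[1, 1:40] <- runif(40, 2, 5)
  maps[2, 101:140] <- runif(40, 2, 5)
  subjects <- lapply(seq_len(n_subjects), function(s) {
    raw <- matrix(rnorm(n_timepoints * 2), ncol = 2)
    ts <- qr.Q(qr(raw)) # orthonormal, near-zero-mean columns
    ts <- scale(ts, scale = FALSE)
    list(ts = ts, data = ts %*% maps)
  })
  list(maps = maps,
       ts = lapply(subjects, `[[`, "ts"),
       data = lapply(subjects, `[[`, "data"))
}

# --- cached simulation studies -------------------------------------------
# Study problem sizes are the package's documented defaults for desk-scale
# verification (see the methods vignette): the two-node study keeps the
# full-scale subject, timepoint and repeat counts with a proportionally
# scaled voxel grid; the mode study keeps the full subject/run/timepoint/
# mode structure on a reduced voxel grid.

.study_cache <- new.env(parent = emptyenv())

sim1_study_config <- function() {
  overlap_sim_config(n_voxels = 2500, node_size = 24, n_subjects = 50,
                     n_timepoints = 200, n_repeats = 10, seed = 20240801)
}

sim2_study_config <- function(...) {
  modes_sim_config(n_voxels = 2000, n_subjects = 30, n_runs = 2,
                   n_timepoints = 600, n_parcels = 100, n_modes = 15,
                   n_repeats = 3, record_noise = FALSE, seed = 20240802, ...)
}

sim2_nowarp_config <- function() {
  modes_sim_config(n_voxels = 2000, n_subjects = 15, n_runs = 1,
                   n_timepoints = 600, n_parcels = 100, n_modes = 15,
                   n_repeats = 2, warp_amplitude = 0, record_noise = FALSE,
                   seed = 20240803)
}

cached <- function(name, expr) {
  if (!exists(name, envir = .study_cache)) {
    assign(name, force(expr), envir = .study_cache)
  }
  get(name, envir = .study_cache)
}

get_sim1_study <- function() {
  cached("sim1", suppressWarnings(
    overlap_bias_study(sim1_study_config(), thresholded = TRUE)))
}

get_sim2_study <- function() {
  cached("sim2", suppressWarnings(
    modes_benchmark_study(sim2_study_config())))
}

get_sim2_nowarp_study <- function() {
  cached("sim2_nowarp", suppressWarnings(
    modes_benchmark_study(sim2_nowarp_config())))
}
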