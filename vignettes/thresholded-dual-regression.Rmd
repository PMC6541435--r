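---
title: "Thresholded dual regression: model, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thresholded dual regression: model, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Node-based functional connectivity from resting-state fMRI is routinely
estimated by group spatial ICA followed by dual regression (ICA-DR). Write a
subject's data as the outer-product model `Y = T R S'`, with `Y` a
timepoints-by-voxels matrix, `S` the true node maps, `T` the true node
timecourses, and `R = Q Q'` a rotation. Spatial ICA chooses the rotation so
that the estimated maps `M = Q' S'` are independent across voxels, which
forces `cov(M')` to the identity; whatever spatial covariance the true maps
carried must then reappear in the estimated timecourses `A = T Q`. Two
consequences follow wherever true networks spatially overlap:

* **Temporal edges are inflated.** The covariance of the stage-1 dual
  regression timeseries is a weighted combination of the true temporal and
  the true spatial covariance, so Pearson correlations between node
  timecourses are shifted away from the true temporal coupling.
* **Spatial edges are deflated.** Stage 2 estimates subject maps as
  `pinv(A) Y`; with standardised timeseries the left factor of the
  pseudo-inverse is the inverse of the timeseries covariance, so the
  inflated temporal correlations weight the estimated maps *negatively*.
  Pooled over edges and subjects, estimated temporal and spatial edges
  become negatively correlated even when the truth carries no such
  coupling.

The corrective procedure is **thresholded dual regression**, four stages
per subject:

1. multiple spatial regression of the data on the group maps (timeseries);
2. multiple temporal regression of the data on the stage-1 timeseries
   (subject maps);
3. Gaussian/Gamma mixture-model thresholding of each stage-2 map: a
   Gaussian background plus positive and negative Gamma tails is fitted to
   the map's weight distribution, weights are shifted and rescaled by the
   fitted background mean and standard deviation, and pseudo-z values with
   `|z| < 2` are set to zero (the boundary value survives);
4. multiple spatial regression of the data on the thresholded maps.

Stage-4 timeseries are the recommended input for temporal network matrices;
stage-3 maps for spatial overlap matrices; un-thresholded stage-2 maps
remain the right object for voxelwise inference on map shape and amplitude.

# Estimation stack

`group_ica()` performs temporal-concatenation group spatial ICA: per-subject
voxelwise demeaning, a two-level PCA (per-subject SVD reduction to a
compact spatial basis, then group PCA of the stacked bases), whitening to
exactly `n_modes` dimensions, and FastICA with a logcosh contrast
(tolerance 1e-6, up to 10 restarts from random rotations, best contrast
kept). The per-subject reduction dimension defaults to
`max(2 * n_modes + 2, 20)`, far above the effective rank of the simulated
data, so the two-level scheme matches full concatenated PCA to numerical
precision while keeping the cost linear in voxels. Components are ordered
by explained variance and signed so the heavier tail of each map is
positive; the PCA dimension equals the requested mode count (no automatic
dimensionality estimation). Voxelwise variance normalisation before
concatenation is available but off by default.

`dr_stage1()`/`dr_stage4()` demean the design maps across voxels and the
data across voxels within each timepoint; `dr_stage2()` demeans the data
across time within each voxel and standardises the timeseries (demeaning
always; unit-variance scaling on by default, matching the assumption under
which the stage-2 operator's left factor is the inverse timeseries
covariance — a flag disables it). Collinear designs fail with an error
naming the worst map pair.

## The mixture model

`fit_ggm()` fits the three-component mixture by EM. Design choices:

* **Initialisation.** Background moments come from the IQR-trimmed sample
  (robust to heavy tails); Gamma parameters from method-of-moments on the
  excursions beyond one trimmed SD. Mixing proportions are initialised
  from the tail mass beyond two trimmed SDs *in excess of the Gaussian
  prediction*: a tail with no excess mass to explain starts inactive and is
  pruned immediately. This keeps tail-free (pure-background) maps
  identifiable — a fixed nonzero tail initialisation lets the Gamma
  components siphon a few percent of a pure Gaussian into the tails and
  biases the background SD low.
* **Offsets.** Both Gamma tails are offset to start at the background
  mean. Offsets track the current mean during a short anchoring phase
  (5 passes) and are then frozen; the recorded log-likelihood trace covers
  the frozen phase, where every pass is a proper generalised EM step and
  the trace is guaranteed non-decreasing. The Gamma M-step solves the
  weighted maximum-likelihood digamma equation by Newton's method (shape
  clamped to `[1, 1e4]`), not moment matching, which is what makes the
  monotonicity guarantee hold.
* **Binned likelihood.** Maps larger than ~2000 voxels are fitted on a
  512-bin histogram with counts as weights — the standard way this mixture
  is fitted to component maps — making the fit's cost independent of map
  size; the background SD is floored at the bin resolution. Small inputs
  are fitted exactly, and the two paths agree to well within the
  parameters' sampling variability.
* **Dropping rule.** A tail is dropped when its mixing proportion falls
  below 0.001 or its responsibility-weighted voxel count below 10, during
  initialisation/anchoring only (so the monotone trace is not broken by a
  mid-run model change).
* **Thresholded values.** Surviving voxels keep their signed pseudo-z
  value rather than the raw weight: any affine rescaling per map cancels
  in the downstream regressions (up to column scaling) and in all
  correlation-based quantities.

# The simulators

Both simulators record complete ground truth (maps, timecourses, netmats,
noise, seeds); every random draw derives deterministically from the root
seed, and repeats use seeds derived from it.

## Two-node overlap simulator (`simulate_overlap`)

The minimal construction that exposes the bias: 10,000 voxels, 50 subjects,
200 timepoints, two nodes of 100 voxels sharing 25% of their support. Each
node map is an independent Laplace(0, 0.5) background plus uniform weights
on [2, 12] over the support; the background is additive everywhere,
including inside the support (an open modelling choice: excluding the
background from the support would only remove a zero-mean perturbation of
SD ~0.7 from weights averaging 7, a second-order effect on every edge
quantity).
Node timecourses are unit-variance Gaussian series plus a shared Gaussian
series weighted by `sqrt(2/3)` and restandardised, giving a population
temporal correlation of 0.4; the realised correlation is recorded rather
than assumed. Per-subject map noise is Gaussian with SD equal to 10% of
the mean node weight; the group-level map is drawn once per repeat and
subject maps add noise to it, so there is no between-subject misalignment.
Data are the exact outer product of timecourses and subject maps — the
recorded truth reproduces the data bit-exactly. Node supports are
contiguous index ranges placed deterministically from the seed; 1-D
geometry is irrelevant to every downstream computation, which treats maps
as vectors.

## Parcel-based mode simulator (`simulate_modes`)

A richer generative chain for benchmarking the correction: 100 contiguous
parcels with Dirichlet widths (largest-remainder integer rounding,
deterministic ties) and Gamma amplitudes; 15 modes, each a weighted union
of contiguous parcel regions (region count `1 + Poisson(2)`, parcel budget
a scaled Beta draw, Dirichlet split across regions, non-primary regions
negated with probability 0.25, Gamma weights); subject maps jitter the
weights log-normally (SD 0.35) and are resampled through subject-specific
warps (tanh-squashed boxcar-smoothed Gaussian gradients, displacement
capped at one average parcel width, gradient within (-1, 1) so the warp is
invertible; jitter is applied before warping). "Neural" timecourses have
random spectra with power falling off above 0.1 Hz (nominal TR 1 s),
inter-mode correlations composed from group/subject/run Wishart draws
(dof 25/100/200 around the identity), and are sparsified by zeroing
samples below 1 SD. Each subject has an HRF drawn as a random combination
(coefficients Gaussian around [1, 0.2, 0.1], spread 0.1) of a canonical
double-gamma HRF and its temporal and dispersion derivatives — a standard
subject-varying HRF basis — renormalised to unit peak. The voxelwise
signal passes through the weak saturating odd nonlinearity
`x -> c tanh(x/c)` with `c = 1/0.05` (strength 0 gives the identity), then
rank-10 structured confounds (outer products of Gaussian maps and
timecourses, 20% of signal variance) and Student-t(8) unstructured noise
(50% of signal variance) are added. Distribution parameters are config
fields recorded in every emitted manifest; the defaults were chosen once
to give a moderate, clearly detectable amount of spatial overlap (about a
fifth to a quarter of mode pairs share at least one parcel) without making
modes unrecoverable at the configured noise level.

Two temporal ground truths are stored per subject: the netmat of the
emitted pre-HRF neural series and the netmat of the post-HRF BOLD
timecourses. Evaluation compares estimated temporal edges against the
BOLD-level truth — the quantity an estimator operating on BOLD data can at
best recover — while the neural-level netmat remains available; the
difference between the two is pure HRF smoothing and is common to every
pipeline compared.

### What the generators do not emulate

No 2-D/3-D geometry, no biophysical BOLD model, no scanner drift or
motion, no physiological confound structure beyond the generic
low-rank-plus-heavy-tail noise model, and (in the two-node simulator) no
misalignment. Passing tests on these simulators therefore demonstrate the
estimator's behaviour under the stated generative assumptions — spatial
overlap with known truth — not performance on real data.

# Evaluation

Estimated components are matched to truth by a Hungarian assignment on the
absolute spatial correlation matrix, with the sign of the matched
correlation fixing each mode's sign. Modes whose group-average matched
subject-map correlation falls below 0.5 are excluded, and their incident
edges leave all edge-level metrics. The four accuracy metrics are the
subject-level correlations of timeseries and maps with truth, and the
per-edge cross-subject correlations of temporal and spatial edge values
(computed on Fisher-z edges by default; raw-r is available). The
positive-spatial-edge subset takes, per repeat and edge, a one-tailed
t-test of true spatial edges against zero, Bonferroni-corrected across
`n_edges x n_repeats` comparisons, and summarises each pipeline's
temporal-edge bias on the surviving cells.

# Study conditions used for verification

The test suite and the acceptance script verify the bias and correction on
desk-scale versions of the study conditions, chosen as the package's
standard verification sizes:

* **Two-node study:** 50 subjects x 200 timepoints, 10 repeats (5 in the
  acceptance script), on a 2,500-voxel grid with 24-voxel nodes — the node
  fraction (~1% of voxels) and 25% overlap of the full-scale configuration
  are preserved, and every reported phenomenon is scale-free
  (correlations and ratios).
* **Mode study:** the full 30 subjects x 2 runs x 600 timepoints x 15
  modes x 100 parcels structure on a 2,000-voxel grid, 3 repeats (2 in the
  acceptance script); the no-misalignment control uses 15 subjects x 1 run
  with warp amplitude 0 and 2 repeats.

The defaults of both simulator configurations remain the full-scale study
conditions.

# Known limitations

* With 15 modes at the default noise level, group ICA typically recovers
  11-13 modes above the 0.5 inclusion threshold per repeat; the excluded
  modes' edges are removed from edge metrics, as in the matching rule.
* Cross-subject spatial-edge accuracy is low in absolute terms for both
  pipelines at desk scale — between-subject variance in true spatial edges
  is small relative to edge-estimation noise — but the thresholded
  pipeline's advantage is stable in aggregate.
* The mixture model assumes a dominant background; within small regions of
  interest where most voxels are "active" the background Gaussian is no
  longer identifiable and stage 3 should not be trusted.
* EM convergence is declared on a relative log-likelihood change of 1e-8;
  near-boundary fits (very weak tails) can use many hundreds of the
  maximum 2,000 iterations, and unconverged fits are used for thresholding
  with a warning.
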