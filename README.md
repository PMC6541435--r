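# threshdr — thresholded dual regression for overlapping brain networks

`threshdr` is an R toolkit for studying — and correcting — a systematic bias
in node-based resting-state fMRI functional connectivity estimated with
group spatial ICA followed by dual regression (ICA-DR). It is aimed at
methods researchers and analysts who use ICA-DR network matrices and want
temporal connectivity estimates that are not contaminated by the spatial
overlap between networks.

## The problem and the method

Write a subject's data as the outer-product model **Y = T R S′**, with
**Y** (timepoints × voxels), true node maps **S**, true node timecourses
**T**, and a rotation **R = Q Q′**. Group spatial ICA picks the rotation
that makes the estimated maps **M = Q′ S′** independent across voxels, so
cov(M′) = I: whatever covariance the true maps carried is pushed into the
estimated timecourses **A = T Q**. Consequently:

* stage-1 dual-regression timeseries have cov(A) equal to a weighted
  combination of the true temporal and true spatial covariance — *temporal
  edges (Pearson correlations between node timecourses) are inflated*;
* stage-2 subject maps **S**<sub>DR</sub> = pinv(A) Y are weighted by the
  inverse of that inflated covariance — *spatial edges (correlations
  between node maps) are deflated*, and pooled over edges and subjects the
  two kinds of edges become negatively correlated.

The corrective **thresholded dual regression** adds two stages: (3) fit
each stage-2 map with a Gaussian background + two Gamma tails mixture,
rescale the map to background pseudo-z values and zero entries with
|z| < 2; (4) re-regress the data on the thresholded maps. Stage-4
timeseries are the recommended input for temporal network matrices, and
stage-3 maps for spatial overlap matrices.

The package provides the full estimation stack (`group_ica()`,
`dual_regression()`, `fit_ggm()`, `temporal_netmat()`,
`spatial_netmat()`), two ground-truth simulators (`simulate_overlap()`,
`simulate_modes()`), evaluation tools (`match_components()`,
`accuracy_metrics()`, `positive_edge_subset()`,
`tnet_snet_association()`), end-to-end study drivers
(`overlap_bias_study()`, `modes_benchmark_study()`), TSV/NIfTI I/O with
checksummed run manifests, and a CLI (`inst/cli/threshdr`).

## Worked example

Simulate 20 subjects with two overlapping nodes (true temporal correlation
≈ 0.4, true spatial correlation ≈ 0.05 from 25% node overlap), then run
the full thresholded pipeline:

```r
library(threshdr)
cfg <- overlap_sim_config(n_voxels = 2500, node_size = 24, n_subjects = 20,
                          n_timepoints = 200, seed = 1)
sim <- simulate_overlap(cfg)
fit <- ica_dr(sim$data, n_modes = 2, thresholded = TRUE, seed = 1)
summary(fit)
#> ICA-DR summary: 20 subjects, 2 modes (thresholded)
#>   mean temporal edge: 0.4173 (stage 1: 0.4636)
#>   mean spatial edge:  0.0581 (stage 2: -0.0219)
#>   pooled stage1-Tnet vs stage2-Snet correlation: -0.7383
```

The ground truth for this seed is a mean temporal edge of 0.4057 and a
mean spatial edge of 0.0534. Reading the summary against it: the plain
pipeline inflates the temporal edge (0.4636 vs 0.4057) and drives the
spatial edge negative (−0.0219 vs 0.0534), and the two estimates are
strongly negatively coupled across subjects (r = −0.74) — the bias.
The thresholded stages pull both back to the truth (temporal 0.4173,
spatial 0.0581) — the correction.

The same study at scale, with accuracy metrics and the positive-edge
subset analysis:

```r
study <- overlap_bias_study(overlap_sim_config(seed = 1))   # 10 repeats
bench <- modes_benchmark_study(modes_sim_config(seed = 1, record_noise = FALSE))
```

From the shell:

```sh
Rscript inst/cli/threshdr simulate-overlap --config cfg.yaml --out sim/
Rscript inst/cli/threshdr group-ica --data sim/ --modes 2 --out ica/
Rscript inst/cli/threshdr dualreg --data sim/data_sub001.tsv \
    --maps ica/group_maps.tsv --thresholded --out dr1/
Rscript inst/cli/threshdr netmats --dualreg dr1/ --out nm1/
Rscript inst/cli/threshdr overlap-bias-study --repeats 10 --seed 1 --out study/
```

Every run directory carries a `manifest.json` with the configuration,
seeds and MD5 checksums of all outputs; re-running with the same
configuration reproduces them byte-identically.

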