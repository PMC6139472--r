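# fcmvpa

Task-dependent functional connectivity multivariate pattern analysis for
event-related fMRI, in R.

Given one BOLD test run per subject, per-subject event tables, and a table
of stereotaxic node coordinates, the package computes
psychophysiological-interaction (PPI) style connectivity features and asks
whether they separate two groups of subjects. It also ships a first-class
synthetic-data generator that plants known condition-dependent coupling
differences, so the whole chain is verifiable against ground truth without
any human data.

## The method

For a network of 16 cube-shaped nodes (3 × 3 × 3 voxels) the pipeline
computes, per voxel and per node:

1. hemodynamic **deconvolution** of the BOLD series — ridge inversion of
   the causal Toeplitz operator of the canonical double-gamma HRF,
   `n̂ = (HᵀH + λI)⁻¹Hᵀy`, with λ chosen per series by generalized
   cross-validation;
2. **detrending** (intercept + linear trend);
3. multiplication by the **psychological contrast** — stick functions at
   trial onsets, +1 for Remember-hits, −1 for Know-hits, 0 otherwise;
4. **reconvolution** with the HRF, detrending, and averaging of the 27
   voxel series into one task-dependent series per node.

Pearson correlations between node series fill a symmetric 16 × 16 matrix
whose lower triangle (16 · 15/2 = 120 edges) is the subject's feature
vector. Features are ranked by absolute two-sample t statistic, and a
linear SVM (C = 1, LOOCV) is evaluated 120 times while the number of
included features grows from 1 to 120. The peak of that curve is assessed
against a label-permutation null (ranking recomputed per shuffle), and the
edges included at the peak are reported with within-group mean r values
and a direction flag.

See `vignettes/fcmvpa-methods.Rmd` for the model, its assumptions, the
small-sample behavior of LOOCV + SVM worth knowing about, and every
numerical choice (λ selection, tie-breaks, clamps, grids).

## Worked example

Simulate a 16-subject cohort with one coupling effect injected on the edge
between nodes 1 and 2 (PP group, R-hit epochs, Δρ = 0.6), run the
connectivity stage, and classify:

```r
library(fcmvpa)
eff <- data.frame(i = 2, j = 1, delta_rho = 0.6)
cfg <- sim_cohort_config(n_ctrl = 8, n_pp = 8, grid_shape = c(24, 24, 16),
                         noise_sd = 0.2, effect_edges = eff, seed = 7)
dir <- file.path(tempdir(), "demo")
fc_simulate(cfg, dir)          # NIfTI runs + events TSVs + manifest
fc_connectivity(dir, tr = 2)   # per-subject 120-edge feature files
res <- fc_classify(dir, n_perm = 100, seed = 7)
print(res)
head(res$report, 3)
```

```
Incremental LOOCV classification over 120 features
  peak accuracy 0.938 at k = 3 (chance: 0.5; majority class: 0.500)
  permutation null at peak k: 0.568 +/- 0.253 (100 permutations)
  rank                                                        edge mean_r_CTRL
1    1 Parahippocampal_Gyrus/Hippocampus_L~Parahippocampal_Gyrus_R   0.2048996
2    2                         Parahippocampal_Gyrus_L~Precuneus_L   0.5400626
3    3          Inferior_Frontal_Gyrus_R~Inferior_Temporal_Gyrus_L   0.1991696
  mean_r_PP direction
1 0.5783574   PP>CTRL
2 0.2316267   CTRL>PP
3 0.3855014   PP>CTRL
```

Reading this: 15 of 16 held-out subjects are classified correctly at the
peak (k = 3 features), well above the permutation null at that k
(0.57 ± 0.25). The top-ranked edge is exactly the one the generator
coupled more strongly in the PP group (mean r 0.58 vs 0.20), and its
direction flag says so; the remaining report rows are edges the ranking
found by chance in a small cohort. `fc_classify` also writes `curve.csv`,
`edge_report.csv`, and `results.json` next to the features, and
`plot(res)` draws the accuracy curve against the dashed null with SD bars.

The same three stages are available from a shell via the thin wrapper
`inst/cli/fcmvpa` (`simulate`, `connectivity`, `classify` subcommands).

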