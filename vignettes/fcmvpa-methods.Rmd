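---
title: "Task-dependent connectivity MVPA: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-dependent connectivity MVPA: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmvpa)
```

## The problem

In a Remember/Know recognition test, "Remember" responses mark recollection
with episodic detail and "Know" responses mark familiarity without it. The
question this package addresses is whether the *coupling* between brain
regions during subjective recollection — not regional activation — carries
enough information to tell two groups of subjects apart. The pipeline turns
one event-related BOLD test run per subject into a vector of task-dependent
connectivity strengths over a fixed network of nodes, and asks a linear
classifier to separate the groups from those vectors.

The default protocol the synthetic generator emulates is a single test run
of 360 volumes at TR = 2 s, with 120 previously studied words and 60 new
words presented in 4-s trials; old items draw R-hit / K-hit / miss
responses and new items correct rejections or false alarms. The network is
a set of 16 cube-shaped nodes (3 × 3 × 3 voxels of 3 mm) placed at
stereotaxic coordinates; 16 nodes give 16 × 15 / 2 = 120 node pairs, so
each subject is summarized by 120 Pearson r values.

## From BOLD to task-dependent node series

For each voxel of each node the chain is the standard
psychophysiological-interaction (PPI) construction:

1. **Deconvolution.** The BOLD series y is modeled as the causal
   convolution of a neural-level series n with the canonical double-gamma
   HRF h, y = Hn, where H is the lower-triangular Toeplitz operator of h
   sampled at the TR. We estimate n by ridge-regularized least squares,
   n̂ = (HᵀH + λI)⁻¹Hᵀy. By default λ is chosen per series by generalized
   cross-validation (GCV) over the grid 10⁻⁶…10²; a fixed λ can be set in
   every user-facing function.
2. **Detrending.** Intercept and linear trend are removed by least-squares
   projection (order-1 trend model; residual mean and slope are zero to
   numerical precision).
3. **Psychological factor.** A stick vector over volumes with +1 at R-hit
   onsets, −1 at K-hit onsets, 0 elsewhere. Onsets are binned to the
   nearest TR; no microtime upsampling. Misses, correct rejections, and
   false alarms contribute zeros. Two opposite-sign onsets in one bin are
   an error, not a silent overwrite.
4. **Interaction and reconvolution.** The detrended neural series is
   multiplied elementwise by the stick vector, reconvolved with the same
   HRF (causal, truncated to run length), and detrended again.
5. **Node averaging.** The 27 voxel series of the node are averaged last,
   after the final detrend, giving one representative series per node.

Pearson correlations between the 16 node series, over the *whole* run
rather than condition epochs, fill a symmetric 16 × 16 matrix; the lower
triangle in row-major order — (2,1), (3,1), (3,2), (4,1), … — is the
120-dimensional feature vector. Correlations are used raw: no Fisher z
transform is applied anywhere, because group summaries are reported as
plain averages of r.

### What the deconvolution contract can and cannot promise

Noiseless convolve-then-deconvolve is essentially exact: with λ = 10⁻⁶ the
relative L2 error of the recovered source is about 0.01% when the full
convolution (run plus kernel tail) is available. With noise, however, the
HRF at TR = 2 attenuates the high-frequency half of a white source so far
below the noise floor that *no* estimator can recover it: across the ridge
path the correlation between n̂ and a white-noise truth saturates well
below 0.9 at an SNR of 10 (the test suite computes this oracle bound). The
package therefore states its noisy round-trip
contract in signal space — reconvolving n̂ with the HRF reproduces the
clean signal with correlation above 0.95 at SNR 10 — which is the quantity
the PPI chain actually relies on, since the interaction series is
reconvolved before it is correlated. The test suite checks both forms.

Numerical details: the Toeplitz operator with the canonical HRF has a zero
first sample (the gamma density vanishes at t = 0), so the operator is
singular and λ = 0 is refused with an explicit error; the GCV score is
evaluated through one SVD of the operator shared across all voxel series
of a run.

## The classifier

Features are ranked once on the whole cohort by descending absolute Welch
two-sample t statistic between groups, ties broken by ascending edge index;
an edge with zero within-group variance and unequal means has infinite |t|
and is ranked first but flagged. A linear SVM (cost C = 1, no kernel, raw
unstandardized features) is then trained under leave-one-out
cross-validation 120 times, growing the included features from the 1
best-ranked to all 120. The peak of the accuracy-versus-k curve (smallest k
at ties) is the headline result, and the edges included at the peak are
reported with their within-group mean r values and a direction flag.

Whole-cohort ranking reuses every subject — including each fold's test
subject — so the curve is optimistically biased at intermediate k. This
mirrors the fixed-ordering design the pipeline reproduces; the unbiased
variant that re-ranks inside every training fold is available via
`nested = TRUE`. The significance reference is a label-permutation null:
class labels are shuffled (class counts preserved), *the ranking is
recomputed on the shuffled labels*, and the whole incremental curve is
re-evaluated, 2000 times by default. Re-ranking inside the permutation is
essential — a null that reuses the observed ranking is far too optimistic.
Because the null inherits both the selection bias and the small-sample
pathologies of the observed analysis, "observed within null_mean ± 3
null_sd at every k" is the calibrated no-effect check.

Two small-sample artifacts are worth knowing about. First, balanced
cohorts make every LOOCV training fold unbalanced by one subject; when the
features carry no signal at their native scale, the C = 1 SVM can collapse
to majority voting and LOOCV accuracy falls *below* chance, to 0 in the
extreme. Second, at intermediate k the whole-cohort ranking inflates
accuracy. Both appear identically in the permutation null, which is why
calibration is asserted against the null rather than against 0.5 alone.
With unbalanced groups (the default cohort is 27 vs 25) outputs report the
majority-class proportion alongside 0.5.

## The synthetic generator

The generator exists to make every stage falsifiable: it plants a known
condition-dependent coupling difference between groups and the tests ask
the pipeline to find it.

Latent node signals are drawn per time bin from a zero-mean correlated
Gaussian. The population coupling is compound-symmetric at
`base_rho = 0.3`. Two refinements make the cohorts behave like real ones:

* **Between-subject heterogeneity.** Each subject's intrinsic coupling
  matrix is the sample correlation of m latent draws from the population
  coupling, with m set so the per-edge jitter sd is `subject_rho_sd`
  (default 0.2). This is positive definite by construction, jitters every
  edge independently, and matches the edge-level between-subject spread
  implied by group mean differences of ~0.1 with usable effect sizes.
  Without it all subjects share one coupling matrix, feature variance
  collapses to sampling noise, and the unscaled SVM degenerates to the
  majority-voting regime described above for *every* cohort.
* **One-sided condition effects.** On each configured effect edge, the
  coupling of PP-group subjects rises by `delta_rho` during R-hit trial
  epochs (nearest-TR binned, onset to onset + 4 s); K-hit epochs,
  between-trial bins, and the whole CTRL group stay at baseline, so the
  R-minus-K coupling contrast differs between groups by exactly
  `delta_rho`. The one-sided form matters: a symmetric ±delta/2 split
  across R and K cancels in the measured feature, because both node series
  are multiplied by the *same* psych factor and the sign flip cancels in
  their product. Post-increment correlations are clamped to ±0.95, and a
  jitter draw that breaks positive definiteness after the increment is
  shrunk back toward the population coupling; a population-level
  infeasible request errors with the offending edge list.

BOLD rendering convolves each node's latent series with the canonical HRF
and adds it to all 27 voxels of the node's cube on a 64 × 64 × 32 grid of
3-mm voxels (RAS+, diagonal affine, grid center at the origin); every
voxel receives white Gaussian noise (`noise_sd`, default 0.5 against a
rendered signal sd of ≈ 0.6) and a linear scanner drift (peak-to-peak
`drift_amplitude`, default 1). Behavioral response rates default to
45/35/20% R-hit/K-hit/miss for old items and 90/10% CR/FA for new ones —
placeholders shaping epoch counts, not estimates of any study's rates. All
randomness flows from one master seed through deterministically derived
per-subject, per-stage seeds, so a cohort is a pure function of its config.

What the generator does *not* emulate: motion, slice-timing, physiological
noise, spatial autocorrelation, anatomical variability, or any encoding-
phase data. Passing tests therefore demonstrate that the pipeline's
mathematics recovers what it is supposed to recover from data obeying its
assumptions — not that it would survive every artifact of real acquisitions.

## Node geometry and coordinate conversion

Node tables are configuration inputs (CSV: name, x, y, z, space), never
hard-coded; the packaged 16-name table uses synthetic lattice coordinates
(15-mm spacing) chosen only to fit the rendering grids, and is labeled
synthetic accordingly. Talairach coordinates are converted to MNI with the
inverse of the published Lacadie-style best-fit affine before rounding to
the grid — conversion first, rounding second. The transform is injectable
(any 4 × 4 matrix) for users with a different calibration. Cube centers
use round-half-away-from-zero on the fractional voxel coordinate, a
documented deterministic tie-break; a cube clipped by the grid boundary is
an error, never a silent truncation. Voxel indices are 0-based in affines
and cube definitions (NIfTI convention), 1-based in R array subscripts,
and cube rows are ordered lexicographically by (x, y, z).

## Problem sizes used by tests and the acceptance script

Cohort-level checks run on a compact 24 × 24 × 16 grid at 3 mm — geometry
identical to the default grid, ~25× less data — with these sizes, chosen
once as the smallest that leave the statistical conclusions unambiguous:

* null calibration: 8-node subset (28 edges), 10 + 10 subjects,
  `noise_sd = 0.3`, 200 permutations;
* effect recovery: full 16 nodes, 20 + 20 subjects, three effect edges at
  `delta_rho = 0.6`, `noise_sd = 0.15`, five seeds;
* direction recovery: 8 nodes, 12 + 12 subjects, four effect edges at
  `delta_rho = ±0.5`, three seeds;
* type-I control: fifty feature-level null cohorts against each one's own
  permutation null.

The full-size default grid is exercised by a rendering/serialization test.

## Known limitations

* The deconvolution is a generic ridge inverse with GCV, not a parametric
  empirical Bayes estimator; the round-trip contracts above define what it
  guarantees.
* Whole-cohort feature ranking is optimistically biased by design (the
  nested mode is the honest alternative); peak accuracies should always be
  read against the permutation null, never in isolation.
* Raw unstandardized r features at C = 1 can underfit when between-subject
  variance is small; `standardize = TRUE` is the remedy when features are
  nearly constant.
* No nuisance regression, band-pass filtering, multi-condition (gPPI)
  variant, nonlinear kernels, or hyperparameter search — deliberately out
  of scope.
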