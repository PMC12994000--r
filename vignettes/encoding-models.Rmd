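---
title: "Voxel-wise encoding models with layered-network features: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise encoding models with layered-network features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(voxelenc)
```

## The model

voxelenc implements a two-stage encoding analysis for task fMRI recorded
while a participant interacts with a time-continuous visual stimulus stream
(here, a simple arcade-style game at 45 Hz).

**Stage 1 — nonlinear feature generation.** Stimulus frames are preprocessed
into network states (element-wise maximum of consecutive frames to remove
sprite flicker, area-resampling to 84 × 84 grayscale) and stacked four deep.
A layered action-value network maps each stack to unit activations:
three convolutional layers (32 8×8/4, 64 4×4/2, 64 3×3/1, ReLU; spatial sizes
20, 9, 7), then — depending on the variant — a 512-unit fully connected layer
(`feedforward`), two 512-unit value/advantage streams recombined as
`Q = V + A - mean(A)` (`dueling`), or a fully connected layer feeding a single
512-unit LSTM cell ahead of the dueling streams (`recurrent_dueling`). The
LSTM hidden and cell state are zeroed immediately after any step flagged as an
episode terminal, so memory never crosses a "game over". Every unit's
activation time series (post-ReLU for convolutional and stream units, tanh-
bounded hidden output for the LSTM, raw Q-values for the output layer) becomes
a candidate predictor.

**Stage 2 — voxel-wise regularized GLM.** Per session, the predictor matrix
is processed in a fixed order:

1. units never active across the whole session set are dropped (plus units
   constant within any session, which cannot be z-scored);
2. z-scoring along time, then across units (`zscore_dual()`; the order is a
   config switch — the text description of the procedure does not fix it, and
   temporal-first makes the feature-dimension pass act on comparable units);
3. causal convolution with a canonical double-gamma hemodynamic kernel
   (peak gamma shape 6, undershoot shape 16, scales 1 s, ratio 6, 32 s
   support; mode at 5 s). No parameter set is published for this step, so the
   SPM-convention defaults are used;
4. linear-interpolation resampling to the acquisition grid (TR = 0.987 s;
   volume *k* at time (k−1)·TR; volumes per session = floor(duration/TR),
   e.g. a 7-minute session gives floor(420/0.987) = 425 volumes);
5. high-pass filtering by regression on a discrete-cosine basis holding every
   component with period above 128 s plus the constant (deterministic, and
   matches drift removal "as part of the GLM" rather than an IIR filter);
6. a final temporal z-score.

Convolve-then-resample follows the order in which the processing steps are
described; both the z-score order and the fit mode below are explicit
configuration switches.

BOLD data are motion-corrected by ordinary least squares on the six motion
parameters together with the same DCT basis; the residuals are the analysis
data. The encoding model itself is the lasso,

  minimize (1/2N)·‖y − Xβ‖² + λ‖β‖₁,

solved by cyclic coordinate descent in covariance form, vectorized over
voxels (each voxel is an independent problem sharing the design, so converged
voxels retire from the sweep; because a per-session fit does not depend on
which fold it serves, each session is fit exactly once and reused across
folds).
Convergence is declared when no coefficient moves more than `tol = 1e-6` in a
sweep, with at most 10⁴ sweeps. λ is applied on the 1/(2N) loss scale; values
are only comparable under a fixed convention, and this one matches the common
coordinate-descent implementations (glmnet is used as an independent
cross-check in the test suite, never as the implementation).

**Cross-validation and scoring.** Five sessions, each held out once. The
documented contract reads the training step as: fit the lasso separately on
each of the four training sessions and average the four coefficient vectors
("fitted to four out of five sessions, then coefficients averaged" admits two
readings; the per-session-average reading is the default, a
concatenate-then-fit-once mode is available via `fit_mode`). The held-out
session is predicted as the linear combination of its predictors with the
averaged coefficients, scored by Pearson correlation; a voxel's accuracy is
the mean over the five test sessions. Predictions with zero variance (fully
shrunk fits) score r = 0 and are flagged, not dropped — maps stay complete
and degenerate fits are penalized.

**Penalty selection.** The mean cross-validated correlation is traced over a
grid spanning [0.005, 0.5]; the plateau is the longest contiguous run within
1% of the curve maximum and λ is fixed at the plateau midpoint for all voxels
(`select_lambda()`). The reference interval [0.04, 0.1] yields the default
`fixed_lambda = 0.07`. The 1% band is the package's own formalization — no
formal plateau rule is published.

**Group inference.** Subject-level accuracy maps are Fisher-Z transformed
(values at ±1 clipped to ±(1−1e−7) and counted), tested voxel-wise against
zero with one-sample t-tests, and family-wise-error corrected by Bonferroni
over in-mask voxels. Bonferroni is a deliberate, conservative stand-in for
random-field-theory correction, which needs smoothness estimates of real
spatial maps and is out of scope for this package. ROI comparisons use a
pooled-variance two-sample t-test on subject-level ROI means. Factorial
comparisons use a hand-implemented, fully within-subject repeated-measures
ANOVA on balanced complete tables: each effect is tested against its
effect-by-subject interaction, degrees of freedom are Greenhouse-Geisser
corrected with ε computed from the covariance of the subject-level
orthonormal contrast scores (no Huynh-Feldt fallback), and effect sizes are
partial η² = SS_effect/(SS_effect + SS_error). Custom contrasts are scored
per subject and Bonferroni corrected. Error bars use the
subject-centering recipe with the small-sample correction factor
√(M/(M−1)) for M conditions (`normalized_ci()`).

**Layer-to-region mapping.** Each voxel surviving the group gate
(FWE-corrected p < 0.05) is assigned to the hidden layer whose layer-wise
model predicts it best; exact ties break toward the earlier layer in network
order (deterministic and conservative for hierarchy claims; float ties are
rare and counted). Per ROI, the winner proportions form a composition
(summing to one), summarized by the early/late log-ratio
log((p_conv1+p_conv2+p_conv3+ε)/(p_lstm+p_layer4+ε)) with a symmetric
pseudo-count ε (default 1/(2·n_voxels) per ROI) — the additive variant of the
compositional log-ratio family, chosen because it is exact-antisymmetric
under swapping the early and late masses and finite for degenerate
compositions. ROI pairs are compared by paired t-tests across subjects,
Bonferroni corrected over pairs. Proportions are computed subject-wise by
default (the paired tests need per-subject values); a pooled mode exists.

## What the synthetic generator emulates

Real gameplay, trained network weights, and human fMRI are not shipped or
required. The generator (`simulate_cohort()`) produces:

- a toy visuomotor stream: a ball bouncing in an 84 × 84 screen over a static
  brick band, tracked by a scripted, imperfect paddle policy; episode
  terminals on misses or a forced timer. Defaults reproduce the study
  conditions — five sessions of 7 minutes at 45 Hz, i.e. 18,900 frames per
  session;
- seeded He-style fixture weights (trained reinforcement learning is out of
  scope; on the toy stream well over half the convolutional units fire);
- BOLD voxels as the generative inverse of the encoding model: each voxel is
  a sparse linear mixture (3 active predictors by default) of the assembled
  design of a single designated layer, plus a motion confound
  (per-voxel loadings on six shared AR(1) motion series) and AR(1) Gaussian
  noise (φ = 0.3, marginal variance normalized so that the signal-to-noise
  ratio is interpretable). The recorded per-voxel ceiling is
  √(SNR/(1+SNR)) — at SNR 1, √0.5 ≈ 0.707;
- disjoint rectangular ROIs stacked along one axis, each sourcing one layer —
  a toy cortical hierarchy with known ground truth.

Because the generative model is exactly the linear model the analysis
assumes, parameter recovery is a well-posed acceptance surface: the pipeline
should reassign voxels to their generating layers and approach the recorded
ceilings. Passing these tests shows the machinery is correct and internally
consistent; it does **not** show that real cortical responses are linear in
network features, that real noise is AR(1), or that motion is ever fully
captured by six regressors. Scanner artifacts, physiological noise,
nonlinearity, and spatial correlation are all outside the generator.

Two generator choices deserve explanation. Head motion is modelled as
stationary AR(1) series (φ = 0.3) rather than random walks: a random walk
concentrates essentially all its power at the lowest frequencies, and
projecting it out (with the drift basis) removes a large share of any
HRF-dominated signal, making the recorded ceiling unattainable *by
construction* rather than through any fault of the estimator. Stationary
motion keeps nuisance regression an approximately benign projection while
still exercising the residualization stage end to end. Second, the simulation
studies retain a seeded subsample of 20 units per layer as predictors: the
full network has ~22,000 units, and the desk-scale studies need design
matrices the cross-validation can refit thousands of times; the subsample is
drawn once per cohort, deterministically from the master seed, and ground
truth draws its active sets from the same retained predictors.

## Problem sizes used by the test and acceptance suites

Chosen as the package's desk-scale study conditions:

- recovery cohort: 10 subjects, 5 ROIs × 200 voxels, SNR 1, five sessions of
  200 volumes (~3.3 min of stimulus at 45 Hz each; 200 volumes is also the
  session length used for the noise-ceiling checks), 20 units per layer;
- noise-ceiling study: 50 seeded repetitions at SNR 1, checked against
  √0.5 within ±0.03;
- null safety: 100 pure-noise cohorts (10 subjects × 50–100 voxels), with at
  least 95% expected to show no FWE-significant voxel; rm-ANOVA type-I rate
  at 1000 null tables, 0.05 ± 0.02;
- the toy-game default (7 min, 18,900 frames) is exercised for the session
  arithmetic itself.

## Numerical choices

- Variance threshold 1e−12 separates "constant" from "near-constant" series.
- Sample standard deviations (n−1) everywhere.
- Resampling uses linear interpolation; acquisition times beyond the
  stimulus end are an error, never extrapolated.
- Fisher-Z clipping at |r| = 1 − 1e−7, counted and reported.
- Voxels with zero across-subject variance are excluded from group tests and
  flagged; they never silently enter the Bonferroni count.
- All randomness flows from a single master seed through labelled child
  seeds (`rlang::hash`-derived, kept below 2³¹), so every artifact is a pure
  function of the seed.

## Known limitations

- Bonferroni is conservative relative to random-field-theory FWE; real-data
  significance counts will be lower than an SPM-style analysis would give.
- The rm-ANOVA handles one or two fully within-subject factors on complete
  balanced tables only; no imputation, no between-subject factors.
- The lasso solver targets the dense, moderate-P regime of the desk-scale
  studies; it is exact but not tuned for the ~20,000-predictor regime of the
  full network (the inactive-unit filter and unit subsampling keep desk-scale
  designs small).
- The pre-LSTM fully connected layer of the recurrent variant is treated as
  internal plumbing and not exported as a labelled feature layer; the five
  mapped layers are conv1–3, lstm, and the dueling streams (layer 4).
- NIfTI support covers plain 3-D/4-D volumes with a shared affine; no BIDS
  ingestion, no DICOM.
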