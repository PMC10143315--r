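---
title: "Quantifying Cd, Cu and Pb in herbal material from LIBS spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cd, Cu and Pb in herbal material from LIBS spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libsquant)
```

## The problem

Laser-induced breakdown spectroscopy (LIBS) ablates a small amount of a
pelletized powder sample and records the atomic emission of the resulting
plasma. Within the 210--231 nm window, cadmium, copper and lead all have
identifiable emission lines (Cd II 214.44/226.50 nm, Cd I 228.80 nm,
Cu II 217.94/222.89/224.26 nm, Pb I 217.00 nm, Pb II 220.35 nm), and the
height of each line grows with the element's concentration in the pellet.
Quantification is a calibration problem: given spectra of samples with known
reference concentrations (mg/kg, from ICP-MS), build a model that predicts
the concentration of new samples from their spectra alone.

`libsquant` implements that calibration pipeline end to end for a spiked
concentration-gradient study design on herbal bulb powder: 8 commercial
brands, each divided into 8 gradient groups (the first unspiked, the rest
brought to predetermined Cd/Cu/Pb levels with nitrate stock solutions), 3
replicate pellets per group — 192 samples of 1024 spectral channels.

## The synthetic data generator

Real spectra of this design are rarely publicly available, so the package
ships a generator that emulates the design and makes every downstream stage
testable. One synthetic spectrum is

$$ I(\lambda) = m \left[ B(\lambda) + \sum_{\ell} s_{e(\ell)}\, r_\ell\,
   g(c_{e(\ell)})\, \phi(\lambda; \mu_\ell, \sigma) +
   \sum_{d} h_d\, \phi(\lambda; \mu_d, \sigma) \right] + o + \varepsilon(\lambda), $$

clipped at zero, where $B$ is a smooth quadratic baseline, $\phi$ a Gaussian
line profile, the first sum runs over the eight analyte emission lines
(element $e(\ell)$, relative strength $r_\ell$), the second over six fixed
"decoy" matrix lines tied to no analyte, $m \sim e^{N(0,\,0.1)}$ is a
per-sample multiplicative scatter factor, $o \sim N(0, 60)$ a per-sample
additive offset, and $\varepsilon \sim N(0, 8)$ per-channel noise. The
response $g(c) = c$ is linear by default; an optional saturation constant
$K$ switches it to $c/(1+c/K)$ to emulate self-absorption.

Parameter choices and what they encode:

* **Gradients and spike volumes.** `build_gradient_plan()` carries the
  spiking arithmetic exactly: levels 0--100 (Cd), 0--300 (Cu), 0--200 (Pb)
  mg/kg on 5 g aliquots of 0.01 mol/L nitrate stocks, with molar masses
  fixed at the conventional roundings Cd 112.4, Cu 64, Pb 207.2 g/mol
  (exact IUPAC masses available via `exact_masses = TRUE`). The spike volume
  is $V[\mu L] = c\,m/(M\,C)$.
* **Brand effects.** Each brand draws once a lognormal native background
  concentration per element (medians 0.4 / 3 / 0.3 mg/kg for Cd/Cu/Pb,
  matching the typical unspiked content of such material) and a lognormal
  intensity factor (sd 0.05) emulating matrix differences between brands.
* **Intensity scales.** Baseline about 3000 counts with mild curvature,
  matrix lines 2500--7000 counts, analyte sensitivities 30/10/15 counts per
  mg/kg. Trace-element lines on real plant-matrix LIBS spectra are small
  against the matrix emission; keeping the analyte contribution a minor
  share of the total variance is also what makes multiplicative scatter
  correction behave as a scatter correction rather than renormalizing the
  analyte signal itself.
* **Line width.** Gaussian sigma 0.06 nm, about 3 channels FWHM on the
  1024-point axis, so neighbouring lines stay resolvable.

What the generator does *not* emulate: plasma physics (Saha--Boltzmann
level populations, self-absorption beyond the optional saturation term),
shot-to-shot temporal drift, detector artifacts, and — importantly — any
correlation structure in the channel noise. Passing tests on this generator
show the pipeline's algorithms behave correctly and that its qualitative
conclusions (scatter correction helps; metaheuristic initialization helps a
BPNN) replicate under controlled conditions; they do not certify
instrument-specific performance on real spectra.

A design property worth knowing: all three element gradients increase
together across the 8 groups, in the synthetic data as in the emulated
design. Concentrations of different elements are therefore strongly
correlated across samples, which makes the prediction task easier than a
full factorial design would be, for every model alike.

## Replicate-aware splitting and cross-validation

`split_by_replicate()` assigns, per (brand, group) cell, exactly
`n_train_reps` (default 2) replicates to calibration and the rest to test —
128/64 for the default design — choosing replicates uniformly at random per
cell from a dedicated per-call generator. Per-cell randomization is the
weaker assumption about how such a split is drawn, and is what we
implement.

Cross-validation (`make_folds()`) uses k = 5 folds stratified by gradient
group, so each fold spans the concentration range. The fold count is a
package convention; there is no canonical choice for this design. All standard deviations (SNV rows, RPD) use the sample
convention (n − 1) throughout.

## Spectral pretreatments

Four row-wise pretreatments plus "none" are available, and
`select_preprocessing()` picks among them by cross-validated RMSECV of a
reference PLSR model, fitted inside each fold so that fitted state never
sees held-out rows:

* **MSC** regresses each spectrum on a reference ($x_i = a_i + b_i\,
  \mathrm{ref}$) and returns $(x_i - a_i)/b_i$. The reference is the mean
  *calibration* spectrum, frozen at fit time and reused on test data, which prevents
  train/test leakage.
  Rows with $|b_i| < 10^{-12}$ are returned unchanged with a warning.
* **SNV** centers and scales each row to unit sample sd; constant rows are
  an error naming the row.
* **SG** (Savitzky--Golay) defaults to window 9, polyorder 3 — common
  chemometric defaults; boundary points come from the edge polynomial fits.
* **WT** wavelet denoising: periodized orthogonal Daubechies-4 (8-tap)
  transform, level 3, soft universal threshold
  $t = \hat\sigma \sqrt{2 \ln n}$ with $\hat\sigma$ the MAD estimate from
  the finest detail level. The DWT is implemented in the package (no R
  wavelet library is a dependency) as explicit orthonormal analysis
  matrices, which makes perfect reconstruction at zero threshold an exact
  property rather than a numerical accident.

Ties in RMSECV go to the simpler method (none < SNV < SG < WT < MSC). On
synthetic data with scatter enabled, MSC or SNV wins; with all artifacts
disabled, "none" is within 1% of the best — both are asserted in the test
suite.

## Variable selection

* **PCA** (`pca_fit()`): mean-centered SVD; the pipeline keeps the smallest
  k reaching 95% cumulative explained variance, mirroring the conventional
  rule. Scores, not channels, feed the downstream models.
* **SPA** (`spa_select()`): for every candidate start channel, a chain is
  grown by repeatedly projecting all remaining columns onto the orthogonal
  complement of the chosen span and taking the maximum-norm projection —
  the classic minimally-collinear forward selection. Every (start, k)
  candidate with k in [k_min, k_max] is scored by 5-fold RMSECV of a
  multiple linear regression; ties break to smaller k, then lower start
  index. The default k_max = 10 reflects the handful of channels this
  method is meant to retain; larger caps
  were measured to change the selected error by nothing while multiplying
  runtime.
* **CARS** (`cars_select()`): N = 50 Monte Carlo runs, each fitting a PLSR
  on 80% of the calibration rows over the currently retained channels,
  shrinking the retained count by the exponential decreasing function
  $r_i = a e^{-k i}$ (with $a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$, so
  run 1 keeps all and run N keeps 2), and resampling channels without
  replacement with probability proportional to |PLS coefficient| —
  a deterministic count with stochastic identity. The run with the lowest
  5-fold RMSECV wins. The PLS component count is chosen once on the full
  spectrum by cross-validation and held fixed, capped when a retained set
  becomes smaller.

A known limitation, visible in the acceptance suite: under this generator's
independent per-channel noise, CARS subsets (which keep tens to hundreds of
channels) consistently match or beat full-spectrum PLSR in cross-validation,
while SPA subsets (≤ 10 channels) consistently land a few percent *above*
full-spectrum PLSR — a handful of channels cannot average channel noise the
way the full spectrum can. On real spectra, where noise is partly shared
across channels, SPA fares relatively better; here the corresponding
acceptance expectation documents the gap rather than hiding it.

## Regressors

* **PLSR** (`plsr_fit()`): NIPALS PLS1 — weights from $X^\top y$, score
  deflation per component; at full rank it reproduces ordinary least
  squares (asserted against an OLS oracle). Component count by 5-fold
  RMSECV, capped at 20.
* **BPNN** (`bpnn_init()` / `bpnn_train()`): one hidden layer of
  `round(sqrt(n_in + n_out)) + 4` tanh units (the conventional sizing
  heuristic for small regression networks), linear output, min--max
  scaling of inputs and outputs to [−1, 1] fitted on calibration data only.
  Training is full-batch gradient descent on the scaled-space MSE —
  learning rate 0.01, 1000 epochs, early stop at MSE 1e-4. These are
  deliberately plain choices: reproducible, fast at this problem size, and
  exactly the procedure the metaheuristics below are meant to improve upon.
  Divergence (non-finite loss) aborts with a diagnostic rather than
  returning garbage.

## PSO-BP and SSA-BP

Both hybrids optimize the *initial* flattened parameter vector (W1, b1, W2,
b2 — weights and thresholds jointly) of the network, with fitness equal to
the calibration RMSE of the network as parameterized (no gradient steps
inside the fitness), then fine-tune by back-propagation:

* **PSO** (`pso_minimize()`): 30 particles, 50 iterations, inertia decayed
  linearly 0.9 → 0.4, c1 = c2 = 1.49445, velocities clipped to 20% of the
  bound span, positions clipped to [−3, 3] per weight. Canonical
  constriction-era defaults; at these settings the 10-seed worst
  sphere-function value (dim 5) is below 1e-4, which the acceptance suite
  asserts.
* **SSA** (`ssa_minimize()`): population 30, 50 iterations, 20% discoverers,
  20% scouts, safety threshold 0.8 — the values of the algorithm's original
  description. The discoverer/joiner/scout updates follow the standard
  formulation; one rule is stated loosely in the literature (the scout
  already at the global best "steps away"), and we implement it as a
  bounded uniform factor in [−1, 1] scaled by the distance to the worst
  individual, normalized by the fitness gap.

With 0 optimizer iterations, `hybrid_train()` reduces exactly to plain
seeded BPNN training — a contract the tests pin down. Fitness is
calibration RMSE rather than a validation split, matching common PSO-BP
practice; wall-clock duration is recorded in every report so model families
can be compared for speed, but it is never asserted, being
hardware-dependent.

## Evaluation

`evaluate_model()` reports the seven conventional quantities: R²c/RMSEC on
calibration, R²cv/RMSECV from 5-fold cross-validation (the factory refitted
per fold, so preprocessing references, scalers and selections are learned
inside each fold), R²p/RMSEP on the held-out test partition, and RPD =
sd(test references)/RMSEP with the usual reading (> 1.5 good, 2.0--2.5
satisfactory, > 3.0 valid). R² is computed as the coefficient of
determination, $1 - \sum(y-\hat y)^2 / \sum(y - \bar y)^2$ — the
RMSE-consistent reading of the ambiguous phrase "correlation coefficient";
`squared_pearson()` is exported for the alternative. A leakage guard aborts
if any sample id appears in both partitions.

`relative_error_table()` reproduces the per-sample relative-error view:
$|\hat y - y|/y$ for positive references, absolute error flagged where the
reference is zero (unspiked control samples), with a low/high stratum label
at a configurable threshold (default: median test reference).

## The pipeline and reproducibility

`run_pipeline()` chains the stages per element — split, preprocessing
("auto" replicates the selection *procedure*, not its data-specific
outcome), selection, models, reports, relative-error tables — and writes
CSV/JSON artifacts with the config and seeds echoed. Every source of
randomness descends deterministically from the config seed via a stage-path
hash, so a rerun with the same config reproduces every machine artifact
except wall-clock durations. Stochastic models can be repeated (`repeats`);
the run with the median RMSEP is flagged as the headline and all runs are
retained.

## Problem sizes and numerical conventions

The test suite exercises the full 192 × 1024 default design where the
design itself is the point (split sizes, the 10-seed replication benchmark)
and scaled-down variants (4 × 8 × 3 brands/groups/replicates, 64--256
channels) where only algorithmic behavior is under test; the benchmark
block completes in a few minutes on one CPU. Degenerate inputs are errors
with named locations (ragged CSV rows, constant SNV rows, zero-variance
response, empty folds, infeasible wavelet levels), not silent fixes; the
two deliberate exceptions — MSC's flat-slope rows and CARS capping its
component count on small retained sets — warn or message and continue,
since both arise routinely mid-procedure on legitimate data.
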